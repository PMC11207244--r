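# ggplot2 graphics for each result type

#' @importFrom ggplot2 autoplot ggplot aes geom_line geom_rect geom_point
#'   facet_wrap labs theme_minimal coord_fixed
#' @export
ggplot2::autoplot

#' Plot link-length series with flagged segments
#'
#' One panel per monitored link; shaded bands mark the outlier segments of
#' `report` (red for left/right switches, blue for misdetections).
#'
#' @param lengths a [link_lengths()] series.
#' @param report optional `outlier_report`.
#' @return a ggplot.
#' @export
plot_link_lengths <- function(lengths, report = NULL) {
  long <- tidyr::pivot_longer(tibble::as_tibble(lengths), -"frame",
                              names_to = "link", values_to = "length")
  p <- ggplot(long, aes(x = .data$frame, y = .data$length)) +
    geom_line(linewidth = 0.3) +
    facet_wrap(~link, scales = "free_y") +
    labs(x = "frame", y = "link length") +
    theme_minimal()
  if (!is.null(report) && nrow(report$segments) > 0) {
    bands <- tidy.outlier_report(report)
    p <- p + geom_rect(
      data = bands,
      aes(xmin = .data$start - 0.5, xmax = .data$end + 0.5,
          ymin = -Inf, ymax = Inf, fill = .data$category),
      alpha = 0.25, inherit.aes = FALSE
    ) +
      ggplot2::scale_fill_manual(
        values = c(switch = "red", misdetection = "blue")
      )
  }
  p
}

#' @rdname plot_link_lengths
#' @param object,... autoplot arguments (`...` passes `report`).
#' @export
autoplot.link_length_series <- function(object, ...) {
  plot_link_lengths(object, ...)
}

#' Plot fitted joint-angle profiles
#'
#' @param x an `angle_trajectory` from [fit_sequence()].
#' @param variables pose variables to show (default: all but `gamma`).
#' @return a ggplot, one panel per variable.
#' @export
plot_angle_profiles <- function(x, variables = setdiff(pose_variables(),
                                                       "gamma")) {
  long <- tidy.angle_trajectory(x)
  long <- long[long$variable %in% variables, ]
  ggplot(long, aes(x = .data$frame, y = .data$value)) +
    geom_line(linewidth = 0.3) +
    facet_wrap(~variable, scales = "free_y") +
    labs(x = "frame", y = "angle (degrees)") +
    theme_minimal()
}

#' @rdname plot_angle_profiles
#' @param object,... autoplot arguments.
#' @export
autoplot.angle_trajectory <- function(object, ...) {
  plot_angle_profiles(object, ...)
}

#' Plot a skeleton frame
#'
#' Frontal (x-y) projection of one frame's joints with the monitored
#' links drawn as segments.
#'
#' @param frame joints of one frame: matrix with joint rownames or a
#'   tibble with `joint`, `x`, `y`, `z`.
#' @return a ggplot.
#' @export
plot_skeleton <- function(frame) {
  if (is.matrix(frame)) {
    frame <- tibble::tibble(joint = rownames(frame),
                            x = frame[, 1], y = frame[, 2], z = frame[, 3])
  }
  links <- link_set()
  segs <- dplyr::bind_rows(lapply(seq_len(nrow(links)), function(i) {
    a <- frame[frame$joint == links$joint_a[i], ]
    b <- frame[frame$joint == links$joint_b[i], ]
    tibble::tibble(x = a$x, y = a$y, xend = b$x, yend = b$y,
                   link = links$link[i])
  }))
  ggplot(frame, aes(x = .data$x, y = .data$y)) +
    ggplot2::geom_segment(data = segs,
                          aes(x = .data$x, y = .data$y,
                              xend = .data$xend, yend = .data$yend),
                          colour = "grey40") +
    geom_point(size = 2) +
    coord_fixed() +
    labs(x = "x (toward subject's left)", y = "y (up)") +
    theme_minimal()
}

#' Plot an ROI track
#'
#' Box centre path over frames, held frames highlighted.
#'
#' @param track a `roi_track` from [track_sequence()].
#' @return a ggplot.
#' @export
plot_roi_track <- function(track) {
  d <- dplyr::mutate(tibble::as_tibble(track),
                     cx = (.data$x_min + .data$x_max) / 2,
                     cy = (.data$y_min + .data$y_max) / 2)
  ggplot(d, aes(x = .data$cx, y = .data$cy)) +
    geom_line(colour = "grey60") +
    geom_point(aes(colour = .data$held)) +
    labs(x = "box centre x (px)", y = "box centre y (px)") +
    theme_minimal()
}

#' @rdname plot_roi_track
#' @param object,... autoplot arguments.
#' @export
autoplot.roi_track <- function(object, ...) plot_roi_track(object)
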
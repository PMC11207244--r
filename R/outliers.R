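# Outlier screening for joint trajectories.  Left/right switches and
# misdetections show up as sudden jumps in the lengths of body links that
# change only slowly during genuine motion, so frames are flagged from the
# per-frame derivative of the 10 monitored link lengths and repaired by
# mean interpolation plus median smoothing.

#' Default assumed statures
#'
#' Population-average statures used to convert pixel-space link lengths to
#' centimetres when no measured height is available: 175 cm for men and
#' 160 cm for women.
#'
#' @return named numeric vector (cm).
#' @export
default_statures <- function() c(male = 175, female = 160)

#' The 10 monitored body links
#'
#' Joint pairs whose lengths are screened for outliers: the shoulder line,
#' the pelvis line, and the left/right upper arm, lower arm, thigh and
#' shin.
#'
#' @return tibble with columns `link`, `joint_a`, `joint_b`.
#' @export
link_set <- function() {
  tibble::tribble(
    ~link,          ~joint_a,     ~joint_b,
    "shoulder",     "l_shoulder", "r_shoulder",
    "pelvis",       "l_hip",      "r_hip",
    "l_upper_arm",  "l_shoulder", "l_elbow",
    "r_upper_arm",  "r_shoulder", "r_elbow",
    "l_lower_arm",  "l_elbow",    "l_wrist",
    "r_lower_arm",  "r_elbow",    "r_wrist",
    "l_thigh",      "l_hip",      "l_knee",
    "r_thigh",      "r_hip",      "r_knee",
    "l_shin",       "l_knee",     "l_ankle",
    "r_shin",       "r_knee",     "r_ankle"
  )
}

# joints incident to a set of link names
link_joints <- function(links) {
  ls <- link_set()
  sel <- ls[ls$link %in% links, ]
  unique(c(sel$joint_a, sel$joint_b))
}

# joints to repair for a set of triggering links: the link endpoints plus
# everything distal on the kinematic chain.  A swap or displacement of a
# consistent distal sub-chain (e.g. elbow + wrist together) only disturbs
# the link at its boundary, so the repair must extend to the limb's end.
link_repair_joints <- function(links) {
  chains <- list(
    shoulder = c("l_shoulder", "l_elbow", "l_wrist",
                 "r_shoulder", "r_elbow", "r_wrist"),
    pelvis = c("l_hip", "l_knee", "l_ankle", "r_hip", "r_knee", "r_ankle"),
    l_upper_arm = c("l_shoulder", "l_elbow", "l_wrist"),
    r_upper_arm = c("r_shoulder", "r_elbow", "r_wrist"),
    l_lower_arm = c("l_elbow", "l_wrist"),
    r_lower_arm = c("r_elbow", "r_wrist"),
    l_thigh = c("l_hip", "l_knee", "l_ankle"),
    r_thigh = c("r_hip", "r_knee", "r_ankle"),
    l_shin = c("l_knee", "l_ankle"),
    r_shin = c("r_knee", "r_ankle")
  )
  unique(unlist(chains[links]))
}

#' Per-frame link lengths of a trajectory
#'
#' Euclidean distance between the two endpoint joints of each monitored
#' link, per frame, in the trajectory's units.
#'
#' @param trajectory wide trajectory tibble (columns `<joint>_x/_y/_z`).
#' @param links link table as from [link_set()].
#' @return tibble with `frame` plus one column per link; class
#'   `link_length_series`.
#' @export
link_lengths <- function(trajectory, links = link_set()) {
  n <- nrow(trajectory)
  out <- lapply(seq_len(nrow(links)), function(i) {
    a <- traj_matrix(trajectory, links$joint_a[i])
    b <- traj_matrix(trajectory, links$joint_b[i])
    sqrt(rowSums((a - b)^2))
  })
  names(out) <- links$link
  res <- tibble::as_tibble(c(list(frame = seq_len(n)), out))
  class(res) <- c("link_length_series", class(res))
  res
}

#' Frame-to-frame link length differences
#'
#' @param lengths a [link_lengths()] series.
#' @return tibble with one fewer row: `frame` (the later frame of each
#'   pair) and per-link differences.
#' @export
link_length_diffs <- function(lengths) {
  stopifnot(nrow(lengths) >= 2)
  link_cols <- setdiff(names(lengths), "frame")
  d <- apply(as.matrix(lengths[link_cols]), 2, diff)
  d <- matrix(d, ncol = length(link_cols),
              dimnames = list(NULL, link_cols))
  tibble::as_tibble(cbind(tibble::tibble(frame = lengths$frame[-1]),
                          tibble::as_tibble(d)))
}

#' Convert pixel lengths to centimetres via assumed stature
#'
#' Link lengths measured in a pixel coordinate system depend on the
#' subject's distance from the camera; they are normalised to centimetres
#' by the ratio of an assumed stature (population averages 175 cm for men,
#' 160 cm for women) to the subject's height in pixels.
#'
#' @param lengths numeric vector/matrix or a [link_lengths()] series in
#'   pixels.
#' @param subject_pixel_height subject height in pixels (> 0), e.g. the
#'   tracked bounding-box height.
#' @param stature_cm assumed stature in cm (> 0).
#' @return same shape as `lengths`, in centimetres.
#' @export
normalize_to_cm <- function(lengths, subject_pixel_height, stature_cm = 175) {
  check_number(subject_pixel_height, "subject_pixel_height")
  check_number(stature_cm, "stature_cm")
  if (subject_pixel_height <= 0) stop_pa("`subject_pixel_height` must be > 0")
  if (stature_cm <= 0) stop_pa("`stature_cm` must be > 0")
  scale <- stature_cm / subject_pixel_height
  if (inherits(lengths, "link_length_series") || is.data.frame(lengths)) {
    link_cols <- setdiff(names(lengths), "frame")
    lengths[link_cols] <- lengths[link_cols] * scale
    lengths
  } else {
    lengths * scale
  }
}

#' Detect outlier frames from link-length derivatives
#'
#' A frame is flagged when the magnitude of some link's frame-to-frame
#' length change exceeds `threshold`.  Each super-threshold jump lies
#' between two frames; the one whose link length deviates more from that
#' link's series median is taken as the outlier.  Flagged frames are then
#' grouped into segments: frames within `merge_gap` of each other merge,
#' and two groups bracketing a plateau whose length stays more than
#' `threshold` away from the median (a sustained switch) merge across any
#' gap.  A segment triggered by at least `switch_link_count` distinct
#' links is categorised as a left/right `switch` (whole-body events move
#' many links at once); otherwise as a `misdetection` of the joints on the
#' triggering links.
#'
#' @param lengths a [link_lengths()] series (at least 2 frames).
#' @param threshold length-change threshold per frame, in the series'
#'   units (default 10, intended as cm/frame at 30 fps).
#' @param merge_gap flagged frames closer than this merge into one
#'   segment.
#' @param switch_link_count minimum number of distinct triggering links
#'   for a segment to be classed as a switch.
#' @return object of class `outlier_report`: `mask` (per-frame logical),
#'   `segments` tibble (`start`, `end`, `links` list-column, `category`),
#'   and the thresholds used.
#' @export
detect_outliers <- function(lengths, threshold = 10, merge_gap = 2,
                            switch_link_count = 4) {
  n <- nrow(lengths)
  if (n < 2) stop_pa("need at least 2 frames to detect outliers")
  check_number(threshold, "threshold", lower = 0)
  link_cols <- setdiff(names(lengths), "frame")
  L <- as.matrix(lengths[link_cols])
  D <- diff(L)
  base <- apply(L, 2, median)
  dev <- abs(sweep(L, 2, base))  # per-frame deviation from typical length

  flags <- vector("list", n)   # triggering links per frame
  hits <- which(abs(D) > threshold, arr.ind = TRUE)
  if (nrow(hits) > 0) {
    for (h in seq_len(nrow(hits))) {
      i <- hits[h, 1]          # jump between frames i and i+1
      j <- hits[h, 2]
      f <- if (dev[i + 1, j] > dev[i, j]) i + 1L else i
      flags[[f]] <- c(flags[[f]], link_cols[j])
    }
  }
  flagged <- which(lengths(flags) > 0)

  segments <- tibble::tibble(start = integer(), end = integer(),
                             links = list(), category = character())
  if (length(flagged) > 0) {
    # initial grouping by merge_gap
    grp <- cumsum(c(1, diff(flagged) > merge_gap + 1))
    segs <- lapply(split(flagged, grp), function(fr) {
      list(start = min(fr), end = max(fr),
           links = unique(unlist(flags[fr])))
    })
    # bridge groups separated by a sustained off-median plateau of a
    # common triggering link (long switches only jump at entry and exit)
    merged <- list(segs[[1]])
    if (length(segs) > 1) {
      for (s in segs[-1]) {
        lastk <- length(merged)
        prev <- merged[[lastk]]
        common <- intersect(prev$links, s$links)
        bridge <- FALSE
        if (length(common) > 0 && s$start - prev$end >= 2) {
          between <- seq(prev$end + 1, s$start - 1)
          for (lk in common) {
            if (all(dev[between, lk] > threshold)) { bridge <- TRUE; break }
          }
        }
        if (bridge) {
          merged[[lastk]] <- list(start = prev$start, end = s$end,
                                  links = union(prev$links, s$links))
        } else {
          merged[[lastk + 1]] <- s
        }
      }
    }
    segments <- dplyr::bind_rows(lapply(merged, function(s) {
      tibble::tibble(start = s$start, end = s$end, links = list(s$links),
                     category = if (length(s$links) >= switch_link_count)
                       "switch" else "misdetection")
    }))
  }
  mask <- rep(FALSE, n)
  for (k in seq_len(nrow(segments))) {
    mask[segments$start[k]:segments$end[k]] <- TRUE
  }
  structure(
    list(mask = mask, segments = segments, threshold = threshold,
         merge_gap = merge_gap, switch_link_count = switch_link_count,
         frames = lengths$frame),
    class = "outlier_report"
  )
}

#' @export
print.outlier_report <- function(x, ...) {
  cat("<outlier_report>\n")
  cat(sprintf("  %d of %d frames flagged in %d segment(s)\n",
              sum(x$mask), length(x$mask), nrow(x$segments)))
  if (nrow(x$segments) > 0) {
    for (k in seq_len(nrow(x$segments))) {
      cat(sprintf("  [%d..%d] %s (%s)\n", x$segments$start[k],
                  x$segments$end[k], x$segments$category[k],
                  paste(x$segments$links[[k]], collapse = ", ")))
    }
  }
  invisible(x)
}

#' Repair one outlier segment by mean interpolation
#'
#' Every coordinate of the selected joints within `start..end` is replaced
#' by the mean of its value in the last clean frame before the segment and
#' the first clean frame after it.  A segment touching the start (end) of
#' the sequence is filled with the single available neighbour.
#'
#' @param trajectory wide trajectory tibble.
#' @param start,end first and last frame index of the segment (inclusive).
#' @param joints joints to repair; default all canonical joints present.
#' @return trajectory with the segment repaired.
#' @export
correct_segment <- function(trajectory, start, end, joints = NULL) {
  n <- nrow(trajectory)
  if (end < start) return(trajectory)
  stopifnot(start >= 1, end <= n)
  if (start == 1 && end == n) {
    stop_pa("segment spans the whole sequence; no clean neighbour exists")
  }
  if (is.null(joints)) {
    joints <- intersect(canonical_joints(aux = TRUE),
                        unique(sub("_[xyz]$", "", names(trajectory))))
  }
  cols <- intersect(coord_cols(joints), names(trajectory))
  pre <- if (start > 1) as.numeric(trajectory[start - 1, cols]) else NULL
  post <- if (end < n) as.numeric(trajectory[end + 1, cols]) else NULL
  fill <- if (is.null(pre)) post else if (is.null(post)) pre else (pre + post) / 2
  trajectory[start:end, cols] <-
    as.list(tibble::as_tibble(matrix(fill, nrow = 1,
                                     dimnames = list(NULL, cols))))
  trajectory
}

#' Running-median smoothing of a trajectory
#'
#' Applies a centred running median of odd width to every coordinate
#' column, shrinking the window symmetrically near the sequence edges so
#' the output has the same length as the input.
#'
#' @param trajectory wide trajectory tibble.
#' @param window odd window width, at least 3.
#' @return smoothed trajectory.
#' @export
median_smooth <- function(trajectory, window = 5) {
  if (window %% 2 != 1 || window < 3) {
    stop_pa("`window` must be an odd integer >= 3")
  }
  n <- nrow(trajectory)
  h <- (window - 1) / 2
  cols <- grep("_[xyz]$", names(trajectory), value = TRUE)
  for (cl in cols) {
    v <- trajectory[[cl]]
    sm <- vapply(seq_len(n), function(i) {
      k <- min(h, i - 1, n - i)     # symmetric shrink at the edges
      median(v[(i - k):(i + k)])
    }, numeric(1))
    trajectory[[cl]] <- sm
  }
  trajectory
}

#' Detect and repair outliers in a joint trajectory
#'
#' The full correction pipeline: compute link lengths (normalising pixel
#' units to centimetres when needed), flag outlier segments from their
#' per-frame derivatives, repair each segment by mean interpolation —
#' all joints for left/right switches, only the triggering links' joints
#' for misdetections — and finally median-smooth the result.
#'
#' @param trajectory wide trajectory tibble; attribute `units` may be
#'   `"meters"` (default) or `"pixels"`.
#' @param threshold_cm_per_frame length-change threshold in cm per frame
#'   at 30 fps; rescaled by `30 / fps` for other frame rates.
#' @param fps frame rate; defaults to the trajectory's `fps` attribute
#'   or 30.
#' @param median_window odd width of the final median filter.
#' @param merge_gap,switch_link_count see [detect_outliers()].
#' @param subject_pixel_height,stature_cm pixel-to-cm normalisation for
#'   pixel-unit input (see [normalize_to_cm()]).
#' @return list of class `corrected_trajectory`: `trajectory` (repaired
#'   and smoothed), `report` (the [detect_outliers()] result),
#'   `link_lengths` (pre-correction, in the screened units).
#' @export
correct_trajectory <- function(trajectory,
                               threshold_cm_per_frame = 10,
                               fps = NULL,
                               median_window = 5,
                               merge_gap = 2,
                               switch_link_count = 4,
                               subject_pixel_height = NULL,
                               stature_cm = 175) {
  fps <- fps %||% attr(trajectory, "fps") %||% 30
  units <- attr(trajectory, "units") %||% "meters"
  lens <- link_lengths(trajectory)
  if (identical(units, "pixels")) {
    if (is.null(subject_pixel_height)) {
      stop_pa("pixel-unit trajectories need `subject_pixel_height` for normalisation")
    }
    lens_cm <- normalize_to_cm(lens, subject_pixel_height, stature_cm)
  } else {
    lens_cm <- lens
    lens_cm[setdiff(names(lens_cm), "frame")] <-
      lens_cm[setdiff(names(lens_cm), "frame")] * 100  # m -> cm
  }
  threshold <- threshold_cm_per_frame * 30 / fps
  report <- detect_outliers(lens_cm, threshold = threshold,
                            merge_gap = merge_gap,
                            switch_link_count = switch_link_count)
  out <- trajectory
  if (nrow(report$segments) > 0) {
    for (k in seq_len(nrow(report$segments))) {
      seg <- report$segments[k, ]
      joints <- if (seg$category == "switch") NULL else
        link_repair_joints(seg$links[[1]])
      out <- correct_segment(out, seg$start, seg$end, joints)
    }
  }
  out <- median_smooth(out, median_window)
  for (a in c("fps", "units", "origin")) attr(out, a) <- attr(trajectory, a)
  structure(
    list(trajectory = out, report = report, link_lengths = lens_cm),
    class = "corrected_trajectory"
  )
}

#' @export
print.corrected_trajectory <- function(x, ...) {
  cat("<corrected_trajectory>\n")
  cat(sprintf("  %d frames, %d flagged\n",
              nrow(x$trajectory), sum(x$report$mask)))
  invisible(x)
}
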
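# Single-person ROI selection and tracking from object-detection records.
# Boxes are half-open pixel rectangles [x_min, x_max) x [y_min, y_max), so
# area arithmetic never double-counts shared edges.

box_area <- function(x_min, y_min, x_max, y_max) {
  pmax(x_max - x_min, 0) * pmax(y_max - y_min, 0)
}

#' Intersection over union of two boxes
#'
#' The ratio of the intersection area of two axis-aligned boxes to the sum
#' of their areas minus the intersection.  By convention the result is 0
#' when the union has zero area (two degenerate boxes).
#'
#' @param a,b boxes: numeric length-4 vectors `(x_min, y_min, x_max,
#'   y_max)` or one-row data frames with those columns.
#' @return overlap ratio in `[0, 1]`.
#' @examples
#' iou(c(0, 0, 2, 2), c(1, 1, 3, 3))  # 1/7
#' @export
iou <- function(a, b) {
  a <- as_box(a); b <- as_box(b)
  ix <- max(0, min(a[3], b[3]) - max(a[1], b[1]))
  iy <- max(0, min(a[4], b[4]) - max(a[2], b[2]))
  inter <- ix * iy
  union <- box_area(a[1], a[2], a[3], a[4]) +
    box_area(b[1], b[2], b[3], b[4]) - inter
  if (union <= 0) return(0)
  inter / union
}

as_box <- function(b) {
  if (is.data.frame(b)) {
    b <- as.numeric(b[1, c("x_min", "y_min", "x_max", "y_max")])
  }
  b <- as.numeric(b)
  if (length(b) != 4 || any(!is.finite(b))) {
    stop_pa("a box must be 4 finite numbers (x_min, y_min, x_max, y_max)")
  }
  if (b[3] < b[1] || b[4] < b[2]) {
    stop_pa("box must satisfy x_max >= x_min and y_max >= y_min")
  }
  b
}

check_detections <- function(detections) {
  need <- c("label", "conf", "x_min", "y_min", "x_max", "y_max")
  missing <- setdiff(need, names(detections))
  if (length(missing) > 0) {
    stop_pa("detections need columns: ", paste(missing, collapse = ", "))
  }
  if (any(detections$conf < 0 | detections$conf > 1)) {
    stop_pa("detection confidences must lie in [0, 1]")
  }
  detections
}

#' Select the subject's initial region of interest
#'
#' From the first frame's detection records: detections below the
#' confidence threshold are removed, then all non-person labels, and the
#' largest-area survivor becomes the region of interest.  If nothing
#' survives, the threshold is halved and the selection retried, down to a
#' floor of `threshold_floor`.
#'
#' @param detections tibble with columns `label`, `conf`, `x_min`,
#'   `y_min`, `x_max`, `y_max` (one row per detection).
#' @param threshold starting confidence threshold in `(0, 1]`.
#' @param human_label class label counted as a person.
#' @param threshold_floor lowest threshold tried before giving up.
#' @return one-row tibble: the selected box with its `conf` and the
#'   threshold at which it was accepted.
#' @export
select_initial_roi <- function(detections, threshold = 0.5,
                               human_label = "person",
                               threshold_floor = 0.05) {
  detections <- check_detections(tibble::as_tibble(detections))
  humans <- detections[detections$label %in% human_label, , drop = FALSE]
  if (nrow(humans) == 0) {
    stop_pa("no subject found: no detection labelled as a person",
            class = "poseangle_no_subject")
  }
  thr <- threshold
  repeat {
    keep <- humans[humans$conf >= thr, , drop = FALSE]
    if (nrow(keep) > 0) {
      area <- box_area(keep$x_min, keep$y_min, keep$x_max, keep$y_max)
      best <- which.max(area)  # which.max: first occurrence wins ties
      out <- keep[best, c("label", "conf", "x_min", "y_min", "x_max", "y_max")]
      out$threshold_used <- thr
      return(tibble::as_tibble(out))
    }
    if (thr <= threshold_floor) {
      stop_pa("no subject found at the floor confidence threshold",
              class = "poseangle_no_subject")
    }
    thr <- max(thr / 2, threshold_floor)
  }
}

#' Track the subject's box into the next frame
#'
#' Among the person-labelled detections of the current frame, selects the
#' one maximising `conf + IoU` with the previous frame's box.
#'
#' @param prev previous frame's box (length-4 vector or one-row frame).
#' @param detections current frame's detection records.
#' @param human_label class label counted as a person.
#' @return one-row tibble with the selected box, its `conf`, `iou` with
#'   the previous box, and `score = conf + iou`; `NULL` when no person is
#'   detected (track lost — the caller decides how to fill the gap).
#' @export
track_roi <- function(prev, detections, human_label = "person") {
  prev <- as_box(prev)
  detections <- check_detections(tibble::as_tibble(detections))
  humans <- detections[detections$label %in% human_label, , drop = FALSE]
  if (nrow(humans) == 0) return(NULL)
  ious <- vapply(seq_len(nrow(humans)), function(i) {
    iou(prev, as.numeric(humans[i, c("x_min", "y_min", "x_max", "y_max")]))
  }, numeric(1))
  score <- humans$conf + ious
  best <- which.max(score)
  out <- humans[best, c("label", "conf", "x_min", "y_min", "x_max", "y_max")]
  out$iou <- ious[best]
  out$score <- score[best]
  tibble::as_tibble(out)
}

#' Track the subject across a full detection sequence
#'
#' Frame 1 uses [select_initial_roi()]; every later frame uses
#' [track_roi()] against the previous selection.  Frames where the track
#' is lost (no person detected) carry the previous box forward for up to
#' `max_gap` consecutive frames, after which tracking errors out.
#'
#' @param detections tibble of detection records with a `frame` column,
#'   or a list of per-frame tibbles.
#' @param threshold initial confidence threshold (see
#'   [select_initial_roi()]).
#' @param human_label class label counted as a person.
#' @param max_gap maximum consecutive frames a lost track may be held.
#' @return tibble of class `roi_track`: per frame, the selected box,
#'   `score` (`conf + iou`, `NA` on held frames) and `held` flag.
#' @export
track_sequence <- function(detections, threshold = 0.5,
                           human_label = "person", max_gap = 5) {
  if (is.data.frame(detections)) {
    if (!"frame" %in% names(detections)) {
      stop_pa("detections data frame needs a `frame` column")
    }
    frames <- sort(unique(detections$frame))
    per_frame <- lapply(frames, function(f) {
      detections[detections$frame == f, , drop = FALSE]
    })
  } else {
    per_frame <- detections
    frames <- seq_along(per_frame)
  }
  if (length(per_frame) < 1) stop_pa("need at least one frame of detections")

  first <- select_initial_roi(per_frame[[1]], threshold, human_label)
  rows <- vector("list", length(per_frame))
  rows[[1]] <- tibble::tibble(
    frame = frames[1], x_min = first$x_min, y_min = first$y_min,
    x_max = first$x_max, y_max = first$y_max,
    score = first$conf, held = FALSE
  )
  prev <- as.numeric(first[1, c("x_min", "y_min", "x_max", "y_max")])
  gap <- 0L
  for (i in seq_along(per_frame)[-1]) {
    sel <- track_roi(prev, per_frame[[i]], human_label)
    if (is.null(sel)) {
      gap <- gap + 1L
      if (gap > max_gap) {
        stop_pa("track lost for more than ", max_gap,
                " consecutive frames at frame ", frames[i],
                class = "poseangle_track_lost")
      }
      rows[[i]] <- tibble::tibble(
        frame = frames[i], x_min = prev[1], y_min = prev[2],
        x_max = prev[3], y_max = prev[4], score = NA_real_, held = TRUE
      )
    } else {
      gap <- 0L
      rows[[i]] <- tibble::tibble(
        frame = frames[i], x_min = sel$x_min, y_min = sel$y_min,
        x_max = sel$x_max, y_max = sel$y_max,
        score = sel$score, held = FALSE
      )
      prev <- as.numeric(sel[1, c("x_min", "y_min", "x_max", "y_max")])
    }
  }
  out <- dplyr::bind_rows(rows)
  class(out) <- c("roi_track", class(out))
  out
}
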
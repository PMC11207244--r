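# Reading and writing joint trajectories, detection records and angle
# tables.  The CSV trajectory dialect is one row per frame with columns
# `<joint>_x`, `<joint>_y`, `<joint>_z`; JSON trajectories are a list of
# frames, each either a named map joint -> [x, y, z] (canonical layout) or
# an array of [x, y, z] landmark triples interpreted through a layout's
# index map.

# canonical joint -> 0-based source landmark index for the supported
# pose-estimation backends.  These follow the standard published skeleton
# orderings of each ecosystem (BlazePose 33, SMPL-derived 29, Human3.6M 17)
# and can be overridden with a user-supplied map.
LAYOUT_MAPS <- list(
  mpp33 = c(
    l_shoulder = 11, r_shoulder = 12, l_elbow = 13, r_elbow = 14,
    l_wrist = 15, r_wrist = 16, l_hip = 23, r_hip = 24,
    l_knee = 25, r_knee = 26, l_ankle = 27, r_ankle = 28
  ),
  hybrik29 = c(
    l_hip = 1, r_hip = 2, l_knee = 4, r_knee = 5, l_ankle = 7, r_ankle = 8,
    l_shoulder = 16, r_shoulder = 17, l_elbow = 18, r_elbow = 19,
    l_wrist = 20, r_wrist = 21
  ),
  h36m17 = c(
    r_hip = 1, r_knee = 2, r_ankle = 3, l_hip = 4, l_knee = 5, l_ankle = 6,
    l_shoulder = 11, l_elbow = 12, l_wrist = 13,
    r_shoulder = 14, r_elbow = 15, r_wrist = 16
  )
)
LAYOUT_COUNTS <- c(mpp33 = 33, hybrik29 = 29, h36m17 = 17, canonical12 = 12)

#' Landmark layout of a pose-estimation backend
#'
#' Describes how a backend's landmark list maps onto the canonical
#' 12-joint skeleton.  Built-in layouts: `"mpp33"` (33 landmarks),
#' `"hybrik29"` (29), `"h36m17"` (17), and `"canonical12"` (joints already
#' named).  Index maps are 0-based to match the source ecosystems.
#'
#' @param name layout name.
#' @param index_map optional replacement map: named integer vector,
#'   canonical joint name to 0-based landmark index.
#' @return list of class `landmark_layout` with `name`, `n_landmarks` and
#'   `index_map`.
#' @export
landmark_layout <- function(name = c("canonical12", "mpp33", "hybrik29",
                                     "h36m17"),
                            index_map = NULL) {
  name <- match.arg(name)
  n <- LAYOUT_COUNTS[[name]]
  map <- index_map %||% LAYOUT_MAPS[[name]]
  if (name != "canonical12") {
    missing <- setdiff(canonical_joints(), names(map))
    if (length(missing) > 0) {
      stop_pa("layout map is missing joints: ", paste(missing, collapse = ", "))
    }
    map <- map[canonical_joints()]
    if (any(map < 0 | map >= n)) {
      stop_pa("layout indices must lie in [0, ", n - 1, "]")
    }
    if (anyDuplicated(map)) {
      stop_pa("layout map must assign a distinct landmark to every joint")
    }
  }
  structure(list(name = name, n_landmarks = n, index_map = map),
            class = "landmark_layout")
}

#' Build a trajectory tibble
#'
#' Attaches frame-rate, unit and origin metadata to a wide per-frame joint
#' table and checks that all canonical joints are present and finite.
#'
#' @param data data frame, one row per frame, columns `<joint>_x/_y/_z`.
#' @param fps frames per second (> 0).
#' @param units `"meters"` or `"pixels"`.
#' @param origin `"pelvis_center"` or `"image"`.
#' @return tibble of class `pose_trajectory` with attributes `fps`,
#'   `units`, `origin`.
#' @export
as_trajectory <- function(data, fps = 30, units = c("meters", "pixels"),
                          origin = c("pelvis_center", "image")) {
  units <- match.arg(units)
  origin <- match.arg(origin)
  check_number(fps, "fps")
  if (fps <= 0) stop_pa("`fps` must be > 0")
  data <- tibble::as_tibble(data)
  if (nrow(data) < 1) stop_pa("a trajectory needs at least one frame")
  missing <- setdiff(coord_cols(canonical_joints()), names(data))
  if (length(missing) > 0) {
    stop_pa("trajectory is missing canonical joint columns: ",
            paste(missing, collapse = ", "))
  }
  m <- traj_matrix(data)
  if (!all(is.finite(m))) stop_pa("trajectory coordinates must be finite")
  if (!"frame" %in% names(data)) {
    data <- dplyr::mutate(data, frame = dplyr::row_number(), .before = 1)
  }
  structure(data, fps = fps, units = units, origin = origin,
            class = c("pose_trajectory", class(data)))
}

#' Read a joint-coordinate trajectory
#'
#' Reads a CSV (one row per frame, columns `<joint>_x/_y/_z`) or a JSON
#' trajectory, mapping backend landmark layouts onto the canonical
#' 12-joint skeleton and deriving the `pelvis_center` / `shoulder_center`
#' mid-points.
#'
#' @param path file path; format chosen by extension (`.json` vs `.csv`).
#' @param layout a [landmark_layout()] or layout name.
#' @param fps,units,origin trajectory metadata (see [as_trajectory()]).
#' @return a `pose_trajectory` tibble.
#' @export
read_trajectory <- function(path, layout = "canonical12", fps = 30,
                            units = "meters", origin = "pelvis_center") {
  if (!file.exists(path)) stop_pa("file not found: ", path)
  if (is.character(layout)) layout <- landmark_layout(layout)
  ext <- tolower(tools::file_ext(path))
  if (ext == "json") {
    frames <- jsonlite::fromJSON(path, simplifyVector = FALSE)
    if (length(frames) == 0) stop_pa("JSON trajectory has no frames")
    rows <- lapply(seq_along(frames), function(i) {
      fr <- frames[[i]]
      if (!is.null(names(fr))) {
        need <- canonical_joints()
        missing <- setdiff(need, names(fr))
        if (length(missing) > 0) {
          stop_pa("frame ", i, " is missing joints: ",
                  paste(missing, collapse = ", "))
        }
        m <- do.call(rbind, lapply(fr[need], function(p) as.numeric(p)))
      } else {
        if (layout$name == "canonical12") {
          stop_pa("frame ", i, " is an unnamed landmark array; pass the ",
                  "backend's layout to interpret it")
        }
        if (length(fr) != layout$n_landmarks) {
          stop_pa("frame ", i, " has ", length(fr), " landmarks; layout `",
                  layout$name, "` expects ", layout$n_landmarks)
        }
        m <- do.call(rbind, lapply(layout$index_map + 1, function(k) {
          as.numeric(frames[[i]][[k]])
        }))
      }
      if (ncol(m) != 3 || !all(is.finite(m))) {
        stop_pa("frame ", i, " has malformed coordinates")
      }
      rownames(m) <- canonical_joints()
      flatten_frame(m)
    })
    data <- tibble::as_tibble(do.call(rbind, rows))
  } else {
    data <- tibble::as_tibble(read.csv(path, check.names = FALSE))
    missing <- setdiff(coord_cols(canonical_joints()), names(data))
    if (length(missing) > 0) {
      stop_pa("CSV is missing canonical joint columns: ",
              paste(missing, collapse = ", "))
    }
  }
  data <- add_center_columns(data)
  as_trajectory(data, fps = fps, units = units, origin = origin)
}

# derive pelvis_center / shoulder_center columns when absent
add_center_columns <- function(data) {
  for (ax in c("x", "y", "z")) {
    pc <- paste0("pelvis_center_", ax)
    sc <- paste0("shoulder_center_", ax)
    if (!pc %in% names(data)) {
      data[[pc]] <- (data[[paste0("l_hip_", ax)]] +
                       data[[paste0("r_hip_", ax)]]) / 2
    }
    if (!sc %in% names(data)) {
      data[[sc]] <- (data[[paste0("l_shoulder_", ax)]] +
                       data[[paste0("r_shoulder_", ax)]]) / 2
    }
  }
  data
}

#' Write a trajectory to CSV
#'
#' @param trajectory a trajectory tibble.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_trajectory <- function(trajectory, path) {
  write.csv(as.data.frame(trajectory), path, row.names = FALSE)
  invisible(path)
}

#' Write fitted joint angles to CSV
#'
#' Writes one row per frame with exactly the 21 pose-variable columns in
#' their canonical printed order (degrees; `gamma` dimensionless).
#'
#' @param angles data frame containing the 21 pose-variable columns
#'   (extra columns such as `frame` or `cost` are dropped), or an
#'   `angle_trajectory` from [fit_sequence()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_angles <- function(angles, path) {
  if (inherits(angles, "angle_trajectory")) angles <- angles$angles
  angles <- tibble::as_tibble(angles)
  if (nrow(angles) == 0) stop_pa("no angle rows to write")
  missing <- setdiff(POSE_VARS, names(angles))
  if (length(missing) > 0) {
    stop_pa("angle table is missing variables: ",
            paste(missing, collapse = ", "))
  }
  write.csv(as.data.frame(angles[POSE_VARS]), path, row.names = FALSE)
  invisible(path)
}

#' Read a joint-angle CSV written by [write_angles()]
#'
#' @param path file path.
#' @return tibble with the 21 pose-variable columns.
#' @export
read_angles <- function(path) {
  if (!file.exists(path)) stop_pa("file not found: ", path)
  data <- tibble::as_tibble(read.csv(path, check.names = FALSE))
  missing <- setdiff(POSE_VARS, names(data))
  if (length(missing) > 0) {
    stop_pa("angle file is missing variables: ",
            paste(missing, collapse = ", "))
  }
  data[POSE_VARS]
}

#' Read detection records from JSON
#'
#' Expects a JSON array of frames, each an array of records
#' `{label, conf, box: [x_min, y_min, x_max, y_max]}`, or a flat array of
#' records each carrying a `frame` field.
#'
#' @param path file path.
#' @return tibble with columns `frame`, `label`, `conf`, `x_min`,
#'   `y_min`, `x_max`, `y_max`.
#' @export
read_detections <- function(path) {
  if (!file.exists(path)) stop_pa("file not found: ", path)
  raw <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  rec_row <- function(r, frame) {
    if (is.null(r$box) || length(r$box) != 4) {
      stop_pa("detection record needs a 4-element `box`")
    }
    tibble::tibble(frame = frame, label = as.character(r$label),
                   conf = as.numeric(r$conf),
                   x_min = as.numeric(r$box[[1]]), y_min = as.numeric(r$box[[2]]),
                   x_max = as.numeric(r$box[[3]]), y_max = as.numeric(r$box[[4]]))
  }
  if (length(raw) > 0 && !is.null(raw[[1]]$box)) {
    rows <- lapply(raw, function(r) rec_row(r, as.integer(r$frame %||% NA)))
  } else {
    rows <- unlist(lapply(seq_along(raw), function(f) {
      lapply(raw[[f]], rec_row, frame = f)
    }), recursive = FALSE)
  }
  check_detections(dplyr::bind_rows(rows))
}

#' Write an outlier report to JSON
#'
#' @param report an `outlier_report` from [detect_outliers()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_outlier_report <- function(report, path) {
  segs <- lapply(seq_len(nrow(report$segments)), function(k) {
    list(start = report$segments$start[k], end = report$segments$end[k],
         links = report$segments$links[[k]],
         category = report$segments$category[k])
  })
  jsonlite::write_json(
    list(threshold = report$threshold, n_frames = length(report$mask),
         flagged_frames = which(report$mask), segments = segs),
    path, auto_unbox = TRUE, digits = NA
  )
  invisible(path)
}
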
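# End-to-end pipeline: ROI tracking (when detections are supplied) ->
# outlier detection/correction -> per-frame uDEAS pose fitting.

#' Pipeline configuration
#'
#' Collects the tunable parameters of every stage.  Can be written to and
#' read from YAML for use with the command-line interface.
#'
#' @param conf_threshold initial detection confidence threshold in (0, 1].
#' @param assumed_stature_cm stature used for pixel-to-cm normalisation
#'   (population averages: 175 male, 160 female) and for the humanoid
#'   segment lengths.
#' @param outlier_threshold_cm_per_frame link-length change flagged as an
#'   outlier, in cm per frame at 30 fps.
#' @param median_window odd width of the trajectory median filter.
#' @param merge_gap,switch_link_count outlier segment grouping (see
#'   [detect_outliers()]).
#' @param max_gap maximum consecutive held frames before a track is
#'   declared lost.
#' @param udeas a [udeas_config()].
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(conf_threshold = 0.5,
                            assumed_stature_cm = 175,
                            outlier_threshold_cm_per_frame = 10,
                            median_window = 5,
                            merge_gap = 2,
                            switch_link_count = 4,
                            max_gap = 5,
                            udeas = udeas_config()) {
  check_number(conf_threshold, "conf_threshold", lower = 1e-9, upper = 1)
  if (median_window %% 2 != 1 || median_window < 3) {
    stop_pa("`median_window` must be odd and >= 3")
  }
  structure(
    list(conf_threshold = conf_threshold,
         assumed_stature_cm = assumed_stature_cm,
         outlier_threshold_cm_per_frame = outlier_threshold_cm_per_frame,
         median_window = median_window,
         merge_gap = merge_gap,
         switch_link_count = switch_link_count,
         max_gap = max_gap,
         udeas = udeas),
    class = "pipeline_config"
  )
}

#' Read a pipeline configuration from YAML
#'
#' Unknown keys error; missing keys take their defaults.  The `udeas`
#' block maps onto [udeas_config()].
#'
#' @param path YAML file path.
#' @return a [pipeline_config()].
#' @export
read_pipeline_config <- function(path) {
  raw <- yaml::read_yaml(path)
  known <- setdiff(names(formals(pipeline_config)), "udeas")
  extra <- setdiff(names(raw), c(known, "udeas"))
  if (length(extra) > 0) {
    stop_pa("unknown config keys: ", paste(extra, collapse = ", "))
  }
  args <- raw[intersect(names(raw), known)]
  if (!is.null(raw$udeas)) {
    args$udeas <- do.call(udeas_config, raw$udeas)
  }
  do.call(pipeline_config, args)
}

#' Run the full post-processing pipeline
#'
#' Optional ROI tracking over the detection records, link-length outlier
#' detection and correction, then per-frame humanoid pose fitting.
#'
#' @param trajectory a `pose_trajectory` (or path to a trajectory file).
#' @param detections optional detection records tibble (or path to a
#'   detections JSON); when omitted the tracking stage is skipped.
#' @param config a [pipeline_config()].
#' @param spec optional [humanoid_spec()]; defaults to one built from
#'   `config$assumed_stature_cm`.
#' @param fit if `FALSE`, stop after outlier correction (no angle
#'   estimation).
#' @return list of class `pipeline_result`: `angles`
#'   (an `angle_trajectory`, or `NULL` when `fit = FALSE`), `corrected`
#'   (the corrected trajectory), `report` (outlier report), `roi_track`
#'   (or `NULL`), and `config`.
#' @export
run_pipeline <- function(trajectory, detections = NULL,
                         config = pipeline_config(), spec = NULL,
                         fit = TRUE) {
  if (is.character(trajectory)) trajectory <- read_trajectory(trajectory)
  if (is.character(detections)) detections <- read_detections(detections)
  spec <- spec %||% humanoid_spec(stature_cm = config$assumed_stature_cm)

  roi <- NULL
  pixel_height <- NULL
  if (!is.null(detections)) {
    roi <- withCallingHandlers(
      track_sequence(detections, threshold = config$conf_threshold,
                     max_gap = config$max_gap),
      error = function(e) stop_pa("tracking stage: ", conditionMessage(e))
    )
    pixel_height <- median(roi$y_max - roi$y_min)
  }

  corrected <- tryCatch(
    correct_trajectory(
      trajectory,
      threshold_cm_per_frame = config$outlier_threshold_cm_per_frame,
      median_window = config$median_window,
      merge_gap = config$merge_gap,
      switch_link_count = config$switch_link_count,
      subject_pixel_height = pixel_height,
      stature_cm = config$assumed_stature_cm
    ),
    error = function(e) stop_pa("outlier stage: ", conditionMessage(e))
  )

  angles <- NULL
  if (isTRUE(fit)) {
    angles <- tryCatch(
      fit_sequence(corrected$trajectory, spec, config$udeas),
      error = function(e) stop_pa("fitting stage: ", conditionMessage(e))
    )
  }
  structure(
    list(angles = angles, corrected = corrected$trajectory,
         report = corrected$report, link_lengths = corrected$link_lengths,
         roi_track = roi, config = config, spec = spec),
    class = "pipeline_result"
  )
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat("<pipeline_result>\n")
  cat(sprintf("  %d frames; %d outlier frame(s) in %d segment(s)\n",
              nrow(x$corrected), sum(x$report$mask), nrow(x$report$segments)))
  if (!is.null(x$roi_track)) {
    cat(sprintf("  ROI tracked over %d frames (%d held)\n",
                nrow(x$roi_track), sum(x$roi_track$held)))
  }
  if (!is.null(x$angles)) {
    cat(sprintf("  median fit MPJPE %.4f m\n", median(x$angles$angles$cost)))
  }
  invisible(x)
}
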
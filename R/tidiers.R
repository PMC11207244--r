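# broom-style tidiers for fitted objects

#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' Tidy a single-frame pose fit
#'
#' @param x a `pose_fit` from [fit_frame()].
#' @param ... unused.
#' @return tibble with one row per pose variable: `variable`, `estimate`,
#'   the configured bounds, and `unit`.
#' @export
tidy.pose_fit <- function(x, ...) {
  tibble::tibble(
    variable = POSE_VARS,
    estimate = unname(x$pose),
    lo = x$spec$bounds$lo,
    hi = x$spec$bounds$hi,
    unit = c("ratio", rep("degrees", length(POSE_VARS) - 1))
  )
}

#' Fit-level summary of a single-frame pose fit
#'
#' @param x a `pose_fit`.
#' @param ... unused.
#' @return one-row tibble: `mpjpe_m`, `gamma`, `n_evals`, `restarts`.
#' @export
glance.pose_fit <- function(x, ...) {
  tibble::tibble(
    mpjpe_m = x$cost,
    gamma = x$pose[["gamma"]],
    n_evals = x$evals,
    restarts = max(x$history$restart)
  )
}

#' Tidy an angle trajectory into long format
#'
#' @param x an `angle_trajectory` from [fit_sequence()].
#' @param ... unused.
#' @return long tibble: `frame`, `variable`, `value` (degrees; `gamma`
#'   dimensionless).
#' @export
tidy.angle_trajectory <- function(x, ...) {
  tidyr::pivot_longer(x$angles, cols = dplyr::all_of(POSE_VARS),
                      names_to = "variable", values_to = "value")
}

#' Sequence-level summary of an angle trajectory
#'
#' @param x an `angle_trajectory`.
#' @param ... unused.
#' @return one-row tibble: frame count, median/max MPJPE, median `gamma`.
#' @export
glance.angle_trajectory <- function(x, ...) {
  tibble::tibble(
    n_frames = nrow(x$angles),
    median_mpjpe_m = median(x$angles$cost),
    max_mpjpe_m = max(x$angles$cost),
    median_gamma = median(x$angles$gamma)
  )
}

#' Tidy an outlier report into its segment table
#'
#' @param x an `outlier_report` from [detect_outliers()].
#' @param ... unused.
#' @return tibble: `start`, `end`, `n_frames`, `category`, `links`
#'   (collapsed string).
#' @export
tidy.outlier_report <- function(x, ...) {
  if (nrow(x$segments) == 0) {
    return(tibble::tibble(start = integer(), end = integer(),
                          n_frames = integer(), category = character(),
                          links = character()))
  }
  tibble::tibble(
    start = x$segments$start,
    end = x$segments$end,
    n_frames = x$segments$end - x$segments$start + 1L,
    category = x$segments$category,
    links = vapply(x$segments$links, paste, "", collapse = ",")
  )
}
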
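# Synthetic motion: smooth sinusoidal joint-angle scripts passed through
# the humanoid forward kinematics, plus the corruption modes the pipeline
# targets (left/right switches, end-joint misdetections, Gaussian jitter),
# with exact ground truth for every stage.

#' Sinusoidal joint-angle motion script
#'
#' Defines per-variable angle trajectories
#' `angle(t) = base + amplitude * sin(2 * pi * t / period_s + phase)`.
#' Three named scripts emulate common exercise motions: `"rowing"` (trunk
#' pitch with synchronous shoulder/elbow pulls and knee drive),
#' `"back_chest"` (trunk extension with arm abduction) and `"arm_leg"`
#' (alternating contralateral arm raises and hip flexion).  Amplitudes sit
#' well inside the physiological bounds of [default_angle_bounds()].
#'
#' @param name script name.
#' @param duration number of frames.
#' @param fps frames per second.
#' @param amplitude_scale multiplies every amplitude (0 gives a constant
#'   pose).
#' @return object of class `motion_script`: tibble of sinusoid parameters
#'   plus timing metadata.
#' @export
motion_script <- function(name = c("rowing", "back_chest", "arm_leg"),
                          duration = 120, fps = 30, amplitude_scale = 1) {
  name <- match.arg(name)
  stopifnot(duration >= 1, fps > 0, amplitude_scale >= 0)
  base_tab <- switch(
    name,
    rowing = tibble::tribble(
      ~variable,     ~base, ~amplitude, ~period_s, ~phase,
      "theta_ws",      25,     18,        2.5,      0,
      "theta_sh_l",    55,     40,        2.5,      pi,
      "theta_sh_r",    55,     40,        2.5,      pi,
      "theta_el_l",    60,     35,        2.5,      0,
      "theta_el_r",    60,     35,        2.5,      0,
      "theta_hp_l",    45,     30,        2.5,      0,
      "theta_hp_r",    45,     30,        2.5,      0,
      "theta_kn_l",    60,     40,        2.5,      0,
      "theta_kn_r",    60,     40,        2.5,      0
    ),
    back_chest = tibble::tribble(
      ~variable,     ~base, ~amplitude, ~period_s, ~phase,
      "theta_ws",       5,     25,        3,        0,
      "phi_sh_l",      45,     35,        3,        0,
      "phi_sh_r",      45,     35,        3,        0,
      "theta_sh_l",    30,     25,        3,        pi / 2,
      "theta_sh_r",    30,     25,        3,        pi / 2,
      "theta_el_l",    25,     20,        3,        0,
      "theta_el_r",    25,     20,        3,        0
    ),
    arm_leg = tibble::tribble(
      ~variable,     ~base, ~amplitude, ~period_s, ~phase,
      "theta_sh_l",    60,     50,        2,        0,
      "theta_sh_r",    60,     50,        2,        pi,
      "theta_hp_l",    40,     30,        2,        pi,
      "theta_hp_r",    40,     30,        2,        0,
      "theta_kn_l",    45,     30,        2,        pi,
      "theta_kn_r",    45,     30,        2,        0,
      "theta_el_l",    20,     15,        2,        0,
      "theta_el_r",    20,     15,        2,        pi
    )
  )
  base_tab$amplitude <- base_tab$amplitude * amplitude_scale
  structure(list(name = name, params = base_tab,
                 duration = as.integer(duration), fps = fps),
            class = "motion_script")
}

#' Generate a ground-truth motion
#'
#' Samples the script's angle curves per frame, checks them against the
#' model's bounds, and runs the forward kinematics to produce the clean
#' coordinate trajectory.
#'
#' @param script a [motion_script()].
#' @param spec a [humanoid_spec()].
#' @param gamma constant size factor for the whole motion.
#' @return list with `angles` (tibble: `frame` + the 21 pose variables)
#'   and `trajectory` (clean `pose_trajectory`, metres, pelvis-centred).
#' @export
generate_motion <- function(script, spec = humanoid_spec(), gamma = 1) {
  stopifnot(inherits(script, "motion_script"))
  n <- script$duration
  t_s <- (seq_len(n) - 1) / script$fps
  angles <- matrix(0, nrow = n, ncol = length(POSE_VARS),
                   dimnames = list(NULL, POSE_VARS))
  angles[, "gamma"] <- gamma
  for (k in seq_len(nrow(script$params))) {
    p <- script$params[k, ]
    angles[, p$variable] <- p$base +
      p$amplitude * sin(2 * pi * t_s / p$period_s + p$phase)
  }
  lo <- spec$bounds$lo; hi <- spec$bounds$hi
  for (j in seq_along(POSE_VARS)) {
    bad <- which(angles[, j] < lo[j] | angles[, j] > hi[j])
    if (length(bad) > 0) {
      stop_pa(sprintf("script drives `%s` out of bounds at frame %d",
                      POSE_VARS[j], bad[1]))
    }
  }
  coords <- t(apply(angles, 1, function(v) {
    as.vector(t(fk_eval(unname(v), spec$lengths)))
  }))
  colnames(coords) <- coord_cols(canonical_joints(aux = TRUE))
  traj <- as_trajectory(tibble::as_tibble(coords), fps = script$fps)
  list(
    angles = dplyr::mutate(tibble::as_tibble(angles),
                           frame = seq_len(n), .before = 1),
    trajectory = traj
  )
}

# the six left/right joint pairs
LR_PAIRS <- list(
  c("l_shoulder", "r_shoulder"), c("l_elbow", "r_elbow"),
  c("l_wrist", "r_wrist"), c("l_hip", "r_hip"),
  c("l_knee", "r_knee"), c("l_ankle", "r_ankle")
)

#' Corrupt a clean trajectory with the failure modes of pose estimators
#'
#' Applies, in order: left/right switches (the listed joint pairs swap
#' coordinates over a frame range; a partial switch swaps a subset of
#' pairs, producing cross-body links), misdetection events (a single joint
#' displaced by a fixed offset over a frame range), and isotropic Gaussian
#' jitter everywhere.  Returns the exact ground-truth outlier mask.
#' A full-body switch of a perfectly symmetric pose leaves coordinates
#' unchanged and is therefore invisible to any detector.
#'
#' @param trajectory clean trajectory tibble.
#' @param switches tibble with columns `start`, `end` and optionally
#'   `joints` (list-column of joint-pair base names such as `"shoulder"`,
#'   `"elbow"`; `NULL` row = all six pairs).
#' @param misdetections tibble with columns `joint`, `start`, `end`,
#'   `dx`, `dy`, `dz`.
#' @param jitter_sd standard deviation (trajectory units) of coordinate
#'   jitter; 0 disables.
#' @param seed RNG seed for the jitter.
#' @return list: `trajectory` (corrupted), `truth_mask` (logical
#'   per-frame), `events` (tibble of injected events).
#' @export
corrupt_trajectory <- function(trajectory, switches = NULL,
                               misdetections = NULL, jitter_sd = 0.005,
                               seed = NULL) {
  n <- nrow(trajectory)
  out <- trajectory
  truth <- rep(FALSE, n)
  events <- list()

  if (!is.null(switches) && nrow(switches) > 0) {
    for (k in seq_len(nrow(switches))) {
      s <- max(1L, switches$start[k]); e <- min(n, switches$end[k])
      if (e < s) stop_pa("switch segment ", k, " is empty or out of range")
      pairs <- if ("joints" %in% names(switches) &&
                   !is.null(switches$joints[[k]])) {
        lapply(switches$joints[[k]], function(b) paste0(c("l_", "r_"), b))
      } else LR_PAIRS
      for (pr in pairs) {
        ca <- coord_cols(pr[1]); cb <- coord_cols(pr[2])
        tmp <- out[s:e, ca]
        out[s:e, ca] <- setNames(out[s:e, cb], ca)
        out[s:e, cb] <- setNames(tmp, cb)
      }
      truth[s:e] <- TRUE
      events[[length(events) + 1]] <- tibble::tibble(
        type = "switch", start = s, end = e,
        detail = paste(vapply(pairs, paste, "", collapse = "/"),
                       collapse = ";")
      )
    }
  }

  if (!is.null(misdetections) && nrow(misdetections) > 0) {
    for (k in seq_len(nrow(misdetections))) {
      m <- misdetections[k, ]
      s <- max(1L, m$start); e <- min(n, m$end)
      if (e < s) stop_pa("misdetection event ", k, " is empty or out of range")
      cols <- coord_cols(m$joint)
      out[s:e, cols[1]] <- out[s:e, cols[1]] + m$dx
      out[s:e, cols[2]] <- out[s:e, cols[2]] + m$dy
      out[s:e, cols[3]] <- out[s:e, cols[3]] + m$dz
      truth[s:e] <- TRUE
      events[[length(events) + 1]] <- tibble::tibble(
        type = "misdetection", start = s, end = e, detail = m$joint
      )
    }
  }

  if (jitter_sd > 0) {
    cols <- grep("_[xyz]$", names(out), value = TRUE)
    noise <- local_seed(seed, matrix(stats::rnorm(n * length(cols),
                                                  sd = jitter_sd),
                                     nrow = n))
    out[cols] <- out[cols] + noise
  }
  for (a in c("fps", "units", "origin")) attr(out, a) <- attr(trajectory, a)
  list(trajectory = out,
       truth_mask = truth,
       events = if (length(events) > 0) dplyr::bind_rows(events)
       else tibble::tibble(type = character(), start = integer(),
                           end = integer(), detail = character()))
}
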
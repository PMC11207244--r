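# Per-frame inverse kinematics: minimise the 12-joint mean per-joint
# position error (MPJPE) between measured coordinates and the humanoid
# forward kinematics, over the 21-variable pose vector.

# measured input for one frame as a 12 x 3 matrix in canonical joint order
as_measured_matrix <- function(measured) {
  if (is.data.frame(measured)) {
    if (all(c("joint", "x", "y", "z") %in% names(measured))) {
      idx <- match(canonical_joints(), measured$joint)
      if (anyNA(idx)) {
        stop_pa("measured frame is missing joints: ",
                paste(canonical_joints()[is.na(idx)], collapse = ", "))
      }
      m <- as.matrix(measured[idx, c("x", "y", "z")])
    } else {
      m <- frame_matrix(measured, 1L)
    }
  } else {
    m <- measured[canonical_joints(), , drop = FALSE]
    if (anyNA(m)) stop_pa("measured frame is missing canonical joints")
  }
  rownames(m) <- canonical_joints()
  if (!all(is.finite(m))) stop_pa("measured coordinates must be finite")
  m
}

# re-centre a 12 x 3 measured matrix on the hip midpoint, the model origin
center_on_pelvis <- function(m) {
  pelvis <- (m["l_hip", ] + m["r_hip", ]) / 2
  sweep(m, 2, pelvis)
}

#' Mean per-joint position error of a pose against measured joints
#'
#' The fitting cost: the mean, over the 12 canonical joints, of the
#' Euclidean distance between the measured coordinates and the forward
#' kinematics of `pose`, both expressed in the pelvis-centred frame.
#' Zero exactly when the fitted model overlaps the measurement.
#'
#' @param pose named pose vector (degrees, plus `gamma`).
#' @param measured one frame of measured joints: a tibble with
#'   `joint`, `x`, `y`, `z` columns, a one-row wide trajectory, or a
#'   matrix with canonical joint rownames.  Metres.
#' @param spec a [humanoid_spec()].
#' @return MPJPE in metres.
#' @export
mpjpe_cost <- function(pose, measured, spec = humanoid_spec()) {
  pose <- as_pose_vector(pose)
  meas <- center_on_pelvis(as_measured_matrix(measured))
  fk <- fk_eval(unname(pose), spec$lengths)[canonical_joints(), ]
  mean(sqrt(rowSums((fk - meas)^2)))
}

#' Closed-form initial pose estimate from measured joints
#'
#' A geometric starting point for the optimizer.  The rigid torso
#' quadrilateral fixes the size factor (`gamma` equals measured
#' shoulder-plus-pelvis width over the model's) and the body orientation
#' (pelvis line direction and pelvis-to-shoulder-centre direction); each
#' limb's sagittal/coronal angles follow from its proximal segment
#' direction in that frame, and knee/elbow flexion from the bend between
#' segments.  The waist is left neutral — the optimizer reapportions trunk
#' orientation between body and waist.  All values are clamped into the
#' model's bounds.
#'
#' @param measured one frame of measured joints (see [mpjpe_cost()]),
#'   metres.
#' @param spec a [humanoid_spec()].
#' @return named pose vector (degrees) suitable as a warm start for
#'   [fit_frame()].
#' @export
initial_pose_estimate <- function(measured, spec = humanoid_spec()) {
  m <- center_on_pelvis(as_measured_matrix(measured))
  L <- spec$lengths
  unit <- function(v) {
    n <- sqrt(sum(v^2))
    if (n < 1e-9) c(0, -1, 0) else v / n
  }
  cross3 <- function(a, b) {
    c(a[2] * b[3] - a[3] * b[2], a[3] * b[1] - a[1] * b[3],
      a[1] * b[2] - a[2] * b[1])
  }
  deg <- 180 / pi

  wp <- sqrt(sum((m["l_hip", ] - m["r_hip", ])^2))
  ws <- sqrt(sum((m["l_shoulder", ] - m["r_shoulder", ])^2))
  g <- (wp + ws) / (2 * (L[["hip_half_width"]] + L[["shoulder_half_width"]]))

  # body frame: x along the pelvis line, y toward the shoulder centre
  xh <- unit(m["l_hip", ] - m["r_hip", ])
  C <- (m["l_shoulder", ] + m["r_shoulder", ]) / 2
  y0 <- unit(C)
  z0 <- cross3(xh, y0)
  if (sqrt(sum(z0^2)) < 1e-6) z0 <- c(0, 0, 1) else z0 <- unit(z0)
  y1 <- cross3(z0, xh)
  R <- cbind(xh, y1, z0)
  # decompose R = Ry(psi) Rz(phi) Rx(theta)
  phi <- asin(max(-1, min(1, R[2, 1])))
  psi <- atan2(-R[3, 1], R[1, 1])
  M <- t(rot_z(phi)) %*% t(rot_y(psi)) %*% R
  theta <- atan2(M[3, 2], M[2, 2])

  p <- reference_pose()
  p["gamma"] <- g
  p["theta_bd"] <- theta * deg
  p["phi_bd"] <- phi * deg
  p["psi_bd"] <- psi * deg

  # waist frame from the measured shoulder line and the trunk direction
  # (shoulder centre relative to the estimated lumbar joint), expressed
  # relative to the body frame as Rx(theta) Rz(phi) Ry(psi)
  W <- R %*% c(0, g * L[["lumbar_offset"]], 0)
  xs <- unit(m["l_shoulder", ] - m["r_shoulder", ])
  yw <- unit(C - as.vector(W))
  zw <- cross3(xs, yw)
  if (sqrt(sum(zw^2)) < 1e-6) zw <- z0 else zw <- unit(zw)
  yw2 <- cross3(zw, xs)
  Rws <- cbind(xs, yw2, zw)
  Mrel <- t(R) %*% Rws
  phi_ws <- asin(max(-1, min(1, -Mrel[1, 2])))
  theta_ws <- atan2(Mrel[3, 2], Mrel[2, 2])
  Myaw <- t(rot_z(phi_ws)) %*% t(rot_x(theta_ws)) %*% Mrel
  psi_ws <- atan2(Myaw[1, 3], Myaw[3, 3])
  p["theta_ws"] <- theta_ws * deg
  p["phi_ws"] <- phi_ws * deg
  p["psi_ws"] <- psi_ws * deg

  # proximal segment direction u in the parent frame satisfies
  # u = (sin phi, -cos phi cos theta, cos phi sin theta)
  seg_angles <- function(u) {
    c(theta = atan2(u[3], -u[2]) * deg, phi = asin(max(-1, min(1, u[1]))) * deg)
  }
  bend <- function(a, b) acos(max(-1, min(1, sum(unit(a) * unit(b))))) * deg
  Rt <- t(R)        # legs hang off the body frame
  Rwt <- t(Rws)     # arms hang off the waist frame

  for (s in c("l", "r")) {
    hip <- m[paste0(s, "_hip"), ]; knee <- m[paste0(s, "_knee"), ]
    ank <- m[paste0(s, "_ankle"), ]
    a <- seg_angles(unit(Rt %*% (knee - hip)))
    p[paste0("theta_hp_", s)] <- a["theta"]
    p[paste0("phi_hp_", s)] <- a["phi"]
    p[paste0("theta_kn_", s)] <- bend(knee - hip, ank - knee)

    sh <- m[paste0(s, "_shoulder"), ]; el <- m[paste0(s, "_elbow"), ]
    wr <- m[paste0(s, "_wrist"), ]
    ua <- unit(Rwt %*% (el - sh))
    a <- seg_angles(ua)
    p[paste0("theta_sh_", s)] <- a["theta"]
    p[paste0("phi_sh_", s)] <- a["phi"]
    p[paste0("theta_el_", s)] <- bend(el - sh, wr - el)
    # forearm direction in the shoulder frame gives the transverse angle
    Rsh <- rot_x(-a["theta"] / deg) %*% rot_z(a["phi"] / deg)
    w <- t(Rsh) %*% (Rwt %*% unit(wr - el))
    if (p[paste0("theta_el_", s)] > 1) {
      p[paste0("psi_sh_", s)] <- atan2(w[1], w[3]) * deg
    }
  }

  # clamp into bounds with a small interior margin
  b <- spec$bounds
  pmin(pmax(p, b$lo + 1e-6 * (b$hi - b$lo)), b$hi - 1e-6 * (b$hi - b$lo))
}

# fast cost closure over the positional pose vector
make_mpjpe_fn <- function(meas, lengths) {
  jidx <- match(canonical_joints(), c(canonical_joints(), AUX_JOINTS))
  function(v) {
    fk <- fk_eval(v, lengths)
    d <- fk[jidx, ] - meas
    mean(sqrt(rowSums(d * d)))
  }
}

#' Fit the humanoid pose to one measured frame
#'
#' Estimates the 21-variable pose vector minimising [mpjpe_cost()] for a
#' single frame with the uDEAS global optimizer.  The measured frame is
#' re-centred on its hip midpoint before fitting; the size factor `gamma`
#' absorbs global scale.
#'
#' @param measured one frame of measured joints (see [mpjpe_cost()]).
#' @param spec a [humanoid_spec()].
#' @param config a [udeas_config()].
#' @param warm_start optional pose vector used to seed one extra restart
#'   (e.g. the previous frame's solution).
#' @param geometric_start seed one restart at the closed-form
#'   [initial_pose_estimate()]?  Random restarts alone can settle in
#'   scale/orientation compensation minima (a smaller, pitched body can
#'   mimic a crouch); the geometric estimate anchors a restart in the
#'   right basin while every variable stays free.
#' @return object of class `pose_fit`: `pose` (named vector, degrees),
#'   `cost` (MPJPE, metres), `fitted` joint positions, and the optimizer
#'   history.
#' @export
fit_frame <- function(measured, spec = humanoid_spec(),
                      config = udeas_config(), warm_start = NULL,
                      geometric_start = TRUE) {
  meas <- center_on_pelvis(as_measured_matrix(measured))
  cost_fn <- make_mpjpe_fn(meas, spec$lengths)
  lo <- spec$bounds$lo
  hi <- spec$bounds$hi
  ws <- list()
  if (!is.null(warm_start)) ws <- c(ws, list(unname(as_pose_vector(warm_start))))
  if (isTRUE(geometric_start)) {
    ws <- c(ws, list(unname(initial_pose_estimate(meas, spec))))
  }
  if (length(ws) == 0) ws <- NULL
  opt <- udeas_optimize(cost_fn, lo, hi, config, warm_start = ws)
  pose <- setNames(opt$par, POSE_VARS)
  structure(
    list(pose = pose, cost = opt$cost,
         fitted = fk_eval(unname(pose), spec$lengths),
         measured = meas, evals = opt$evals, history = opt$history,
         spec = spec),
    class = "pose_fit"
  )
}

#' @export
print.pose_fit <- function(x, ...) {
  cat("<pose_fit>\n")
  cat(sprintf("  MPJPE %.4f m after %d cost evaluations\n", x$cost, x$evals))
  cat(sprintf("  gamma %.3f; largest angles: %s\n", x$pose[["gamma"]],
              paste(names(sort(abs(x$pose[-1]), decreasing = TRUE)[1:3]),
                    collapse = ", ")))
  invisible(x)
}

#' Fit the humanoid pose to every frame of a trajectory
#'
#' Runs [fit_frame()] frame by frame.  By default each frame's search adds
#' one restart warm-started at the previous frame's solution, which keeps
#' angle profiles temporally coherent; set `warm_start = FALSE` for fully
#' independent fits.
#'
#' @param trajectory wide trajectory tibble (one row per frame, columns
#'   `<joint>_x/_y/_z`, metres, pelvis-centred).
#' @param spec a [humanoid_spec()].
#' @param config a [udeas_config()]; when it carries a seed, frame `i`
#'   uses `seed + i - 1` so the whole sequence is reproducible.
#' @param warm_start warm-start each frame at the previous solution?
#' @return object of class `angle_trajectory`: tibble `angles` with
#'   `frame`, the 21 pose variables (degrees), and `cost` (metres), plus
#'   the list of per-frame fits.
#' @export
fit_sequence <- function(trajectory, spec = humanoid_spec(),
                         config = udeas_config(), warm_start = TRUE) {
  n <- nrow(trajectory)
  if (n < 1) stop_pa("trajectory must have at least one frame")
  fits <- vector("list", n)
  prev <- NULL
  for (i in seq_len(n)) {
    cfg <- config
    if (!is.null(config$seed)) cfg$seed <- config$seed + i - 1L
    ws <- if (isTRUE(warm_start)) prev else NULL
    fits[[i]] <- tryCatch(
      fit_frame(frame_matrix(trajectory, i), spec, cfg, warm_start = ws),
      error = function(e) stop_pa("fit failed at frame ", i, ": ",
                                  conditionMessage(e))
    )
    prev <- fits[[i]]$pose
  }
  angles <- dplyr::bind_rows(lapply(seq_len(n), function(i) {
    tibble::as_tibble(as.list(fits[[i]]$pose))
  }))
  angles <- dplyr::mutate(angles,
                          frame = seq_len(n), cost = vapply(fits, `[[`, numeric(1), "cost"),
                          .before = 1)
  structure(
    list(angles = angles, fits = fits,
         fps = attr(trajectory, "fps") %||% NA_real_, spec = spec),
    class = "angle_trajectory"
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.angle_trajectory <- function(x, ...) {
  cat("<angle_trajectory>\n")
  cat(sprintf("  %d frames, median MPJPE %.4f m\n",
              nrow(x$angles), median(x$angles$cost)))
  invisible(x)
}
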
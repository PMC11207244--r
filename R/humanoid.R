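# 21 optimisation variables in their canonical printed order:
# global size factor, 3 body angles, 3 waist (lumbar) angles, then the
# sagittal hip/knee/shoulder/elbow pairs, coronal hip pairs, coronal and
# transverse shoulder pairs.  Angles in degrees, gamma dimensionless.
POSE_VARS <- c(
  "gamma",
  "theta_bd", "phi_bd", "psi_bd",
  "theta_ws", "phi_ws", "psi_ws",
  "theta_hp_l", "theta_kn_l", "theta_hp_r", "theta_kn_r",
  "theta_sh_l", "theta_el_l", "theta_sh_r", "theta_el_r",
  "phi_hp_l", "phi_hp_r",
  "phi_sh_l", "phi_sh_r",
  "psi_sh_l", "psi_sh_r"
)

#' Names of the pose optimisation variables
#'
#' The 21 variables fitted per frame: the global size factor `gamma`, the
#' three body orientation angles (`*_bd`), the three waist angles (`*_ws`),
#' and 14 limb joint angles.  `theta`, `phi` and `psi` denote rotations in
#' the sagittal, coronal and transverse anatomical planes respectively.
#'
#' @return character vector of length 21, in the canonical column order used
#'   by [write_angles()] and all fitted results.
#' @export
pose_variables <- function() POSE_VARS

# the full humanoid joint table: 26 rotational degrees of freedom.
# `optimized` marks the 17 joint angles fitted from data; the three body
# angles are fitted too but describe camera-relative orientation rather
# than a joint.  The remaining six (neck pair, transverse hips, sagittal
# ankles) are articulation points of the model held at zero during fitting.
humanoid_joint_table <- function() {
  tibble::tribble(
    ~variable,      ~plane,       ~side,    ~optimized, ~body,
    "theta_bd",     "sagittal",   "center", TRUE,  TRUE,
    "phi_bd",       "coronal",    "center", TRUE,  TRUE,
    "psi_bd",       "transverse", "center", TRUE,  TRUE,
    "theta_ws",     "sagittal",   "center", TRUE,  FALSE,
    "phi_ws",       "coronal",    "center", TRUE,  FALSE,
    "psi_ws",       "transverse", "center", TRUE,  FALSE,
    "theta_nk",     "sagittal",   "center", FALSE, FALSE,
    "phi_nk",       "coronal",    "center", FALSE, FALSE,
    "theta_hp_l",   "sagittal",   "left",   TRUE,  FALSE,
    "theta_hp_r",   "sagittal",   "right",  TRUE,  FALSE,
    "phi_hp_l",     "coronal",    "left",   TRUE,  FALSE,
    "phi_hp_r",     "coronal",    "right",  TRUE,  FALSE,
    "psi_hp_l",     "transverse", "left",   FALSE, FALSE,
    "psi_hp_r",     "transverse", "right",  FALSE, FALSE,
    "theta_kn_l",   "sagittal",   "left",   TRUE,  FALSE,
    "theta_kn_r",   "sagittal",   "right",  TRUE,  FALSE,
    "theta_an_l",   "sagittal",   "left",   FALSE, FALSE,
    "theta_an_r",   "sagittal",   "right",  FALSE, FALSE,
    "theta_sh_l",   "sagittal",   "left",   TRUE,  FALSE,
    "theta_sh_r",   "sagittal",   "right",  TRUE,  FALSE,
    "phi_sh_l",     "coronal",    "left",   TRUE,  FALSE,
    "phi_sh_r",     "coronal",    "right",  TRUE,  FALSE,
    "psi_sh_l",     "transverse", "left",   TRUE,  FALSE,
    "psi_sh_r",     "transverse", "right",  TRUE,  FALSE,
    "theta_el_l",   "sagittal",   "left",   TRUE,  FALSE,
    "theta_el_r",   "sagittal",   "right",  TRUE,  FALSE
  )
}

# default segment lengths as fractions of stature (standard anthropometric
# proportions); lumbar_offset places the 3-DoF waist joint at the sacrum,
# slightly above the hip line, which also makes trunk pitch observable from
# joint positions alone.
DEFAULT_PROPORTIONS <- c(
  hip_half_width      = 0.0955,
  shoulder_half_width = 0.1295,
  trunk               = 0.300,
  lumbar_offset       = 0.050,
  upper_arm           = 0.186,
  lower_arm           = 0.146,
  thigh               = 0.245,
  shin                = 0.246
)

default_angle_bounds <- function() {
  tibble::tribble(
    ~variable,    ~lo,   ~hi,
    "gamma",       0.5,   2.0,
    "theta_bd",  -90,    90,
    "phi_bd",    -90,    90,
    "psi_bd",   -180,   180,
    "theta_ws",  -45,    90,
    "phi_ws",    -45,    45,
    "psi_ws",    -60,    60,
    "theta_hp_l", -30,  120,
    "theta_kn_l",   0,  150,
    "theta_hp_r", -30,  120,
    "theta_kn_r",   0,  150,
    "theta_sh_l", -60,  180,
    "theta_el_l",   0,  150,
    "theta_sh_r", -60,  180,
    "theta_el_r",   0,  150,
    "phi_hp_l",   -45,   45,
    "phi_hp_r",   -45,   45,
    "phi_sh_l",   -90,   90,
    "phi_sh_r",   -90,   90,
    "psi_sh_l",   -90,   90,
    "psi_sh_r",   -90,   90
  )
}

#' Humanoid skeleton specification
#'
#' Builds the 26 degree-of-freedom humanoid model used for pose fitting:
#' a kinematic tree rooted at the pelvis centre (mid-hip), with a 3-DoF
#' waist joint just above the hip line, 3-DoF shoulders, and 1-DoF sagittal
#' knees and elbows.  All segment lengths are fractions of stature and are
#' multiplied by the global size factor `gamma` at evaluation time, so the
#' model can match a subject at any distance from the camera.
#'
#' @param stature_cm subject stature in centimetres.  The defaults used for
#'   link-length normalisation elsewhere are 175 (male) and 160 (female)
#'   population averages.
#' @param proportions named vector of segment lengths as fractions of
#'   stature; defaults to standard anthropometric proportions.  Must contain
#'   the same names as the default.
#' @param bounds data frame with columns `variable`, `lo`, `hi` giving
#'   per-variable limits in degrees (and the dimensionless range for
#'   `gamma`).  Defaults to physiological ranges.
#' @return object of class `humanoid_spec`: a list with the segment length
#'   table (metres at `gamma = 1`), the 26-row joint table, the bounds
#'   table, and the stature.
#' @examples
#' spec <- humanoid_spec()
#' nrow(spec$joints)       # 26 degrees of freedom
#' length(pose_variables())  # 21 fitted variables
#' @export
humanoid_spec <- function(stature_cm = 175,
                          proportions = DEFAULT_PROPORTIONS,
                          bounds = default_angle_bounds()) {
  check_number(stature_cm, "stature_cm", lower = 1)
  if (!all(names(DEFAULT_PROPORTIONS) %in% names(proportions))) {
    stop_pa("`proportions` must name all segments: ",
            paste(names(DEFAULT_PROPORTIONS), collapse = ", "))
  }
  if (any(proportions <= 0)) stop_pa("all segment proportions must be > 0")
  stopifnot(all(c("variable", "lo", "hi") %in% names(bounds)))
  if (!setequal(bounds$variable, POSE_VARS)) {
    stop_pa("`bounds` must cover exactly the 21 pose variables")
  }
  if (any(bounds$lo >= bounds$hi)) stop_pa("bounds must satisfy lo < hi")
  lengths_m <- proportions[names(DEFAULT_PROPORTIONS)] * stature_cm / 100
  structure(
    list(
      stature_cm = stature_cm,
      lengths = lengths_m,
      joints = humanoid_joint_table(),
      bounds = tibble::as_tibble(bounds[match(POSE_VARS, bounds$variable), ])
    ),
    class = "humanoid_spec"
  )
}

#' @export
print.humanoid_spec <- function(x, ...) {
  cat("<humanoid_spec>\n")
  cat(sprintf("  stature: %.0f cm, %d joint DoF (%d optimized + 3 body), %d pose variables\n",
              x$stature_cm, nrow(x$joints),
              sum(x$joints$optimized & !x$joints$body), length(POSE_VARS)))
  cat(sprintf("  segment lengths at gamma = 1 (m): %s\n",
              paste(sprintf("%s=%.3f", names(x$lengths), x$lengths),
                    collapse = ", ")))
  invisible(x)
}

#' Default pose vector
#'
#' The upright reference pose: all angles zero and `gamma = 1` (arms hanging
#' at the sides, legs straight, facing the camera).
#'
#' @return named numeric vector of length 21.
#' @export
reference_pose <- function() {
  p <- setNames(numeric(length(POSE_VARS)), POSE_VARS)
  p["gamma"] <- 1
  p
}

as_pose_vector <- function(pose) {
  if (is.data.frame(pose)) {
    if (nrow(pose) != 1L) stop_pa("pose data frame must have exactly one row")
    pose <- unlist(pose[intersect(names(pose), POSE_VARS)])
  }
  if (is.null(names(pose))) {
    if (length(pose) != length(POSE_VARS)) {
      stop_pa("unnamed pose vector must have length ", length(POSE_VARS))
    }
    names(pose) <- POSE_VARS
  }
  missing <- setdiff(POSE_VARS, names(pose))
  if (length(missing) > 0) {
    stop_pa("pose is missing variables: ", paste(missing, collapse = ", "))
  }
  pose[POSE_VARS]
}

check_pose_bounds <- function(pose, spec) {
  lo <- spec$bounds$lo
  hi <- spec$bounds$hi
  bad <- which(pose < lo - 1e-9 | pose > hi + 1e-9)
  if (length(bad) > 0) {
    stop_pa(sprintf("pose variable `%s` = %.4g outside bounds [%g, %g]",
                    POSE_VARS[bad[1]], pose[bad[1]], lo[bad[1]], hi[bad[1]]),
            class = "poseangle_bounds_error")
  }
  invisible(pose)
}

# elementary rotations; theta in radians.  Coordinate frame: +y up,
# +x toward the subject's anatomical left, +z toward the camera.
rot_x <- function(a) {
  c <- cos(a); s <- sin(a)
  matrix(c(1, 0, 0, 0, c, s, 0, -s, c), 3, 3)
}
rot_y <- function(a) {
  c <- cos(a); s <- sin(a)
  matrix(c(c, 0, -s, 0, 1, 0, s, 0, c), 3, 3)
}
rot_z <- function(a) {
  c <- cos(a); s <- sin(a)
  matrix(c(c, s, 0, -s, c, 0, 0, 0, 1), 3, 3)
}

# core forward kinematics on an unchecked numeric pose in canonical
# variable order (degrees).
# Returns a 14 x 3 matrix (12 canonical joints + pelvis/shoulder centres).
fk_eval <- function(pose, lengths) {
  d <- pi / 180
  g <- pose[1L]
  hw <- g * lengths[["hip_half_width"]]
  sw <- g * lengths[["shoulder_half_width"]]
  tr <- g * lengths[["trunk"]]
  lb <- g * lengths[["lumbar_offset"]]
  ua <- g * lengths[["upper_arm"]]
  la <- g * lengths[["lower_arm"]]
  th <- g * lengths[["thigh"]]
  sh <- g * lengths[["shin"]]

  # body orientation: transverse, then coronal, then sagittal pitch
  R0 <- rot_y(d * pose[4L]) %*%
        rot_z(d * pose[3L]) %*%
        rot_x(d * pose[2L])

  hip_l <- R0 %*% c(hw, 0, 0)
  hip_r <- R0 %*% c(-hw, 0, 0)

  leg <- function(hip, th_hp, ph_hp, th_kn) {
    # +theta_hp flexes the thigh forward (toward the camera)
    Rh <- R0 %*% rot_x(-d * th_hp) %*% rot_z(d * ph_hp)
    knee <- hip + Rh %*% c(0, -th, 0)
    Rk <- Rh %*% rot_x(d * th_kn)   # +theta_kn bends the shin backward
    ankle <- knee + Rk %*% c(0, -sh, 0)
    list(knee = knee, ankle = ankle)
  }
  ll <- leg(hip_l, pose[8L], pose[16L], pose[9L])
  lr <- leg(hip_r, pose[10L], pose[17L], pose[11L])

  # waist joint sits at the sacrum, lumbar_offset above the hip line
  waist <- R0 %*% c(0, lb, 0)
  Rw <- R0 %*% rot_x(d * pose[5L]) %*%   # +theta_ws leans forward
        rot_z(d * pose[6L]) %*%
        rot_y(d * pose[7L])
  shoulder_center <- waist + Rw %*% c(0, tr - lb, 0)
  sh_l <- shoulder_center + Rw %*% c(sw, 0, 0)
  sh_r <- shoulder_center - Rw %*% c(sw, 0, 0)

  arm <- function(shj, th_sh, ph_sh, ps_sh, th_el) {
    # +theta_sh raises the arm forward
    Rs <- Rw %*% rot_x(-d * th_sh) %*% rot_z(d * ph_sh) %*% rot_y(d * ps_sh)
    elbow <- shj + Rs %*% c(0, -ua, 0)
    Re <- Rs %*% rot_x(-d * th_el)  # +theta_el flexes the forearm forward
    wrist <- elbow + Re %*% c(0, -la, 0)
    list(elbow = elbow, wrist = wrist)
  }
  al <- arm(sh_l, pose[12L], pose[18L],
            pose[20L], pose[13L])
  ar <- arm(sh_r, pose[14L], pose[19L],
            pose[21L], pose[15L])

  out <- rbind(
    l_shoulder = as.vector(sh_l), r_shoulder = as.vector(sh_r),
    l_elbow = as.vector(al$elbow), r_elbow = as.vector(ar$elbow),
    l_wrist = as.vector(al$wrist), r_wrist = as.vector(ar$wrist),
    l_hip = as.vector(hip_l), r_hip = as.vector(hip_r),
    l_knee = as.vector(ll$knee), r_knee = as.vector(lr$knee),
    l_ankle = as.vector(ll$ankle), r_ankle = as.vector(lr$ankle),
    pelvis_center = c(0, 0, 0),
    shoulder_center = as.vector(shoulder_center)
  )
  colnames(out) <- c("x", "y", "z")
  out
}

#' Forward kinematics of the humanoid model
#'
#' Computes 3D joint positions (metres, pelvis-centred, +y up, +x toward the
#' subject's left, +z toward the camera) for a pose vector.  Joint rotations
#' compose sagittal, then coronal, then transverse as intrinsic rotations;
#' the body orientation is applied ahead of every chain.  All segment
#' lengths are scaled by `gamma`.  The six model DoF not in the pose vector
#' (neck pair, transverse hips, sagittal ankles) are held at zero.
#'
#' @param pose named numeric vector (or 1-row data frame) with the 21
#'   variables of [pose_variables()]; angles in degrees.
#' @param spec a [humanoid_spec()].
#' @param as_tibble if `TRUE` return a tibble with columns `joint`, `x`,
#'   `y`, `z`; otherwise a 14 x 3 matrix with joint rownames.
#' @param check if `TRUE` (default) error when a variable is outside its
#'   configured bounds.
#' @return joint positions for the 12 canonical joints plus
#'   `pelvis_center` and `shoulder_center`.
#' @examples
#' fk <- forward_kinematics(reference_pose(), humanoid_spec())
#' fk["l_wrist", ]  # hangs below the left shoulder
#' @export
forward_kinematics <- function(pose, spec = humanoid_spec(),
                               as_tibble = FALSE, check = TRUE) {
  pose <- as_pose_vector(pose)
  if (check) check_pose_bounds(pose, spec)
  m <- fk_eval(unname(pose), spec$lengths)
  if (!as_tibble) return(m)
  tibble::tibble(joint = rownames(m), x = m[, 1], y = m[, 2], z = m[, 3])
}

#' Mirror a pose left-to-right
#'
#' Swaps the left/right members of every joint-angle pair and negates the
#' coronal and transverse components of the body and waist (and of the
#' swapped pairs), so that the forward kinematics of the mirrored pose is
#' the x-negated forward kinematics of the original with left and right
#' joint labels exchanged.  Applying it twice is the identity.
#'
#' @param pose named pose vector (degrees).
#' @return mirrored pose vector.
#' @export
mirror_pose <- function(pose) {
  p <- as_pose_vector(pose)
  out <- p
  swap <- function(a, b) {
    tmp <- out[a]; out[a] <<- out[b]; out[b] <<- tmp
  }
  swap("theta_hp_l", "theta_hp_r")
  swap("theta_kn_l", "theta_kn_r")
  swap("theta_sh_l", "theta_sh_r")
  swap("theta_el_l", "theta_el_r")
  swap("phi_hp_l", "phi_hp_r")
  swap("phi_sh_l", "phi_sh_r")
  swap("psi_sh_l", "psi_sh_r")
  neg <- c("phi_bd", "psi_bd", "phi_ws", "psi_ws",
           "phi_hp_l", "phi_hp_r", "phi_sh_l", "phi_sh_r",
           "psi_sh_l", "psi_sh_r")
  out[neg] <- -out[neg]
  out
}
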
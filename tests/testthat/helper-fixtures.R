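# shared fixtures: all generated in code, no stored data

# a random in-bounds pose; gamma drawn near 1 unless full_box = TRUE
random_pose <- function(spec, full_box = FALSE) {
  b <- spec$bounds
  p <- stats::setNames(b$lo + stats::runif(nrow(b)) * (b$hi - b$lo),
                       pose_variables())
  if (!full_box) p["gamma"] <- stats::runif(1, 0.8, 1.2)
  p
}

# measured frame (12 x 3 matrix) from a pose
measured_from_pose <- function(pose, spec) {
  forward_kinematics(pose, spec)[canonical_joints(), ]
}

# a small detection tibble builder
det <- function(label, conf, x_min, y_min, x_max, y_max, frame = NULL) {
  out <- tibble::tibble(label = label, conf = conf, x_min = x_min,
                        y_min = y_min, x_max = x_max, y_max = y_max)
  if (!is.null(frame)) out <- dplyr::mutate(out, frame = frame, .before = 1)
  out
}

# independent IoU oracle: rasterise integer-coordinate boxes into unit
# cells and count (half-open convention)
iou_raster <- function(a, b) {
  cells <- function(bx) {
    if (bx[3] <= bx[1] || bx[4] <= bx[2]) return(character(0))
    xs <- seq(bx[1], bx[3] - 1)
    ys <- seq(bx[2], bx[4] - 1)
    as.vector(outer(xs, ys, paste, sep = ","))
  }
  ca <- cells(a); cb <- cells(b)
  inter <- length(intersect(ca, cb))
  uni <- length(union(ca, cb))
  if (uni == 0) 0 else inter / uni
}

# independent running-median oracle with shrinking edge windows
median_oracle <- function(v, window) {
  h <- (window - 1) / 2
  n <- length(v)
  vapply(seq_len(n), function(i) {
    k <- min(h, i - 1, n - i)
    w <- sort(v[(i - k):(i + k)])
    w[(length(w) + 1) / 2]
  }, numeric(1))
}

# corruption experiment shared by the property test and acceptance:
# an asymmetric arm/leg motion with injected partial switches and
# end-joint misdetections whose induced link-length jumps are all well
# above 3x the 10 cm/frame detection threshold.
outlier_experiment <- function(seed = 1, n_frames = 150) {
  script <- motion_script("arm_leg", duration = n_frames, fps = 30)
  clean <- generate_motion(script, humanoid_spec())
  # event windows sit at high-asymmetry phases of the 2 s (60-frame) cycle.
  # switches are partial (a subset of pairs) so they produce cross-body
  # links: swapping a full limb chain is a pure relabelling that leaves
  # every link length unchanged and is invisible to length screening.
  switches <- tibble::tibble(
    start = c(20L, 80L), end = c(23L, 83L),
    joints = list("shoulder", c("elbow", "wrist"))
  )
  mis <- tibble::tibble(
    joint = c("l_wrist", "r_ankle", "l_knee"),
    start = c(45L, 105L, 130L), end = c(47L, 108L, 132L),
    dx = c(0.45, 0, 0.4), dy = c(0, -0.45, 0.2), dz = c(0.1, 0.2, 0)
  )
  mis <- mis[mis$end <= n_frames, ]
  switches <- switches[switches$end <= n_frames, ]
  crp <- corrupt_trajectory(clean$trajectory, switches = switches,
                            misdetections = mis, jitter_sd = 0.002,
                            seed = seed)
  list(clean = clean, corrupted = crp, switches = switches, mis = mis)
}

# frame-level detection quality against a ground-truth mask
detection_quality <- function(mask, truth) {
  tp <- sum(mask & truth)
  list(recall = tp / sum(truth),
       precision = if (sum(mask) == 0) NA_real_ else tp / sum(mask))
}
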
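# link-length screening, outlier detection and repair

make_traj <- function(frames) {
  # frames: list of named joint -> c(x, y, z)
  rows <- lapply(frames, function(f) {
    m <- do.call(rbind, f)
    poseangle:::flatten_frame(m)
  })
  as_trajectory(tibble::as_tibble(do.call(rbind, rows)))
}

test_that("link lengths are Euclidean distances per frame, 10 links monitored", {
  expect_equal(nrow(link_set()), 10)
  expect_setequal(
    link_set()$link,
    c("shoulder", "pelvis", "l_upper_arm", "r_upper_arm", "l_lower_arm",
      "r_lower_arm", "l_thigh", "r_thigh", "l_shin", "r_shin")
  )
  # 3-4-5 triangle on one link, coincident endpoints on another
  spec <- humanoid_spec()
  traj <- generate_motion(motion_script("rowing", duration = 3), spec)$trajectory
  traj$l_shoulder_x[1] <- 0;   traj$l_shoulder_y[1] <- 0; traj$l_shoulder_z[1] <- 0
  traj$l_elbow_x[1] <- 0.3;    traj$l_elbow_y[1] <- 0;    traj$l_elbow_z[1] <- 0.4
  traj$l_knee_x[2] <- traj$l_hip_x[2]
  traj$l_knee_y[2] <- traj$l_hip_y[2]
  traj$l_knee_z[2] <- traj$l_hip_z[2]
  lens <- link_lengths(traj)
  expect_equal(lens$l_upper_arm[1], 0.5)
  expect_equal(lens$l_thigh[2], 0)

  # independent distance-formula oracle on a random frame
  withr::with_seed(2, {
    m <- matrix(rnorm(36), nrow = 12,
                dimnames = list(canonical_joints(), c("x", "y", "z")))
    traj1 <- make_traj(list(apply(m, 1, identity, simplify = FALSE)))
    lens1 <- link_lengths(traj1)
    ls <- link_set()
    for (i in seq_len(10)) {
      a <- m[ls$joint_a[i], ]; b <- m[ls$joint_b[i], ]
      oracle <- sqrt((a[1] - b[1])^2 + (a[2] - b[2])^2 + (a[3] - b[3])^2)
      expect_equal(lens1[[ls$link[i]]][1], unname(oracle), tolerance = 1e-12)
    }
  })
})

test_that("pixel lengths normalise to centimetres by stature over pixel height", {
  # 175 cm over 350 px: scale 0.5, so a 60 px link is 30 cm
  expect_equal(normalize_to_cm(60, 350, 175), 30)
  # scale invariance: doubling both leaves the result unchanged
  expect_equal(normalize_to_cm(120, 700, 175), 30)
  expect_error(normalize_to_cm(60, 0, 175), "> 0")
  expect_error(normalize_to_cm(60, -10, 175))
  # series form scales every link column but not the frame index
  spec <- humanoid_spec()
  lens <- link_lengths(generate_motion(motion_script("rowing", duration = 4),
                                       spec)$trajectory)
  out <- normalize_to_cm(lens, 350, 175)
  expect_equal(out$frame, lens$frame)
  expect_equal(out$shoulder, lens$shoulder / 2)
})

test_that("constant and linearly drifting series produce no outlier flags", {
  n <- 40
  base <- generate_motion(motion_script("rowing", duration = n,
                                        amplitude_scale = 0),
                          humanoid_spec())$trajectory
  lens <- link_lengths(base)
  lens[setdiff(names(lens), "frame")] <-
    lens[setdiff(names(lens), "frame")] * 100
  rep0 <- detect_outliers(lens, threshold = 10)
  expect_equal(sum(rep0$mask), 0)
  expect_equal(nrow(rep0$segments), 0)
  # drift of 0.5 cm/frame stays under a 10 cm threshold
  drift <- lens
  drift$l_thigh <- drift$l_thigh + 0.5 * seq_len(n)
  expect_equal(sum(detect_outliers(drift, threshold = 10)$mask), 0)
})

test_that("a single super-threshold jump is flagged on the offending frames", {
  n <- 30
  lens <- tibble::as_tibble(
    c(list(frame = 1:n),
      stats::setNames(rep(list(rep(50, n)), 10), link_set()$link))
  )
  # 30 cm jump on the left thigh from frames 12..14 (diff-scan oracle:
  # |diff| = 30 at transitions 11->12 and 14->15 only)
  lens$l_thigh[12:14] <- 80
  rep1 <- detect_outliers(lens, threshold = 10)
  expect_equal(which(rep1$mask), 12:14)
  expect_equal(nrow(rep1$segments), 1)
  expect_equal(rep1$segments$category, "misdetection")
  expect_equal(rep1$segments$links[[1]], "l_thigh")
})

test_that("long abnormal plateaus merge across the flag gap", {
  n <- 60
  lens <- tibble::as_tibble(
    c(list(frame = 1:n),
      stats::setNames(rep(list(rep(40, n)), 10), link_set()$link))
  )
  lens$r_lower_arm[20:35] <- 90   # 16-frame event, jumps only at entry/exit
  rep1 <- detect_outliers(lens, threshold = 10)
  expect_equal(which(rep1$mask), 20:35)
  expect_equal(nrow(rep1$segments), 1)
})

test_that("segments flagged on many links are categorised as switches", {
  n <- 30
  lens <- tibble::as_tibble(
    c(list(frame = 1:n),
      stats::setNames(rep(list(rep(40, n)), 10), link_set()$link))
  )
  for (lk in c("l_upper_arm", "r_upper_arm", "l_thigh", "r_thigh", "l_shin")) {
    lens[[lk]][10:12] <- 75
  }
  rep1 <- detect_outliers(lens, threshold = 10, switch_link_count = 4)
  expect_equal(rep1$segments$category, "switch")
  expect_setequal(rep1$segments$links[[1]],
                  c("l_upper_arm", "r_upper_arm", "l_thigh", "r_thigh", "l_shin"))
})

test_that("mean interpolation replaces a segment by the neighbour average", {
  # hand arithmetic: neighbours 1.0 and 3.0 bracket a 3-frame segment -> 2.0
  n <- 7
  cols <- poseangle:::coord_cols(canonical_joints())
  m <- matrix(1, nrow = n, ncol = length(cols),
              dimnames = list(NULL, cols))
  m[4:6, ] <- 99  # corrupted
  m[7, ] <- 3
  traj <- as_trajectory(tibble::as_tibble(m))
  fixed <- correct_segment(traj, 4, 6)
  expect_true(all(as.matrix(fixed[4:6, cols]) == 2))
  expect_true(all(as.matrix(fixed[c(1:3, 7), cols]) ==
                    as.matrix(traj[c(1:3, 7), cols])))

  # zero-length (empty) segment is the identity
  expect_equal(correct_segment(traj, 5, 4), traj)

  # segment at the sequence start copies the post-segment neighbour
  fixed0 <- correct_segment(traj, 1, 2)
  expect_true(all(as.matrix(fixed0[1:2, cols]) ==
                    as.matrix(traj[3, cols])[rep(1, 2), ]))

  # selective joint repair leaves other joints alone
  sel <- correct_segment(traj, 4, 6, joints = c("l_wrist"))
  expect_true(all(as.matrix(sel[4:6, c("l_wrist_x", "l_wrist_y", "l_wrist_z")]) == 2))
  expect_true(all(as.matrix(sel[4:6, "l_knee_x"]) == 99))
})

test_that("median smoothing matches a sort-based oracle and keeps length", {
  withr::with_seed(8, {
    n <- 41
    v <- cumsum(rnorm(n))
    cols <- poseangle:::coord_cols(canonical_joints())
    m <- matrix(rnorm(n * length(cols)), nrow = n,
                dimnames = list(NULL, cols))
    m[, "l_wrist_x"] <- v
    traj <- as_trajectory(tibble::as_tibble(m))
    for (w in c(3, 5, 9)) {
      sm <- median_smooth(traj, w)
      expect_equal(nrow(sm), n)
      expect_equal(sm$l_wrist_x, median_oracle(v, w))
      expect_equal(sm$r_knee_z, median_oracle(m[, "r_knee_z"], w))
    }
  })
  spec <- humanoid_spec()
  traj <- generate_motion(motion_script("rowing", duration = 10), spec)$trajectory
  expect_error(median_smooth(traj, 4), "odd")
  # constant series unchanged
  const <- generate_motion(motion_script("rowing", duration = 10,
                                         amplitude_scale = 0), spec)$trajectory
  expect_equal(median_smooth(const, 5)$l_wrist_y, const$l_wrist_y)
  # single-frame spike in a constant series is removed
  spiked <- const
  spiked$r_elbow_x[5] <- spiked$r_elbow_x[5] + 1
  expect_equal(median_smooth(spiked, 5)$r_elbow_x, const$r_elbow_x)
})

test_that("clean motion passes through correction with an empty mask", {
  spec <- humanoid_spec()
  clean <- generate_motion(motion_script("rowing", duration = 60), spec)
  res <- correct_trajectory(clean$trajectory)
  expect_equal(sum(res$report$mask), 0)
  expect_equal(
    as.matrix(res$trajectory[poseangle:::coord_cols(canonical_joints())]),
    as.matrix(median_smooth(clean$trajectory, 5)[
      poseangle:::coord_cols(canonical_joints())])
  )
})

test_that("injected corruptions are flagged and repaired below threshold", {
  exp1 <- outlier_experiment(seed = 21)
  res <- correct_trajectory(exp1$corrupted$trajectory)
  truth <- exp1$corrupted$truth_mask
  q <- detection_quality(res$report$mask, truth)
  expect_gte(q$recall, 0.9)
  expect_gte(q$precision, 0.8)
  # repaired trajectory has no remaining super-threshold length jumps
  lens_after <- link_lengths(res$trajectory)
  d <- as.matrix(link_length_diffs(lens_after)[link_set()$link]) * 100
  expect_lt(max(abs(d)), 10)
  # wrist teleport is caught through the lower-arm link
  wrist_seg <- res$report$segments[
    vapply(res$report$segments$links, function(l) "l_lower_arm" %in% l,
           logical(1)), ]
  expect_gte(nrow(wrist_seg), 1)
})

test_that("non-flagged frames are modified only by the median filter", {
  exp1 <- outlier_experiment(seed = 22)
  res <- correct_trajectory(exp1$corrupted$trajectory)
  med_only <- median_smooth(exp1$corrupted$trajectory, 5)
  clean_frames <- which(!res$report$mask)
  # away from segment edges the median window sees no repaired frame,
  # so correction and plain smoothing agree exactly
  buffered <- clean_frames[vapply(clean_frames, function(f) {
    all(abs(f - which(res$report$mask)) > 2)
  }, logical(1))]
  cols <- poseangle:::coord_cols(canonical_joints())
  expect_equal(as.matrix(res$trajectory[buffered, cols]),
               as.matrix(med_only[buffered, cols]))
})

test_that("correction is idempotent on already-corrected data", {
  exp1 <- outlier_experiment(seed = 23)
  once <- correct_trajectory(exp1$corrupted$trajectory)
  twice <- correct_trajectory(once$trajectory)
  expect_equal(sum(twice$report$mask), 0)
  cols <- poseangle:::coord_cols(canonical_joints())
  # second pass applies only the median filter to already-smooth data
  dev <- max(abs(as.matrix(twice$trajectory[cols]) -
                   as.matrix(once$trajectory[cols])))
  amp <- diff(range(once$trajectory$l_wrist_z))
  expect_lt(dev, 0.02 * amp)
})

test_that("pixel-unit trajectories are screened after stature normalisation", {
  spec <- humanoid_spec()
  clean <- generate_motion(motion_script("arm_leg", duration = 40), spec)
  px <- clean$trajectory
  cols <- grep("_[xyz]$", names(px), value = TRUE)
  px[cols] <- px[cols] * 200  # fake 200 px/m camera scale
  attr(px, "units") <- "pixels"
  px$l_wrist_x[15:16] <- px$l_wrist_x[15:16] + 100  # 0.5 m teleport
  # subject pixel height approximately stature * 200 px
  res <- correct_trajectory(px, subject_pixel_height = 1.75 * 200,
                            stature_cm = 175)
  expect_true(any(res$report$mask[15:16]))
  expect_error(correct_trajectory(px), "subject_pixel_height")
})
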
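calib_trials_with_mounts <- function(seed, mounts = NULL,
                                     max_mount_deg = 10,
                                     noise = sensor_noise_spec()) {
  noise$mount_rotation <- mounts
  noise$max_mount_deg <- max_mount_deg
  ses <- simulate_session(seed = seed, noise = noise, phases = 1)
  list(trials = lumbarload:::session_trials(ses,
                                            kind = "segment_calibration"),
       mounts = ses$sim_truth$mount_rotation)
}

test_that("an exactly aligned sensor calibrates to identity", {
  mounts <- lapply(stats::setNames(immu_sites(), immu_sites()),
                   function(s) c(0, 0, 0))
  cw <- calib_trials_with_mounts(2, mounts = mounts)
  cal <- estimate_segment_frames(cw$trials)
  for (site in immu_sites()) {
    expect_lt(quat_angle_deg(cal$rotations[[site]], c(1, 0, 0, 0)), 0.5)
    expect_lt(cal$residual_deg[site], 0.5)
  }
})

test_that("mount rotations up to 20 degrees are recovered within 2 degrees", {
  worst <- 0
  for (seed in 1:20) {
    cw <- calib_trials_with_mounts(seed, max_mount_deg = 20)
    cal <- estimate_segment_frames(cw$trials)
    for (site in immu_sites()) {
      mr <- cw$mounts[[site]]
      ang <- sqrt(sum(mr^2))
      q_true <- if (ang > 0) quat_from_axis_angle(mr / ang, ang)
                else c(1, 0, 0, 0)
      err <- quat_angle_deg(cal$rotations[[site]],
                            quat_conjugate(q_true))
      worst <- max(worst, err)
    }
  }
  expect_lt(worst, 2)
})

test_that("a longitudinal-rotation trial cannot replace the sagittal cue", {
  cw <- calib_trials_with_mounts(3)
  trials <- cw$trials
  movements <- vapply(trials, function(tr) tr$movement, character(1))
  rot <- trials[[which(movements == "rotation")]]
  rot$movement <- "bending"   # mislabel: pure twist offered as bending
  trials <- c(trials[movements %in% "neutral"], list(rot))
  expect_error(estimate_segment_frames(trials, sites = "sternum"),
               "degenerate")
})

test_that("missing calibration trials are reported with the site name", {
  cw <- calib_trials_with_mounts(3)
  movements <- vapply(cw$trials, function(tr) tr$movement, character(1))
  expect_error(
    estimate_segment_frames(cw$trials[movements != "neutral"]),
    "neutral")
  expect_error(
    estimate_segment_frames(cw$trials[movements != "bending"],
                            sites = "sacrum"),
    "sacrum.*bending")
})

test_that("re-expression preserves vector norms and inverts cleanly", {
  cw <- calib_trials_with_mounts(4)
  cal <- estimate_segment_frames(cw$trials)
  s <- cw$trials[[2]]$immu$sternum
  s2 <- apply_calibration(s, cal)
  expect_equal(sqrt(rowSums(s2$angvel^2)), sqrt(rowSums(s$angvel^2)),
               tolerance = 1e-9)
  expect_equal(sqrt(rowSums(s2$linacc^2)), sqrt(rowSums(s$linacc^2)),
               tolerance = 1e-9)
  # applying the inverse calibration returns the original stream
  inv <- cal
  inv$rotations <- lapply(cal$rotations,
                          function(q) as.numeric(quat_conjugate(q)))
  s3 <- apply_calibration(s2, inv)
  expect_equal(s3$angvel, s$angvel, tolerance = 1e-9)
  expect_equal(s3$linacc, s$linacc, tolerance = 1e-9)
  expect_lt(max(quat_angle_deg(s3$quat, s$quat)), 1e-4)
})

test_that("identity calibration leaves a stream unchanged", {
  cw <- calib_trials_with_mounts(2)
  cal <- estimate_segment_frames(cw$trials)
  cal$rotations$sternum <- c(1, 0, 0, 0)
  s <- cw$trials[[2]]$immu$sternum
  s2 <- apply_calibration(s, cal)
  expect_equal(s2$angvel, s$angvel, tolerance = 1e-12)
  expect_equal(s2$quat, s$quat, tolerance = 1e-12)
})
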
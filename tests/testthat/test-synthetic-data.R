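test_that("neutral stance yields identity poses and gravity-only sensors", {
  kin <- simulate_kinematics(motion_spec("neutral", 0, period = 3),
                             default_subject())
  truth <- simulate_truth_moment(kin)
  for (seg in kin$segments) {
    expect_equal(seg$quat[, 1], rep(1, length(kin$t)))
    expect_equal(max(abs(seg$omega)), 0)
  }
  # noise-free, identity-mount sensors: specific force is -g in the casing
  # frame (accelerometer reads 1 g upward at rest)
  sens <- simulate_sensors(kin, truth,
                           sensor_noise_spec(gyro_sd = 0, acc_sd = 0,
                                             emg_noise_sd = 0),
                           seed = 1)
  for (s in sens$immu) {
    expect_equal(unique(round(s$linacc[, 3], 9)), -9.81)
    expect_equal(max(abs(s$linacc[, 1:2])), 0)
    expect_equal(max(abs(s$angvel)), 0)
  }
})

test_that("bending attains its specified peak angle exactly on the grid", {
  kin <- simulate_kinematics(motion_spec("bending", pi / 2,
                                         repetitions = 1),
                             default_subject())
  ang <- 2 * acos(pmin(1, abs(kin$segments$trunk$quat[, 1])))
  expect_equal(max(ang), pi / 2, tolerance = 1e-6 / (pi / 2))
})

test_that("emitted angular velocity matches finite differences of the quaternion track", {
  kin <- simulate_kinematics(motion_spec("bending", pi / 2,
                                         repetitions = 2),
                             default_subject())
  q <- kin$segments$trunk$quat
  n <- nrow(q)
  # omega (body) from q_dot: omega = 2 * Im(q* x dq/dt)
  dq <- (q[3:n, ] - q[1:(n - 2), ]) / (2 * 0.02)
  om_fd <- 2 * quat_multiply(quat_conjugate(q[2:(n - 1), ]), dq)[, 2:4]
  om <- lumbarload:::state_angvel_body(kin$segments$trunk)[2:(n - 1), ]
  # the central-difference oracle is valid where the profile is smooth;
  # movement onset and end carry an acceleration step
  tt <- kin$t[2:(n - 1)]
  smooth <- abs(tt - 1.5) > 0.1 & abs(tt - 9.5) > 0.1
  expect_lt(max(abs(om_fd - om)[smooth]), 1e-3)
})

test_that("segment accelerations are consistent with twice-differentiated positions", {
  kin <- simulate_kinematics(motion_spec("bending", pi / 3,
                                         repetitions = 2),
                             default_subject())
  st <- kin$segments$upper_arm_L   # hanging arm: origin follows shoulder
  n <- length(kin$t)
  p <- st$p0
  a_fd <- (p[3:n, ] - 2 * p[2:(n - 1), ] + p[1:(n - 2), ]) / 0.02^2
  tt <- kin$t[2:(n - 1)]
  smooth <- abs(tt - 1.5) > 0.1 & abs(tt - 9.5) > 0.1
  expect_lt(max(abs(a_fd - st$a0[2:(n - 1), ])[smooth]), 0.05)
})

test_that("identity-mount noise-free sensors replicate segment kinematics", {
  kin <- simulate_kinematics(motion_spec("bending", pi / 3,
                                         repetitions = 1),
                             default_subject())
  truth <- simulate_truth_moment(kin)
  sens <- simulate_sensors(kin, truth,
                           sensor_noise_spec(gyro_sd = 0, acc_sd = 0),
                           seed = 1)
  expect_identical(sens$immu$sternum$quat, kin$segments$trunk$quat)
  expect_equal(sens$immu$sternum$angvel,
               lumbarload:::state_angvel_body(kin$segments$trunk),
               tolerance = 1e-12)
})

test_that("EMG envelope sits at the noise floor when the moment is zero", {
  kin <- simulate_kinematics(motion_spec("neutral", 0, period = 4),
                             default_subject())
  truth <- net_moment_series(kin$t, matrix(0, length(kin$t), 3))
  ns <- sensor_noise_spec()
  sens <- simulate_sensors(kin, truth, ns, seed = 2)
  env <- emg_amplitude(sens$emg[[1]])
  expect_lte(mean(env$envelope), 3 * ns$emg_noise_sd)
})

test_that("load contribution to extensor envelopes is linear in load mass", {
  subj <- default_subject()
  kin <- simulate_kinematics(motion_spec("hold_posture", pi / 4,
                                         period = 6),
                             subj)
  env_for <- function(lm) {
    truth <- simulate_truth_moment(kin, load_mass = lm)
    lumbarload:::emg_clean_envelopes(truth, gain = 0.05, crosstalk = 0)
  }
  idx <- which(kin$t > 5 & kin$t < 8)   # mid-hold
  e0 <- colMeans(env_for(0)[idx, ])
  e5 <- colMeans(env_for(5)[idx, ])
  e10 <- colMeans(env_for(10)[idx, ])
  expect_equal(e10 - e0, 2 * (e5 - e0), tolerance = 1e-6)
})

test_that("the default scenario encodes the stated study conditions", {
  sp <- scenario_parameters()
  expect_equal(sp$borg$mean, c(0.9, 3.8, 6.0))
  expect_equal(sp$borg$sd, c(0.8, 1.6, 2.0))
  expect_equal(sp$ranks$light, 1L)
  expect_equal(sp$ranks$heavy_dynamic, 5L)
  set.seed(11)
  draws <- replicate(2000, lumbarload:::rborg(3.8, 1.6))
  expect_true(all(draws >= 0 & draws <= 10))
  expect_equal(mean(draws), 3.8, tolerance = 0.05)
  expect_equal(sd(draws), 1.6, tolerance = 0.1)
})

test_that("the default session is deterministic and well-formed", {
  s1 <- simulate_session(seed = 7, phases = 3)
  s2 <- simulate_session(seed = 7, phases = 3)
  expect_equal(s1, s2, tolerance = 0)
  labs <- vapply(s1$trials, function(tr) tr$task_label, character(1))
  expect_setequal(labs, c("light", "static", "dynamic"))
  borg <- vapply(s1$trials, function(tr) tr$borg, numeric(1))
  expect_true(all(borg >= 0 & borg <= 10))
})

test_that("the static task's ground-truth magnitude varies less than the dynamic task's", {
  ses <- sim_session_cached(seed = 1, phases = 1:3)
  v <- function(id) stats::sd(lumbarload:::session_trial(ses, id)$truth_moment$norm)
  expect_lt(v("task_static"), v("task_dynamic"))
})

test_that("static ground truth equals the closed-form gravitational sum", {
  subj <- default_subject()
  kin <- simulate_kinematics(motion_spec("hold_posture", pi / 2,
                                         period = 6, load_mass = 10),
                             subj)
  truth <- simulate_truth_moment(kin)
  idx <- which(kin$t > 5.5 & kin$t < 7.5)
  oracle <- static_gravity_oracle(subj, pi / 2, load_mass = 10)
  expect_equal(colMeans(truth$M[idx, ]), oracle, tolerance = 1e-6,
               ignore_attr = TRUE)
  # adding 10 kg raises the flexion moment by m g d of the load point
  truth0 <- simulate_truth_moment(kin, load_mass = 0)
  d_horiz <- 0.300 * subj$height   # load hangs below the shoulder line
  expect_equal(mean(truth$M[idx, 2] - truth0$M[idx, 2]),
               10 * 9.81 * d_horiz, tolerance = 0.1 / 50)
})
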
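test_that("body-model scaling is linear and mass-consistent", {
  subj <- subject_info("m", 1.85, 93)
  bm <- scale_body_model(subj)
  expect_equal(sum(bm$mass), 0.678 * 93, tolerance = 0.5 / (0.678 * 93))
  bm2 <- scale_body_model(subject_info("m2", 1.85, 186))
  expect_equal(bm2$mass, 2 * bm$mass)
  expect_error(subject_info("bad", 0, 93), "height")
})

# noise-free segment-frame streams for a static flexed posture, built
# directly (not via the simulator) so the LSM is exercised on its own
static_streams <- function(subject, pitch, n = 400) {
  kin <- simulate_kinematics(motion_spec("hold_posture", pitch,
                                         period = n * 0.02, lead_in = 0,
                                         tail = 0),
                             subject)
  streams <- list()
  geom <- lumbarload:::site_geometry(kin$body_model)
  g <- matrix(rep(c(0, 0, 9.81), each = length(kin$t)), ncol = 3)
  for (site in immu_sites()) {
    st <- kin$segments[[geom[[site]]$segment]]
    pk <- lumbarload:::point_kinematics(st, geom[[site]]$r, a0 = st$a0)
    f_body <- quat_rotate(quat_conjugate(st$quat), pk$a - g)
    streams[[site]] <- immu_stream(site, kin$t, st$quat,
                                   lumbarload:::state_angvel_body(st),
                                   f_body)
  }
  list(streams = streams, kin = kin)
}

test_that("upright static stance gives a near-zero net moment", {
  ss <- static_streams(subject_info("m", 1.85, 93), 0)
  nm <- lsm_net_moment(ss$streams, ss$kin$body_model, load_spec(0))
  expect_lt(sqrt(sum(colMeans(nm$M)^2)), 5)
})

test_that("static flexion matches the independent gravitational oracle to 1e-6 Nm", {
  subj <- subject_info("m", 1.85, 93)
  for (pitch in c(pi / 6, pi / 2)) {
    ss <- static_streams(subj, pitch)
    nm <- lsm_net_moment(ss$streams, ss$kin$body_model, load_spec(0))
    idx <- which(ss$kin$t > 4 & ss$kin$t < 5)   # inside the hold
    oracle <- static_gravity_oracle(subj, pitch)
    expect_lt(max(abs(sweep(nm$M[idx, ], 2, oracle))), 1e-6)
  }
})

test_that("a known handheld load raises the flexion moment by m g d", {
  subj <- subject_info("m", 1.85, 93)
  ss <- static_streams(subj, pi / 2)
  idx <- which(ss$kin$t > 4 & ss$kin$t < 5)
  m0 <- lsm_net_moment(ss$streams, ss$kin$body_model, load_spec(0))
  m10 <- lsm_net_moment(ss$streams, ss$kin$body_model,
                        load_spec(10, position = c(0.10, 0, 0)))
  d <- 0.300 * subj$height   # horizontal distance of the hanging load
  expect_equal(mean(m10$M[idx, 2] - m0$M[idx, 2]), 10 * 9.81 * d,
               tolerance = 0.1 / (10 * 9.81 * d))
})

test_that("moment differences are proportional to load-mass differences", {
  subj <- subject_info("m", 1.80, 80)
  ss <- static_streams(subj, pi / 4)
  m <- lapply(c(0, 4, 8), function(l)
    lsm_net_moment(ss$streams, ss$kin$body_model, load_spec(l))$M)
  expect_equal(m[[3]] - m[[1]], 2 * (m[[2]] - m[[1]]), tolerance = 1e-9)
})

test_that("a missing segment stream is reported by segment name", {
  ss <- static_streams(subject_info("m", 1.85, 93), pi / 6)
  s <- ss$streams
  s$upper_arm_L <- NULL
  expect_error(lsm_net_moment(s, ss$kin$body_model), "upper_arm_L")
})

test_that("the moment norm is invariant under rotation of the components", {
  set.seed(13)
  M <- matrix(rnorm(300), 100, 3)
  nm <- net_moment_series((0:99) * 0.02, M)
  for (i in 1:5) {
    q <- quat_normalize(rnorm(4))
    nm2 <- net_moment_series(nm$t, quat_rotate(q, M))
    expect_equal(nm2$norm, nm$norm, tolerance = 1e-9)
  }
})
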
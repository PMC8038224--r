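# Forward simulator: segment kinematics, ground-truth L5/S1 moments and
# synthetic sensor signals with the statistical structure the estimation
# method assumes.
#
# Motions are single-axis raised-cosine angle profiles (smooth start/stop,
# C^2), rooted at a stationary L5/S1 point.  The pelvis follows the trunk at
# a fixed lumbopelvic ratio; arms either hang vertically (bending,
# lateroflexion, lifting), follow the trunk rigidly (axial rotation, load
# close to the body) or move about the shoulders (shoulder calibration
# movements).

PELVIS_RATIO <- 0.4   # pelvis rotation as a fraction of trunk rotation

#' Motion specification for the simulator
#'
#' @param movement one of "bending", "lateroflexion", "rotation",
#'   "shoulder_flexion", "shoulder_abduction", "neutral", "lift_cycle",
#'   "hold_posture".
#' @param peak_angle peak angle in rad, in [0, pi/2].
#' @param period seconds per repetition (> 0.2 s).
#' @param repetitions number of repetitions (>= 1); for "hold_posture" the
#'   hold duration in seconds is `period`.
#' @param load_mass handheld load, kg.
#' @param load_offset load position relative to mid-hands, m, trunk frame.
#' @param lead_in,tail quiet neutral standing before/after the movement, s.
#' @return object of class `motion_spec`.
#' @export
motion_spec <- function(movement, peak_angle = pi / 4, period = 4,
                        repetitions = 1L, load_mass = 0,
                        load_offset = c(0.10, 0, 0),
                        lead_in = 1.5, tail = 1) {
  movement <- match.arg(movement,
                        c("bending", "lateroflexion", "rotation",
                          "shoulder_flexion", "shoulder_abduction",
                          "neutral", "lift_cycle", "hold_posture"))
  if (peak_angle < 0 || peak_angle > pi / 2 + 1e-12)
    stop("peak_angle must lie in [0, pi/2]")
  if (period <= 0.2) stop("period must exceed 0.2 s")
  if (repetitions < 1) stop("repetitions must be >= 1")
  structure(list(movement = movement, peak_angle = peak_angle,
                 period = period, repetitions = as.integer(repetitions),
                 load_mass = load_mass, load_offset = as.numeric(load_offset),
                 lead_in = lead_in, tail = tail),
            class = "motion_spec")
}

#' Sensor noise and imperfection specification
#'
#' Defaults emulate consumer-grade inertial sensors (gyro noise 0.01 rad/s,
#' accelerometer noise 0.05 m/s^2), sensor mounting misalignments of up to
#' 10 degrees, and surface EMG with an amplitude SNR of about 10.
#'
#' @param gyro_sd gyroscope white-noise SD, rad/s.
#' @param acc_sd accelerometer white-noise SD, m/s^2.
#' @param mount_rotation either `NULL` (random per-site mountings up to
#'   `max_mount_deg`, drawn from the session seed) or a named list of
#'   axis-angle 3-vectors (axis * angle, rad) per sensor site.
#' @param max_mount_deg upper bound for randomly drawn mounting
#'   misalignment angles, degrees (<= 30).
#' @param emg_gain EMG envelope gain, arbitrary units per Nm.
#' @param emg_noise_sd additive raw EMG noise SD, units.
#' @param emg_crosstalk bilateral cross-talk fraction in [0, 0.3].
#' @param tap_offset EMG clock offset relative to the inertial clock, s: an
#'   event at inertial time t carries EMG timestamp t + tap_offset.
#' @param emg_rate raw EMG sampling rate, Hz (>= 500).
#' @return object of class `sensor_noise_spec`.
#' @export
sensor_noise_spec <- function(gyro_sd = 0.01, acc_sd = 0.05,
                              mount_rotation = NULL, max_mount_deg = 10,
                              emg_gain = 0.05, emg_noise_sd = 0.25,
                              emg_crosstalk = 0.05, tap_offset = 0,
                              emg_rate = 1000) {
  if (any(c(gyro_sd, acc_sd, emg_noise_sd) < 0))
    stop("noise SDs must be nonnegative")
  if (emg_crosstalk < 0 || emg_crosstalk > 0.3)
    stop("emg_crosstalk must lie in [0, 0.3]")
  if (max_mount_deg > 30) stop("mounting misalignment must be <= 30 degrees")
  if (!is.null(mount_rotation)) {
    for (v in mount_rotation)
      if (sqrt(sum(v^2)) > 30 * pi / 180 + 1e-9)
        stop("mounting misalignment must be <= 30 degrees")
  }
  structure(list(gyro_sd = gyro_sd, acc_sd = acc_sd,
                 mount_rotation = mount_rotation,
                 max_mount_deg = max_mount_deg, emg_gain = emg_gain,
                 emg_noise_sd = emg_noise_sd, emg_crosstalk = emg_crosstalk,
                 tap_offset = tap_offset, emg_rate = emg_rate),
            class = "sensor_noise_spec")
}

# ---- angle profiles ---------------------------------------------------------
# each returns list(theta, dtheta, ddtheta) over the time vector t (s),
# analytic derivatives

profile_zero <- function(t) {
  z <- numeric(length(t))
  list(theta = z, dtheta = z, ddtheta = z)
}

# raised-cosine repetitions: theta = A/2 (1 - cos(2 pi u/T)) within each rep
profile_reps <- function(t, t0, reps, period, peak) {
  th <- dth <- ddth <- numeric(length(t))
  u <- t - t0
  active <- u >= 0 & u < reps * period
  ua <- u[active] %% period
  w <- 2 * pi / period
  th[active] <- peak / 2 * (1 - cos(w * ua))
  dth[active] <- peak / 2 * w * sin(w * ua)
  ddth[active] <- peak / 2 * w^2 * cos(w * ua)
  list(theta = th, dtheta = dth, ddtheta = ddth)
}

# ramp up (half raised cosine), hold, ramp down
profile_hold <- function(t, t0, ramp, hold, peak) {
  th <- dth <- ddth <- numeric(length(t))
  u <- t - t0
  w <- pi / ramp
  up <- u >= 0 & u < ramp
  th[up] <- peak / 2 * (1 - cos(w * u[up]))
  dth[up] <- peak / 2 * w * sin(w * u[up])
  ddth[up] <- peak / 2 * w^2 * cos(w * u[up])
  mid <- u >= ramp & u < ramp + hold
  th[mid] <- peak
  dn <- u >= ramp + hold & u < 2 * ramp + hold
  ud <- u[dn] - ramp - hold
  th[dn] <- peak / 2 * (1 + cos(w * ud))
  dth[dn] <- -peak / 2 * w * sin(w * ud)
  ddth[dn] <- -peak / 2 * w^2 * cos(w * ud)
  list(theta = th, dtheta = dth, ddtheta = ddth)
}

# kinematic state of a segment rotating about a fixed global axis through a
# fixed root point: orientation, global angular velocity/acceleration
axis_state <- function(axis, prof) {
  axis <- axis / sqrt(sum(axis^2))
  list(quat = quat_from_axis_angle(axis, prof$theta),
       omega = outer(prof$dtheta, axis),
       alpha = outer(prof$ddtheta, axis))
}

identity_state <- function(n) {
  list(quat = cbind(1, matrix(0, n, 3)),
       omega = matrix(0, n, 3), alpha = matrix(0, n, 3))
}

# acceleration of a point fixed in a rotating segment: a = a0 + alpha x r +
# omega x (omega x r), r the global lever arm from the segment origin
point_kinematics <- function(state, r_body, p0 = NULL, a0 = NULL) {
  r <- quat_rotate(state$quat, r_body)
  p <- if (is.null(p0)) r else p0 + r
  a <- cross3(state$alpha, r) + cross3(state$omega, cross3(state$omega, r))
  if (!is.null(a0)) a <- a + a0
  list(p = p, a = a)
}

#' Simulate noise-free segment kinematics for one movement
#'
#' Generates pose trajectories (orientation, angular velocity, linear
#' acceleration) at 50 Hz for the pelvis, trunk and both arms performing the
#' requested movement, rooted at a stationary L5/S1 point.  Angular
#' velocities are the analytic derivatives of the orientation tracks.
#'
#' @param spec a [motion_spec()].
#' @param subject a [subject_info()].
#' @param seed unused (the kinematic model is deterministic); accepted so
#'   all simulator entry points share a signature.
#' @return object of class `segment_kinematics`: `t`, per-segment states
#'   (quat, global omega/alpha, origin position/acceleration), the scaled
#'   `body_model`, and the generating `spec`.
#' @export
simulate_kinematics <- function(spec, subject, seed = NULL) {
  stopifnot(inherits(spec, "motion_spec"), inherits(subject, "subject_info"))
  bm <- scale_body_model(subject)
  move_dur <- switch(spec$movement,
    neutral = spec$period,
    hold_posture = 2 * 2 + spec$period,   # 2 s ramps around the hold
    spec$repetitions * spec$period)
  dur <- spec$lead_in + move_dur + spec$tail
  n <- round(dur / SAMPLE_DT)
  t <- (seq_len(n) - 1L) * SAMPLE_DT
  t0 <- spec$lead_in

  prof <- switch(spec$movement,
    neutral = profile_zero(t),
    hold_posture = profile_hold(t, t0, ramp = 2, hold = spec$period,
                                peak = spec$peak_angle),
    profile_reps(t, t0, spec$repetitions, spec$period, spec$peak_angle))

  # trunk/pelvis rotation axis per movement (global frame, x anterior,
  # y right, z down): forward flexion is a rotation about -y, left
  # lateroflexion about -x, left axial rotation about -z
  trunk_axis <- switch(spec$movement,
    bending = , lift_cycle = , hold_posture = c(0, -1, 0),
    lateroflexion = c(-1, 0, 0),
    rotation = c(0, 0, -1),
    NULL)

  if (!is.null(trunk_axis)) {
    trunk <- axis_state(trunk_axis, prof)
    pelvis <- axis_state(trunk_axis, lapply(prof, `*`, PELVIS_RATIO))
  } else {
    trunk <- identity_state(n)
    pelvis <- identity_state(n)
  }

  arm_mode <- switch(spec$movement,
    rotation = "follow",
    shoulder_flexion = "shoulder",
    shoulder_abduction = "shoulder",
    "hang")
  arms <- list()
  for (side in c("L", "R")) {
    if (arm_mode == "follow") {
      arms[[side]] <- trunk
    } else if (arm_mode == "hang" || spec$movement == "neutral") {
      arms[[side]] <- identity_state(n)
    } else {
      axis <- if (spec$movement == "shoulder_flexion") c(0, -1, 0)
              else if (side == "L") c(1, 0, 0) else c(-1, 0, 0)
      arms[[side]] <- axis_state(axis, prof)
    }
  }

  tr <- body_segment(bm, "trunk")
  wsh <- attr(bm, "shoulder_halfwidth")
  zero3 <- matrix(0, n, 3)
  segments <- list(
    pelvis = c(pelvis, list(p0 = zero3, a0 = zero3)),
    trunk = c(trunk, list(p0 = zero3, a0 = zero3))
  )
  for (side in c("L", "R")) {
    r_sh <- c(0, if (side == "L") -wsh else wsh, -tr$length)
    sh <- point_kinematics(trunk, r_sh)
    ua_name <- paste0("upper_arm_", side)
    la_name <- paste0("lower_arm_", side)
    ua <- body_segment(bm, ua_name)
    segments[[ua_name]] <- c(arms[[side]], list(p0 = sh$p, a0 = sh$a))
    el <- point_kinematics(arms[[side]], c(0, 0, ua$length),
                           p0 = sh$p, a0 = sh$a)
    segments[[la_name]] <- c(arms[[side]], list(p0 = el$p, a0 = el$a))
  }

  structure(list(t = t, segments = segments, body_model = bm,
                 subject = subject, spec = spec),
            class = "segment_kinematics")
}

# body-frame angular velocity of a segment state
state_angvel_body <- function(state) {
  quat_rotate(quat_conjugate(state$quat), state$omega)
}

#' Ground-truth L5/S1 net moment for simulated kinematics
#'
#' Evaluates the same mechanical formulation as [lsm_net_moment()] on the
#' noise-free segment poses, so truth and estimator share one moment engine
#' and differ only in their inputs.
#'
#' @param kin a [simulate_kinematics()] result.
#' @param body_model a [scale_body_model()] result (defaults to the one
#'   embedded in `kin`).
#' @param load_mass handheld load, kg.
#' @param load_offset load position relative to mid-hands, m, trunk frame.
#' @return a [net_moment_series()].
#' @export
simulate_truth_moment <- function(kin, body_model = kin$body_model,
                                  load_mass = kin$spec$load_mass,
                                  load_offset = kin$spec$load_offset) {
  stopifnot(inherits(kin, "segment_kinematics"))
  segs <- list()
  for (nm in c("trunk", "upper_arm_L", "upper_arm_R",
               "lower_arm_L", "lower_arm_R")) {
    st <- kin$segments[[nm]]
    segs[[nm]] <- list(quat = st$quat, angvel = state_angvel_body(st))
  }
  poses <- list(t = kin$t, segments = segs, root_acc = NULL)
  moment_engine(poses, body_model,
                load_spec(load_mass, position = load_offset))
}

# sensor mounting geometry: site offsets in the segment frame (m); arm
# sensors sit mid-segment, the sternum sensor high on the chest and the
# sacrum sensor on the posterior pelvis
site_geometry <- function(bm) {
  tr <- body_segment(bm, "trunk")
  ua <- body_segment(bm, "upper_arm_L")
  la <- body_segment(bm, "lower_arm_L")
  list(
    sternum = list(segment = "trunk", r = c(0.06, 0, -0.75 * tr$length)),
    sacrum = list(segment = "pelvis", r = c(-0.08, 0, 0.03)),
    upper_arm_L = list(segment = "upper_arm_L", r = c(0, 0, 0.5 * ua$length)),
    upper_arm_R = list(segment = "upper_arm_R", r = c(0, 0, 0.5 * ua$length)),
    lower_arm_L = list(segment = "lower_arm_L", r = c(0, 0, 0.5 * la$length)),
    lower_arm_R = list(segment = "lower_arm_R", r = c(0, 0, 0.5 * la$length))
  )
}

# linear EMG forward model: noise-free envelope per channel is
# gain * (max(0, a*My + b*|Mx| + c*|Mz|) + tonic), with side-dependent
# (a, b, c); bilateral asymmetry enters through the |Mx| and |Mz| weights
EMG_MOMENT_COEFS <- matrix(
  c(0.50, 0.35, 0.15,
    0.50, 0.15, 0.35,
    0.45, 0.40, 0.25,
    0.45, 0.25, 0.40),
  nrow = 4, byrow = TRUE,
  dimnames = list(c("longissimus_L1_L", "longissimus_L1_R",
                    "iliocostalis_L23_L", "iliocostalis_L23_R"),
                  c("My", "absMx", "absMz")))
EMG_TONIC_NM <- 1.0   # tonic activation floor, Nm-equivalent

emg_clean_envelopes <- function(truth, gain, crosstalk) {
  drive <- cbind(truth$M[, "My"], abs(truth$M[, "Mx"]), abs(truth$M[, "Mz"]))
  env <- sapply(rownames(EMG_MOMENT_COEFS), function(ch) {
    gain * (pmax(0, drive %*% EMG_MOMENT_COEFS[ch, ]) + EMG_TONIC_NM)
  })
  # bilateral cross-talk mixes each channel with its contralateral partner
  partner <- c(2, 1, 4, 3)
  (1 - crosstalk) * env + crosstalk * env[, partner]
}

#' Simulate sensor signals from kinematics and ground truth
#'
#' Produces the six inertial streams (casing kinematics: segment poses
#' pre-rotated by the mounting misalignment, plus white noise) and the four
#' raw surface EMG channels (an amplitude-modulated zero-mean carrier whose
#' rectified-smoothed envelope recovers a linear function of the net moment,
#' plus noise and bilateral cross-talk).  When `tap_marker` is `TRUE` a
#' short high-amplitude transient is injected at 0.5 s (inertial clock) into
#' the sacrum accelerometer and the two L1 EMG channels; the EMG timestamps
#' carry the clock offset `noise$tap_offset`.
#'
#' @param kin a [simulate_kinematics()] result.
#' @param truth the matching ground-truth [net_moment_series()] (drives the
#'   EMG amplitude model).
#' @param noise a [sensor_noise_spec()]; `mount_rotation` must be a fully
#'   resolved per-site list here (as prepared by [simulate_session()]), or
#'   `NULL` for identity mounting.
#' @param seed integer seed for the noise draws.
#' @param tap_marker inject synchronization tap transients.
#' @return list with elements `immu` (named [immu_stream()] list) and `emg`
#'   (named [emg_stream()] list).
#' @export
simulate_sensors <- function(kin, truth, noise = sensor_noise_spec(),
                             seed = 1L, tap_marker = FALSE) {
  stopifnot(inherits(kin, "segment_kinematics"),
            inherits(truth, "net_moment_series"))
  set.seed(seed)
  t <- kin$t
  n <- length(t)
  g <- matrix(rep(c(0, 0, GRAVITY), each = n), ncol = 3)
  geom <- site_geometry(kin$body_model)

  immu <- list()
  for (site in immu_sites()) {
    st <- kin$segments[[geom[[site]]$segment]]
    pk <- point_kinematics(st, geom[[site]]$r, a0 = st$a0)
    f_global <- pk$a - g
    q_seg <- st$quat
    w_body <- state_angvel_body(st)
    f_body <- quat_rotate(quat_conjugate(q_seg), f_global)
    mr <- noise$mount_rotation[[site]]
    if (!is.null(mr) && sqrt(sum(mr^2)) > 0) {
      ang <- sqrt(sum(mr^2))
      q_sc <- as.numeric(quat_from_axis_angle(mr / ang, ang))
      q_cas <- quat_multiply(q_seg, q_sc)
      w_cas <- quat_rotate(quat_conjugate(q_sc), w_body)
      f_cas <- quat_rotate(quat_conjugate(q_sc), f_body)
    } else {
      q_cas <- q_seg; w_cas <- w_body; f_cas <- f_body
    }
    if (noise$gyro_sd > 0)
      w_cas <- w_cas + matrix(stats::rnorm(3 * n, sd = noise$gyro_sd), n, 3)
    if (noise$acc_sd > 0)
      f_cas <- f_cas + matrix(stats::rnorm(3 * n, sd = noise$acc_sd), n, 3)
    if (tap_marker && site == "sacrum") {
      # sharp decaying transient whose peak sits at the tap instant
      idx <- which(t >= 0.5)[1:3]
      f_cas[idx, 3] <- f_cas[idx, 3] - 40 * c(1, 0.6, 0.3)
    }
    immu[[site]] <- immu_stream(site, t, q_cas, w_cas, f_cas)
  }

  env <- emg_clean_envelopes(truth, noise$emg_gain, noise$emg_crosstalk)
  rate <- noise$emg_rate
  t_phys <- seq(0, max(t) + SAMPLE_DT - 1 / rate, by = 1 / rate)
  emg <- list()
  for (i in seq_along(emg_channels())) {
    ch <- emg_channels()[i]
    env_hi <- stats::approx(t, env[, i], xout = t_phys, rule = 2)$y
    raw <- env_hi * stats::rnorm(length(t_phys)) +
      stats::rnorm(length(t_phys), sd = noise$emg_noise_sd)
    if (tap_marker && i <= 2L) {
      idx <- which(t_phys >= 0.5)[1:30]
      pulse_amp <- 40 * max(noise$emg_gain * 100, noise$emg_noise_sd, 0.1)
      raw[idx] <- raw[idx] +
        pulse_amp * exp(-(seq_along(idx) - 1) / 8)
    }
    emg[[ch]] <- emg_stream(ch, t_phys + noise$tap_offset, raw)
  }

  list(immu = immu, emg = emg)
}

#' Default-scenario task parameters
#'
#' The task-level study conditions used by [simulate_session()]: Borg CR-10
#' perceived-workload distributions (truncated normal, rounded to half
#' points) and physical-workload checklist ranks per task class.
#'
#' @return list with a `borg` data.frame (task, mean, sd) and a `ranks`
#'   list.
#' @export
scenario_parameters <- function() {
  list(
    borg = data.frame(task = c("light", "static", "heavy_dynamic"),
                      mean = c(0.9, 3.8, 6.0), sd = c(0.8, 1.6, 2.0),
                      stringsAsFactors = FALSE),
    ranks = list(light = 1L, static = 3:4, heavy_dynamic = 5L)
  )
}

# truncated-normal draw for Borg CR-10 scores
rborg <- function(mu, sd) {
  x <- stats::rnorm(1, mu, sd)
  while (x < 0 || x > 10) x <- stats::rnorm(1, mu, sd)
  round(x * 2) / 2
}

#' Simulate a complete three-phase measurement session
#'
#' Generates, under the default scenario, the full session protocol: phase 1
#' segment-calibration trials (neutral stance, then 90 deg trunk bending,
#' 45 deg lateroflexion, 45 deg rotation, 45 deg shoulder flexion and 90 deg
#' shoulder abduction, each five repetitions followed by 3 s of neutral
#' standing), phase 2 known-load trials (bending / lateroflexion / rotation
#' crossed with 0, 6 and 10 kg), and phase 3 work tasks: a light task (low
#' amplitude, checklist rank 1), a static task (posture held well beyond
#' 4 s, rank 3-4) and a combined heavy+dynamic lifting task (rank 5).  Borg
#' CR-10 scores are drawn from truncated normal distributions with means
#' (SDs) 0.9 (0.8), 3.8 (1.6) and 6.0 (2.0) for light, static and
#' heavy/dynamic tasks.  Synchronization tap markers are injected into the
#' first (neutral) trial only, mirroring a single pre-measurement tap.
#'
#' Ground-truth moments are attached to every trial; the drawn mounting
#' misalignments and the EMG clock offset are recorded in `$sim_truth`.
#'
#' @param subject a [subject_info()]; default is the cohort-mean subject
#'   (1.85 m, 93 kg).
#' @param scenario scenario name; only "field_default" is defined.
#' @param seed integer seed controlling every random element.
#' @param noise a [sensor_noise_spec()].
#' @param phases which phases to generate (subset of 1:3); phase 1 is always
#'   required for calibration and synchronization.
#' @return a [session()].
#' @export
simulate_session <- function(subject = subject_info("sim", 1.85, 93),
                             scenario = "field_default", seed = 1L,
                             noise = sensor_noise_spec(), phases = 1:3) {
  scenario <- match.arg(scenario, "field_default")
  set.seed(seed)
  if (is.null(noise$mount_rotation)) {
    noise$mount_rotation <- lapply(stats::setNames(immu_sites(),
                                                   immu_sites()),
      function(s) {
        ax <- stats::rnorm(3); ax <- ax / sqrt(sum(ax^2))
        ax * stats::runif(1, 0, noise$max_mount_deg * pi / 180)
      })
  }

  plan <- list()
  add <- function(plan, id, kind, spec, label = "none",
                  rank = NA_integer_, borg = NA_real_, tap = FALSE) {
    plan[[id]] <- list(id = id, kind = kind, spec = spec, label = label,
                       rank = rank, borg = borg, tap = tap)
    plan
  }

  if (1 %in% phases) {
    plan <- add(plan, "cal_neutral", "segment_calibration",
                motion_spec("neutral", 0, period = 4, tail = 0), tap = TRUE)
    cal <- list(bending = pi / 2, lateroflexion = pi / 4, rotation = pi / 4,
                shoulder_flexion = pi / 4, shoulder_abduction = pi / 2)
    for (mv in names(cal))
      plan <- add(plan, paste0("cal_", mv), "segment_calibration",
                  motion_spec(mv, cal[[mv]], repetitions = 5, tail = 3))
  }
  if (2 %in% phases) {
    peaks <- c(bending = pi / 3, lateroflexion = 35 * pi / 180,
               rotation = 40 * pi / 180)
    for (mv in names(peaks))
      for (lm in c(0, 6, 10))
        plan <- add(plan, sprintf("load_%s_%02d", mv, lm), "load_trial",
                    motion_spec(mv, peaks[[mv]], repetitions = 5,
                                load_mass = lm))
  }
  if (3 %in% phases) {
    sp <- scenario_parameters()
    bpar <- function(task) sp$borg[sp$borg$task == task, ]
    b <- bpar("light")
    plan <- add(plan, "task_light", "work_task",
                motion_spec("bending", 15 * pi / 180, repetitions = 6),
                label = "light", rank = sp$ranks$light,
                borg = rborg(b$mean, b$sd))
    b <- bpar("static")
    plan <- add(plan, "task_static", "work_task",
                motion_spec("hold_posture", 20 * pi / 180, period = 8),
                label = "static", rank = sample(sp$ranks$static, 1),
                borg = rborg(b$mean, b$sd))
    b <- bpar("heavy_dynamic")
    plan <- add(plan, "task_dynamic", "work_task",
                motion_spec("lift_cycle", pi / 3, repetitions = 8,
                            load_mass = 10),
                label = "dynamic", rank = sp$ranks$heavy_dynamic,
                borg = rborg(b$mean, b$sd))
  }
  if (!length(plan)) stop("no phases selected")

  trials <- list()
  for (p in plan) {
    kin <- simulate_kinematics(p$spec, subject)
    truth <- simulate_truth_moment(kin)
    sens <- simulate_sensors(kin, truth, noise,
                             seed = sample.int(.Machine$integer.max, 1),
                             tap_marker = p$tap)
    movement <- if (p$kind == "work_task") "task"
                else if (p$spec$movement %in% MOVEMENTS) p$spec$movement
                else "task"
    trials[[p$id]] <- trial(
      id = p$id, kind = p$kind, movement = movement,
      immu = sens$immu, emg = sens$emg,
      load_mass = p$spec$load_mass, task_label = p$label,
      checklist_rank = p$rank, borg = p$borg,
      load_offset = p$spec$load_offset, truth_moment = truth)
  }

  session(subject, unname(trials),
          sim_truth = list(mount_rotation = noise$mount_rotation,
                           tap_offset = noise$tap_offset,
                           seed = seed))
}
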
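# Shared fixtures: simulated sessions are expensive, so processed sessions
# are cached per (seed, phases) within a test run.

.sim_cache <- new.env(parent = emptyenv())

sim_session_cached <- function(seed = 1, phases = 1:3,
                               noise = sensor_noise_spec()) {
  key <- paste0("s", seed, "_p", paste(phases, collapse = ""),
                "_o", noise$tap_offset)
  if (is.null(.sim_cache[[key]]))
    .sim_cache[[key]] <- simulate_session(seed = seed, noise = noise,
                                          phases = phases)
  .sim_cache[[key]]
}

# calibrated + synchronized + enveloped session
processed_session_cached <- function(seed = 1, phases = 1:3) {
  key <- paste0("proc_s", seed, "_p", paste(phases, collapse = ""))
  if (is.null(.sim_cache[[key]])) {
    ses <- sim_session_cached(seed, phases)
    ses <- lumbarload:::calibrate_session(ses)
    ses <- synchronize(ses)
    ses <- lumbarload:::envelope_session(ses)
    .sim_cache[[key]] <- ses
  }
  .sim_cache[[key]]
}

default_subject <- function() subject_info("sim", 1.85, 93)

series_of <- function(M) net_moment_series((seq_len(nrow(M)) - 1) * 0.02, M)

load_trial_ids <- function(masses = c(0, 6, 10)) {
  as.vector(t(outer(c("bending", "lateroflexion", "rotation"), masses,
                    function(m, l) sprintf("load_%s_%02d", m, l))))
}

# minimal single-trial session with tap markers, for synchronization tests
sync_session <- function(seed, tap_offset) {
  subj <- default_subject()
  kin <- simulate_kinematics(motion_spec("neutral", 0, period = 3,
                                         tail = 0), subj)
  truth <- simulate_truth_moment(kin)
  sens <- simulate_sensors(kin, truth,
                           sensor_noise_spec(tap_offset = tap_offset),
                           seed = seed, tap_marker = TRUE)
  tr <- trial("sync_trial", "segment_calibration", "neutral",
              immu = sens$immu, emg = sens$emg)
  session(default_subject(), list(tr))
}

# independent static oracle: gravitational moment about L5/S1 as a direct
# point-mass sum over a static posture defined by trunk pitch (forward
# flexion, rad) with hanging arms and an optional handheld load
static_gravity_oracle <- function(subject, pitch, load_mass = 0,
                                  load_offset = c(0.10, 0, 0)) {
  bm <- scale_body_model(subject)
  seg <- function(nm) bm[match(nm, bm$segment), ]
  tr <- seg("trunk"); hd <- seg("head_neck")
  wsh <- attr(bm, "shoulder_halfwidth")
  g <- 9.81
  # rotation of a trunk-frame point by `pitch` about the -y axis
  rot <- function(v) c(cos(pitch) * v[1] - sin(pitch) * v[3], v[2],
                       sin(pitch) * v[1] + cos(pitch) * v[3])
  pts <- list()
  pts$trunk <- list(p = rot(c(0, 0, -tr$com)), m = tr$mass)
  pts$head <- list(p = rot(c(0, 0, -(tr$length + hd$com))), m = hd$mass)
  hand <- list()
  for (side in c("L", "R")) {
    sgn <- if (side == "L") -1 else 1
    sh <- rot(c(0, sgn * wsh, -tr$length))
    ua <- seg(paste0("upper_arm_", side))
    fa <- seg(paste0("lower_arm_", side))
    pts[[paste0("ua", side)]] <- list(p = sh + c(0, 0, ua$com), m = ua$mass)
    elbow <- sh + c(0, 0, ua$length)
    pts[[paste0("fa", side)]] <- list(p = elbow + c(0, 0, fa$com),
                                      m = fa$mass)
    hand[[side]] <- elbow + c(0, 0, fa$length)
  }
  if (load_mass > 0)
    pts$load <- list(p = (hand$L + hand$R) / 2 + rot(load_offset),
                     m = load_mass)
  # static M = sum r x m (0 - g_vec), g_vec = (0, 0, +g); expressed in the
  # trunk frame (rotate back by the pitch)
  M <- c(0, 0, 0)
  for (pt in pts) {
    F <- c(0, 0, -pt$m * g)
    M <- M + c(pt$p[2] * F[3] - pt$p[3] * F[2],
               pt$p[3] * F[1] - pt$p[1] * F[3],
               pt$p[1] * F[2] - pt$p[2] * F[1])
  }
  inv <- function(v) c(cos(pitch) * v[1] + sin(pitch) * v[3], v[2],
                       -sin(pitch) * v[1] + cos(pitch) * v[3])
  inv(M)
}
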
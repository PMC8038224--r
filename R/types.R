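# Core domain types for a measurement session.
#
# Coordinate conventions used throughout the package
# --------------------------------------------------
# Global and anatomical frames are right-handed with x anterior, y to the
# subject's right, z caudal (pointing down); gravity is +9.81 m/s^2 along z.
# In this frame the net L5/S1 reaction moment M = sum r x m (a - g) + dH/dt
# is positive about y for forward trunk flexion, positive about x for
# lateroflexion to the left and positive about z for rotation to the left,
# matching the reporting conventions of field studies of lumbar load.
# All orientation quaternions map body-frame coordinates to global
# coordinates; angular velocity and linear acceleration (specific force,
# IMU convention) are expressed in the body frame of their stream.

SAMPLE_RATE <- 50
SAMPLE_DT <- 1 / SAMPLE_RATE
GRAVITY <- 9.81

#' Sensor sites and EMG channel names
#'
#' `immu_sites()` returns the six inertial sensor mounting sites;
#' `emg_channels()` the four bilateral trunk EMG channels (longissimus
#' thoracis at L1 and iliocostalis lumborum at L2-L3, left/right).
#'
#' @return character vector of site / channel identifiers.
#' @export
immu_sites <- function() {
  c("sternum", "sacrum", "upper_arm_L", "upper_arm_R",
    "lower_arm_L", "lower_arm_R")
}

#' @rdname immu_sites
#' @export
emg_channels <- function() {
  c("longissimus_L1_L", "longissimus_L1_R",
    "iliocostalis_L23_L", "iliocostalis_L23_R")
}

#' Subject anthropometry and metadata
#'
#' @param id subject identifier.
#' @param height standing height in m; must lie in (1.0, 2.5).
#' @param mass body mass in kg; must lie in (30, 200).
#' @param handedness "left" or "right".
#' @return object of class `subject_info`.
#' @export
subject_info <- function(id, height, mass, handedness = "right") {
  stopifnot(is.character(id), length(id) == 1L)
  if (!is.numeric(height) || length(height) != 1L || !is.finite(height) ||
      height <= 1.0 || height >= 2.5)
    stop("subject height must be a single value in (1.0, 2.5) m")
  if (!is.numeric(mass) || length(mass) != 1L || !is.finite(mass) ||
      mass <= 30 || mass >= 200)
    stop("subject mass must be a single value in (30, 200) kg")
  handedness <- match.arg(handedness, c("left", "right"))
  structure(list(id = id, height = height, mass = mass,
                 handedness = handedness),
            class = "subject_info")
}

#' Inertial sensor stream
#'
#' One sensor's kinematic time series at 50 Hz: orientation quaternion
#' (body-to-global, w/x/y/z), angular velocity (rad/s, body frame) and
#' linear acceleration as specific force (m/s^2, body frame; reads
#' (0, 0, -9.81) at rest in the package frame convention).
#'
#' @param site one of [immu_sites()].
#' @param t sample times in s, uniformly spaced at 0.02 s.
#' @param quat n x 4 matrix of unit quaternions.
#' @param angvel n x 3 matrix, rad/s.
#' @param linacc n x 3 matrix, m/s^2.
#' @return object of class `immu_stream`.
#' @export
immu_stream <- function(site, t, quat, angvel, linacc) {
  site <- match.arg(site, immu_sites())
  x <- structure(list(site = site, t = as.numeric(t),
                      quat = unname(as.matrix(quat)),
                      angvel = unname(as.matrix(angvel)),
                      linacc = unname(as.matrix(linacc))),
                 class = "immu_stream")
  validate_immu_stream(x)
  x
}

validate_immu_stream <- function(x) {
  n <- length(x$t)
  if (nrow(x$quat) != n || nrow(x$angvel) != n || nrow(x$linacc) != n)
    stop(sprintf("immu_stream '%s': channel lengths differ", x$site))
  if (ncol(x$quat) != 4L || ncol(x$angvel) != 3L || ncol(x$linacc) != 3L)
    stop(sprintf("immu_stream '%s': wrong channel width", x$site))
  if (n >= 2L) {
    dt <- diff(x$t)
    bad <- which(abs(dt - SAMPLE_DT) > 1e-9)
    if (length(bad))
      stop(sprintf(
        "immu_stream '%s': sample spacing violates 0.02 s grid at sample %d",
        x$site, bad[1]))
  }
  qn <- sqrt(rowSums(x$quat^2))
  bad <- which(abs(qn - 1) > 1e-6)
  if (length(bad))
    stop(sprintf("immu_stream '%s': non-unit quaternion at sample %d",
                 x$site, bad[1]))
  if (!all(is.finite(x$angvel)) || !all(is.finite(x$linacc)))
    stop(sprintf("immu_stream '%s': non-finite samples (gaps are not allowed)",
                 x$site))
  invisible(x)
}

#' Surface EMG stream
#'
#' Raw bipolar signal on its own (EMG hardware) clock plus, once computed,
#' the amplitude envelope resampled to the 50 Hz session grid.
#'
#' @param channel one of [emg_channels()].
#' @param t_raw raw sample times in s (uniform, rate >= 500 Hz).
#' @param raw signed raw amplitudes, arbitrary units.
#' @param t_env,envelope optional envelope track at 50 Hz (set by
#'   [emg_amplitude()]).
#' @return object of class `emg_stream`.
#' @export
emg_stream <- function(channel, t_raw, raw, t_env = NULL, envelope = NULL) {
  channel <- match.arg(channel, emg_channels())
  x <- structure(list(channel = channel, t_raw = as.numeric(t_raw),
                      raw = as.numeric(raw), t_env = t_env,
                      envelope = envelope),
                 class = "emg_stream")
  validate_emg_stream(x)
  x
}

validate_emg_stream <- function(x) {
  if (length(x$t_raw) != length(x$raw))
    stop(sprintf("emg_stream '%s': t_raw and raw lengths differ", x$channel))
  if (length(x$t_raw) >= 2L) {
    rate <- 1 / stats::median(diff(x$t_raw))
    if (rate < 500 - 1e-6)
      stop(sprintf("emg_stream '%s': raw sample rate %.1f Hz below 500 Hz",
                   x$channel, rate))
  }
  if (!all(is.finite(x$raw)))
    stop(sprintf("emg_stream '%s': non-finite raw samples", x$channel))
  if (!is.null(x$envelope)) {
    if (length(x$envelope) != length(x$t_env))
      stop(sprintf("emg_stream '%s': envelope track lengths differ",
                   x$channel))
    if (any(x$envelope < 0))
      stop(sprintf("emg_stream '%s': negative envelope sample", x$channel))
  }
  invisible(x)
}

emg_raw_rate <- function(x) 1 / stats::median(diff(x$t_raw))

#' 3D net moment series at L5/S1
#'
#' Components in Nm in the trunk anatomical frame: Mx about the
#' anterior-posterior axis (positive = lateroflexion to the left), My about
#' the mediolateral axis (positive = forward flexion), Mz about the
#' longitudinal axis (positive = rotation to the left).  The per-sample
#' Euclidean norm is stored alongside.
#'
#' @param t times in s at 50 Hz.
#' @param M n x 3 matrix of (Mx, My, Mz) in Nm.
#' @return object of class `net_moment_series` with elements `t`, `M`,
#'   `norm`.
#' @export
net_moment_series <- function(t, M) {
  M <- as.matrix(M)
  stopifnot(ncol(M) == 3L, nrow(M) == length(t))
  if (!all(is.finite(M))) stop("net_moment_series: non-finite moment samples")
  colnames(M) <- c("Mx", "My", "Mz")
  structure(list(t = as.numeric(t), M = M, norm = sqrt(rowSums(M^2))),
            class = "net_moment_series")
}

#' Per-sample moment magnitude
#'
#' Euclidean norm of the (Mx, My, Mz) triple, the magnitude summary used in
#' task descriptives.
#'
#' @param series a `net_moment_series`.
#' @return numeric vector of per-sample norms in Nm.
#' @export
moment_norm <- function(series) {
  stopifnot(inherits(series, "net_moment_series"))
  sqrt(rowSums(series$M^2))
}

TRIAL_KINDS <- c("segment_calibration", "load_trial", "work_task")
MOVEMENTS <- c("bending", "lateroflexion", "rotation", "shoulder_flexion",
               "shoulder_abduction", "neutral", "task")
TASK_LABELS <- c("light", "heavy", "static", "dynamic", "none")

#' A single measurement trial
#'
#' @param id trial identifier (unique within the session).
#' @param kind "segment_calibration", "load_trial" or "work_task".
#' @param movement movement label; "task" for work tasks.
#' @param immu named list of [immu_stream()]s (by site).
#' @param emg named list of [emg_stream()]s (by channel).
#' @param load_mass handheld load in kg; load trials must use 0, 6 or 10.
#' @param task_label work-task character ("light", "heavy", "static",
#'   "dynamic" or "none").
#' @param checklist_rank physical-workload checklist rank 1-5, or NA.
#' @param borg Borg CR-10 perceived workload in [0, 10], or NA.
#' @param load_offset position of the handheld load relative to mid-hands,
#'   m, in the trunk frame.
#' @param truth_moment optional simulator ground-truth `net_moment_series`.
#' @return object of class `trial`.
#' @export
trial <- function(id, kind, movement, immu, emg = list(), load_mass = 0,
                  task_label = "none", checklist_rank = NA_integer_,
                  borg = NA_real_, load_offset = c(0.10, 0, 0),
                  truth_moment = NULL) {
  kind <- match.arg(kind, TRIAL_KINDS)
  movement <- match.arg(movement, MOVEMENTS)
  task_label <- match.arg(task_label, TASK_LABELS)
  x <- structure(list(id = id, kind = kind, movement = movement,
                      load_mass = load_mass, task_label = task_label,
                      checklist_rank = checklist_rank, borg = borg,
                      load_offset = as.numeric(load_offset),
                      immu = immu, emg = emg, truth_moment = truth_moment),
                 class = "trial")
  validate_trial(x)
  x
}

validate_trial <- function(x) {
  if (x$kind == "load_trial" && !x$load_mass %in% c(0, 6, 10))
    stop(sprintf("trial '%s': load trials must use a 0, 6 or 10 kg load",
                 x$id))
  if (x$kind == "work_task" && !is.na(x$borg) && (x$borg < 0 || x$borg > 10))
    stop(sprintf("trial '%s': Borg CR-10 score must lie in [0, 10]", x$id))
  if (!is.na(x$checklist_rank) &&
      !(x$checklist_rank %in% 1:5))
    stop(sprintf("trial '%s': checklist rank must be 1-5", x$id))
  if (length(x$load_offset) != 3L)
    stop(sprintf("trial '%s': load_offset must be a 3-vector", x$id))
  for (s in x$immu) validate_immu_stream(s)
  for (s in x$emg) validate_emg_stream(s)
  invisible(x)
}

#' A full measurement session
#'
#' Ordered container of calibration, known-load and work-task trials for one
#' subject, plus (once computed) the sensor-to-segment calibration and the
#' stream synchronization offsets.  The sacrum inertial sensor is the session
#' master clock.
#'
#' @param subject a [subject_info()].
#' @param trials list of [trial()]s.
#' @param sync optional `sync_result` from [synchronize()].
#' @param calibration optional `segment_calibration` from
#'   [estimate_segment_frames()].
#' @param sim_truth optional list of simulator ground-truth parameters
#'   (mount rotations, clock offset); present only for simulated sessions.
#' @return object of class `session`.
#' @export
session <- function(subject, trials, sync = NULL, calibration = NULL,
                    sim_truth = NULL) {
  stopifnot(inherits(subject, "subject_info"))
  ids <- vapply(trials, function(tr) tr$id, character(1))
  if (anyDuplicated(ids)) stop("duplicate trial ids in session")
  x <- structure(list(subject = subject, trials = trials, sync = sync,
                      calibration = calibration, sim_truth = sim_truth),
                 class = "session")
  x
}

session_trials <- function(ses, kind = NULL, movement = NULL,
                           load_mass = NULL) {
  keep <- vapply(ses$trials, function(tr) {
    (is.null(kind) || tr$kind %in% kind) &&
      (is.null(movement) || tr$movement %in% movement) &&
      (is.null(load_mass) || tr$load_mass %in% load_mass)
  }, logical(1))
  ses$trials[keep]
}

session_trial <- function(ses, id) {
  for (tr in ses$trials) if (identical(tr$id, id)) return(tr)
  stop(sprintf("no trial '%s' in session", id))
}

#' @export
print.subject_info <- function(x, ...) {
  cat(sprintf("Subject '%s': %.2f m, %.1f kg, %s-handed\n",
              x$id, x$height, x$mass, x$handedness))
  invisible(x)
}

#' @export
print.session <- function(x, ...) {
  kinds <- table(vapply(x$trials, function(tr) tr$kind, character(1)))
  cat(sprintf("Session for subject '%s': %d trials (%s)\n", x$subject$id,
              length(x$trials),
              paste(sprintf("%s: %d", names(kinds), kinds), collapse = ", ")))
  cat(sprintf("  calibrated: %s; synchronized: %s\n",
              !is.null(x$calibration), !is.null(x$sync)))
  invisible(x)
}

#' @export
print.net_moment_series <- function(x, ...) {
  cat(sprintf(
    "net_moment_series: %d samples (%.1f s), mean ||M|| = %.1f Nm, peak = %.1f Nm\n",
    length(x$t), diff(range(x$t)), mean(x$norm), max(x$norm)))
  invisible(x)
}
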
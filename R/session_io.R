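# On-disk session format: a YAML manifest (`session.yaml`) plus one CSV per
# stream.  Stream dialects: inertial `t,qw,qx,qy,qz,wx,wy,wz,ax,ay,az`;
# raw EMG `t,value`; envelopes `t,value`; moments `t,Mx,My,Mz`.  Numbers
# are written with 17 significant digits so doubles survive a round trip
# bit-identically.

fmt17 <- function(x) sprintf("%.17g", x)

write_csv17 <- function(df, file) {
  out <- df
  for (j in seq_along(out))
    if (is.numeric(out[[j]])) out[[j]] <- fmt17(out[[j]])
  utils::write.csv(out, file, row.names = FALSE, quote = FALSE)
}

num_or_null <- function(x) if (is.null(x)) NULL else as.numeric(x)

#' Write a session to a directory
#'
#' Creates `session.yaml` plus one CSV per stream (and per truth-moment and
#' envelope track).  The written form re-reads to an equal session; stream
#' files are byte-stable under write-read-write.
#'
#' @param ses a [session()].
#' @param path target directory (created if needed).
#' @return invisibly, `path`.
#' @export
write_session <- function(ses, path) {
  stopifnot(inherits(ses, "session"))
  if (!dir.exists(path)) dir.create(path, recursive = TRUE)

  man_trials <- list()
  for (tr in ses$trials) {
    immu_files <- list()
    for (site in names(tr$immu)) {
      s <- tr$immu[[site]]
      f <- sprintf("%s_immu_%s.csv", tr$id, site)
      write_csv17(data.frame(
        t = s$t, qw = s$quat[, 1], qx = s$quat[, 2], qy = s$quat[, 3],
        qz = s$quat[, 4], wx = s$angvel[, 1], wy = s$angvel[, 2],
        wz = s$angvel[, 3], ax = s$linacc[, 1], ay = s$linacc[, 2],
        az = s$linacc[, 3]), file.path(path, f))
      immu_files[[site]] <- f
    }
    emg_files <- list(); env_files <- list()
    for (ch in names(tr$emg)) {
      s <- tr$emg[[ch]]
      f <- sprintf("%s_emg_%s.csv", tr$id, ch)
      write_csv17(data.frame(t = s$t_raw, value = s$raw),
                  file.path(path, f))
      emg_files[[ch]] <- f
      if (!is.null(s$envelope)) {
        fe <- sprintf("%s_env_%s.csv", tr$id, ch)
        write_csv17(data.frame(t = s$t_env, value = s$envelope),
                    file.path(path, fe))
        env_files[[ch]] <- fe
      }
    }
    truth_file <- NULL
    if (!is.null(tr$truth_moment)) {
      truth_file <- sprintf("%s_truth.csv", tr$id)
      tm <- tr$truth_moment
      write_csv17(data.frame(t = tm$t, Mx = tm$M[, 1], My = tm$M[, 2],
                             Mz = tm$M[, 3]), file.path(path, truth_file))
    }
    man_trials[[length(man_trials) + 1L]] <- list(
      id = tr$id, kind = tr$kind, movement = tr$movement,
      load_mass = fmt17(tr$load_mass), task_label = tr$task_label,
      checklist_rank = if (is.na(tr$checklist_rank)) NULL
                       else as.integer(tr$checklist_rank),
      borg = if (is.na(tr$borg)) NULL else fmt17(tr$borg),
      load_offset = fmt17(tr$load_offset),
      immu = immu_files, emg = emg_files,
      envelopes = if (length(env_files)) env_files else NULL,
      truth = truth_file)
  }

  man <- list(
    subject = list(id = ses$subject$id, height = fmt17(ses$subject$height),
                   mass = fmt17(ses$subject$mass),
                   handedness = ses$subject$handedness),
    trials = man_trials)
  if (!is.null(ses$sync))
    man$sync <- list(offset = fmt17(ses$sync$offset),
                     marker_times = as.list(fmt17(ses$sync$marker_times)),
                     marker_names = as.list(names(ses$sync$marker_times)),
                     confidence = as.list(fmt17(ses$sync$confidence)),
                     confidence_names = as.list(names(ses$sync$confidence)),
                     source_trial = ses$sync$source_trial)
  if (!is.null(ses$calibration))
    man$calibration <- list(
      sites = as.list(names(ses$calibration$rotations)),
      rotations = lapply(ses$calibration$rotations, fmt17),
      residual_deg = lapply(as.list(ses$calibration$residual_deg), fmt17),
      source_trials = as.list(ses$calibration$source_trials))
  if (!is.null(ses$sim_truth))
    man$sim_truth <- list(
      mount_rotation = lapply(ses$sim_truth$mount_rotation, fmt17),
      tap_offset = fmt17(ses$sim_truth$tap_offset),
      seed = ses$sim_truth$seed)
  yaml::write_yaml(man, file.path(path, "session.yaml"))
  invisible(path)
}

read_stream_csv <- function(path, trial_id, kind, name, file) {
  f <- file.path(path, file)
  if (!file.exists(f))
    stop(sprintf("trial '%s': missing %s stream file '%s' (%s)",
                 trial_id, kind, name, file))
  utils::read.csv(f)
}

#' Read a session from a directory
#'
#' Loads and validates the manifest plus every stream file; a missing
#' stream file is an error naming the stream, and any stream invariant
#' violation (quaternion norm, sample spacing, gaps) is a validation error
#' with the offending sample index.
#'
#' @param path directory containing `session.yaml`.
#' @return a [session()].
#' @export
read_session <- function(path) {
  mf <- file.path(path, "session.yaml")
  if (!file.exists(mf)) stop(sprintf("no session manifest at '%s'", mf))
  man <- yaml::read_yaml(mf)
  subj <- subject_info(man$subject$id, as.numeric(man$subject$height),
                       as.numeric(man$subject$mass),
                       man$subject$handedness)
  trials <- list()
  for (mt in man$trials) {
    immu <- list()
    for (site in names(mt$immu)) {
      df <- read_stream_csv(path, mt$id, "inertial", site, mt$immu[[site]])
      immu[[site]] <- immu_stream(
        site, df$t, as.matrix(df[, c("qw", "qx", "qy", "qz")]),
        as.matrix(df[, c("wx", "wy", "wz")]),
        as.matrix(df[, c("ax", "ay", "az")]))
    }
    emg <- list()
    for (ch in names(mt$emg)) {
      df <- read_stream_csv(path, mt$id, "EMG", ch, mt$emg[[ch]])
      t_env <- NULL; env <- NULL
      if (!is.null(mt$envelopes[[ch]])) {
        de <- read_stream_csv(path, mt$id, "envelope", ch,
                              mt$envelopes[[ch]])
        t_env <- de$t; env <- de$value
      }
      emg[[ch]] <- emg_stream(ch, df$t, df$value, t_env, env)
    }
    truth <- NULL
    if (!is.null(mt$truth)) {
      df <- read_stream_csv(path, mt$id, "truth-moment", "truth", mt$truth)
      truth <- net_moment_series(df$t,
                                 as.matrix(df[, c("Mx", "My", "Mz")]))
    }
    trials[[length(trials) + 1L]] <- trial(
      id = mt$id, kind = mt$kind, movement = mt$movement,
      immu = immu, emg = emg, load_mass = as.numeric(mt$load_mass),
      task_label = mt$task_label,
      checklist_rank = if (is.null(mt$checklist_rank)) NA_integer_
                       else as.integer(mt$checklist_rank),
      borg = if (is.null(mt$borg)) NA_real_ else as.numeric(mt$borg),
      load_offset = as.numeric(mt$load_offset), truth_moment = truth)
  }
  sync <- NULL
  if (!is.null(man$sync)) {
    mk <- as.numeric(unlist(man$sync$marker_times))
    names(mk) <- unlist(man$sync$marker_names)
    cf <- as.numeric(unlist(man$sync$confidence))
    names(cf) <- unlist(man$sync$confidence_names)
    sync <- structure(list(offset = as.numeric(man$sync$offset),
                           marker_times = mk, confidence = cf,
                           source_trial = man$sync$source_trial),
                      class = "sync_result")
  }
  calib <- NULL
  if (!is.null(man$calibration)) {
    sites <- unlist(man$calibration$sites)
    rot <- lapply(man$calibration$rotations, as.numeric)
    names(rot) <- sites
    res <- vapply(man$calibration$residual_deg,
                  function(x) as.numeric(x), numeric(1))
    names(res) <- sites
    calib <- structure(list(rotations = rot, residual_deg = res,
                            source_trials =
                              unlist(man$calibration$source_trials)),
                       class = "segment_calibration")
  }
  sim_truth <- NULL
  if (!is.null(man$sim_truth))
    sim_truth <- list(
      mount_rotation = lapply(man$sim_truth$mount_rotation, as.numeric),
      tap_offset = as.numeric(man$sim_truth$tap_offset),
      seed = man$sim_truth$seed)
  session(subj, trials, sync = sync, calibration = calib,
          sim_truth = sim_truth)
}
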
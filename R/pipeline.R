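# End-to-end pipeline: calibrate -> synchronize -> EMG envelopes -> LSM
# targets -> network training -> moment estimation -> validity statistics.

#' Pipeline configuration
#'
#' @param sessions list of session sources: either directory paths
#'   (read with [read_session()]) or lists
#'   `list(seed =, height =, mass =, id =)` handed to [simulate_session()].
#' @param out_dir directory for the report tables, or `NULL` to skip
#'   writing.
#' @param seed base seed for simulated sessions and network training.
#' @param use_linacc use measured root linear acceleration in the linked
#'   segment model (controlled environments).
#' @param smoothing_cutoff EMG envelope low-pass cutoff, Hz.
#' @param max_epochs,restarts network training budget.
#' @return configuration list of class `pipeline_config`.
#' @export
pipeline_config <- function(sessions = list(list(seed = 1)),
                            out_dir = NULL, seed = 1L, use_linacc = TRUE,
                            smoothing_cutoff = 3, max_epochs = 2000L,
                            restarts = 3L) {
  structure(list(sessions = sessions, out_dir = out_dir, seed = seed,
                 use_linacc = use_linacc,
                 smoothing_cutoff = smoothing_cutoff,
                 max_epochs = max_epochs, restarts = restarts),
            class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#'
#' @param path YAML file with fields matching [pipeline_config()].
#' @return a `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  do.call(pipeline_config, cfg)
}

stage <- function(name, ses_id, expr) {
  tryCatch(expr, error = function(e)
    stop(sprintf("pipeline stage '%s' failed for session '%s': %s",
                 name, ses_id, conditionMessage(e)), call. = FALSE))
}

# LSM target moments for a set of trials (named by trial id)
lsm_targets <- function(ses, trial_ids, bm, use_linacc = TRUE) {
  out <- list()
  for (id in trial_ids) {
    tr <- session_trial(ses, id)
    out[[id]] <- lsm_net_moment(tr$immu, bm,
                                load_spec(tr$load_mass,
                                          position = tr$load_offset),
                                use_linacc = use_linacc)
  }
  out
}

# train on the given load trials and return model + per-trial features
train_on_trials <- function(ses, trial_ids, bm, cfg, seed) {
  feats <- build_feature_matrix(ses, trial_ids)
  targs <- lsm_targets(ses, trial_ids, bm, cfg$use_linacc)
  Y <- do.call(rbind, lapply(trial_ids, function(id) targs[[id]]$M))
  model <- train_ann(feats, Y, seed = seed, max_epochs = cfg$max_epochs,
                     restarts = cfg$restarts)
  list(model = model, features = feats, targets = targs)
}

# per-subject processing: returns the result set consumed by build_report()
process_session <- function(ses, cfg, seed) {
  sid <- ses$subject$id

  ses <- stage("calibrate", sid, calibrate_session(ses))
  ses <- stage("synchronize", sid, synchronize(ses))
  ses <- stage("emg_envelopes", sid,
               envelope_session(ses, envelope_params(cfg$smoothing_cutoff)))
  bm <- scale_body_model(ses$subject)

  load_ids <- vapply(session_trials(ses, kind = "load_trial"),
                     function(tr) tr$id, character(1))
  if (!length(load_ids))
    stop(sprintf("pipeline stage 'train' failed for session '%s': %s",
                 sid, "ANN training requires load trials"), call. = FALSE)

  # phase-2 evaluation: train on the 0 and 10 kg trials, hold out 6 kg
  ids_train <- load_ids[vapply(load_ids, function(id)
    session_trial(ses, id)$load_mass %in% c(0, 10), logical(1))]
  ids_test <- setdiff(load_ids, ids_train)
  fit2 <- stage("train_phase2", sid,
                train_on_trials(ses, ids_train, bm, cfg, seed))

  agreement <- NULL; rmse_tab <- NULL
  for (id in ids_test) {
    tr <- session_trial(ses, id)
    feats <- build_feature_matrix(ses, id)
    est <- stage("estimate", sid, predict_moments(fit2$model, feats))
    target <- lsm_targets(ses, id, bm, cfg$use_linacc)[[id]]
    agr <- compare_curves(est, target)
    ax <- MOVEMENT_AXIS[[tr$movement]]
    row <- agr$per_axis[agr$per_axis$axis == ax, ]
    agreement <- rbind(agreement,
                       data.frame(movement = tr$movement, axis = ax,
                                  r = row$r, r2 = row$r2, band = row$band,
                                  trial = id, stringsAsFactors = FALSE))
    rmse_tab <- rbind(rmse_tab,
                      data.frame(movement = tr$movement,
                                 axis = agr$per_axis$axis,
                                 rmse = agr$per_axis$rmse, trial = id,
                                 stringsAsFactors = FALSE))
  }

  # phase-3: fresh network trained on all load trials, applied to the work
  # tasks
  fit3 <- stage("train_phase3", sid,
                train_on_trials(ses, load_ids, bm, cfg, seed + 1000L))
  work <- session_trials(ses, kind = "work_task")
  sel_ids <- if (length(work)) select_tasks(work) else NULL

  sel <- NULL; directions <- NULL
  if (!is.null(sel_ids)) {
    est_by_trial <- list()
    for (id in unique(unlist(sel_ids))) {
      feats <- build_feature_matrix(ses, id)
      est_by_trial[[id]] <- stage("estimate", sid,
                                  predict_moments(fit3$model, feats))
    }
    for (role in names(sel_ids)) {
      id <- sel_ids[[role]]
      tr <- session_trial(ses, id)
      est <- est_by_trial[[id]]
      td <- task_descriptives(tr, est)
      sel <- rbind(sel, data.frame(
        role = role, trial = id, mean = td$mean, peak = td$peak,
        variance = td$variance, borg = td$borg,
        rank = as.numeric(td$checklist_rank), stringsAsFactors = FALSE))
      for (ax in c("norm", "x", "y", "z")) {
        ds <- direction_split(est, ax)
        for (dr in c("positive", "negative")) {
          d <- ds[[dr]]
          directions <- rbind(directions, data.frame(
            role = role, trial = id, axis = ax, direction = dr,
            n = d$n, mean = d$mean, peak = d$peak, variance = d$variance,
            stringsAsFactors = FALSE))
        }
      }
    }
  }

  list(subject = sid, agreement = agreement, rmse = rmse_tab, sel = sel,
       directions = directions,
       phase2 = list(model = fit2$model, train_ids = ids_train,
                     test_ids = ids_test),
       phase3 = list(model = fit3$model, train_ids = load_ids,
                     task_ids = sel_ids))
}

#' Run the full estimation and validation pipeline
#'
#' For every configured session: sensor-to-segment calibration, tap-marker
#' synchronization, EMG envelope extraction, linked-segment-model target
#' moments, per-session network training (phase-2 held-out 6 kg evaluation
#' and phase-3 all-load training), moment estimation for the selected work
#' tasks, and the validity statistics.  Writes the report tables when an
#' output directory is configured.
#'
#' @param config a [pipeline_config()] (or a list coerced through it).
#' @return a [build_report()] `validity_report`; per-subject details are
#'   attached as attribute `subject_results`.
#' @export
run_pipeline <- function(config = pipeline_config()) {
  if (!inherits(config, "pipeline_config"))
    config <- do.call(pipeline_config, config)
  results <- list()
  for (i in seq_along(config$sessions)) {
    src <- config$sessions[[i]]
    if (is.character(src)) {
      ses <- read_session(src)
    } else {
      seed <- if (!is.null(src$seed)) src$seed else config$seed + i - 1L
      subj <- subject_info(
        id = if (!is.null(src$id)) src$id else sprintf("sim%02d", i),
        height = if (!is.null(src$height)) src$height else 1.85,
        mass = if (!is.null(src$mass)) src$mass else 93)
      ses <- simulate_session(subj, seed = seed)
    }
    results[[ses$subject$id]] <-
      process_session(ses, config, seed = config$seed + 100L * i)
  }
  report <- build_report(results)
  if (!is.null(config$out_dir)) write_report(report, config$out_dir)
  attr(report, "subject_results") <- results
  report
}
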
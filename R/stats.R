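# Discriminant-validity statistics: curve agreement, task descriptives,
# direction-split analysis, normality-gated paired testing and task
# selection.

MOVEMENT_AXIS <- c(bending = "y", lateroflexion = "x", rotation = "z")

# correlation band cutpoints: weak (0.1, 0.5], moderate (0.5, 0.7],
# good (0.7, 0.9], very good > 0.9
r_band <- function(r) {
  ifelse(is.na(r), NA_character_,
    ifelse(r > 0.9, "very_good",
      ifelse(r > 0.7, "good",
        ifelse(r > 0.5, "moderate",
          ifelse(r > 0.1, "weak", "none")))))
}

#' Curve agreement between estimated and target moments
#'
#' Per-axis RMSE (Nm), Pearson r and r^2 plus the RMSE of the moment-norm
#' channel.  Correlations are banded as weak / moderate / good / very good
#' at the 0.1, 0.5, 0.7 and 0.9 cutpoints.  A zero-variance channel has an
#' undefined correlation, reported as `NA` (never as 0).
#'
#' @param estimated,target aligned [net_moment_series()] of equal length.
#' @return object of class `agreement_result`: data.frame `per_axis`
#'   (axis, rmse, r, r2, band) and `norm_rmse`.
#' @export
compare_curves <- function(estimated, target) {
  stopifnot(inherits(estimated, "net_moment_series"),
            inherits(target, "net_moment_series"))
  if (length(estimated$t) != length(target$t))
    stop("estimated and target series differ in length")
  r_of <- function(a, b) {
    if (stats::sd(a) == 0 || stats::sd(b) == 0) return(NA_real_)
    stats::cor(a, b)
  }
  ax <- c("x", "y", "z")
  rmse <- sqrt(colMeans((estimated$M - target$M)^2))
  r <- vapply(1:3, function(j) r_of(estimated$M[, j], target$M[, j]),
              numeric(1))
  per_axis <- data.frame(axis = ax, rmse = as.numeric(rmse), r = r,
                         r2 = r^2, band = r_band(r),
                         stringsAsFactors = FALSE)
  structure(list(per_axis = per_axis,
                 norm_rmse = sqrt(mean((estimated$norm - target$norm)^2))),
            class = "agreement_result")
}

#' Within-trial descriptives of the moment magnitude
#'
#' Mean, peak (max) and variance (the within-trial standard deviation,
#' n - 1 denominator) of the per-sample moment norm, with the trial's Borg
#' CR-10 score and checklist rank carried through.
#'
#' @param tr a [trial()].
#' @param moments the trial's [net_moment_series()].
#' @return object of class `task_descriptives`.
#' @export
task_descriptives <- function(tr, moments) {
  stopifnot(inherits(moments, "net_moment_series"))
  if (!length(moments$t)) stop("empty moment series")
  structure(list(trial = tr$id, mean = mean(moments$norm),
                 peak = max(moments$norm),
                 variance = stats::sd(moments$norm),
                 borg = tr$borg, checklist_rank = tr$checklist_rank),
            class = "task_descriptives")
}

split_descriptives <- function(v) {
  if (!length(v)) return(list(n = 0L, mean = NA_real_, peak = NA_real_,
                              variance = NA_real_))
  a <- abs(v)
  list(n = length(v), mean = mean(a), peak = max(a),
       variance = if (length(a) > 1) stats::sd(a) else NA_real_)
}

#' Split moment samples by movement direction
#'
#' Partitions the samples of one axis component by sign (e.g. flexion vs
#' extension for the mediolateral axis) and computes magnitude descriptives
#' within each sign class.  Samples that are exactly zero belong to neither
#' segment.  For `axis = "norm"` the nonnegative norm samples are split by
#' the sign of the dominant component (largest absolute value) at each
#' sample.
#'
#' @param moments a [net_moment_series()].
#' @param axis "x", "y", "z" or "norm".
#' @return object of class `direction_split` with `positive` and `negative`
#'   descriptive lists (`n`, `mean`, `peak`, `variance`; `NA` descriptives
#'   for an empty segment).
#' @export
direction_split <- function(moments, axis = c("x", "y", "z", "norm")) {
  stopifnot(inherits(moments, "net_moment_series"))
  axis <- match.arg(axis)
  if (axis == "norm") {
    dom <- max.col(abs(moments$M), ties.method = "first")
    sgn <- sign(moments$M[cbind(seq_along(dom), dom)])
    val <- moments$norm
  } else {
    val <- moments$M[, match(axis, c("x", "y", "z"))]
    sgn <- sign(val)
  }
  structure(list(axis = axis,
                 positive = split_descriptives(val[sgn > 0]),
                 negative = split_descriptives(val[sgn < 0])),
            class = "direction_split")
}

#' Paired comparison with a Shapiro-Wilk normality gate
#'
#' Computes the mean of the paired differences (MD), its standard deviation
#' (SDD), the t-based 95% confidence interval of the mean difference, and a
#' two-sided p-value.  The Shapiro-Wilk test on the paired differences
#' selects the test: paired t-test when the differences are compatible with
#' normality (p > alpha), Wilcoxon signed-rank otherwise.  The gate p-value
#' is recorded so either reading can be audited.
#'
#' The relative difference is reported two ways: as the mean of the
#' per-pair percentage differences (`rel_md`, with `rel_sdd` and CI) and as
#' 100 * MD / mean of the reference values (`rel_md_group`).
#'
#' @param values_a,values_b paired per-subject values; the difference is
#'   `values_a - values_b` and `values_b` is the reference for relative
#'   differences.
#' @param alpha significance level of the normality gate.
#' @return object of class `paired_comparison`.
#' @export
paired_comparison <- function(values_a, values_b, alpha = 0.05) {
  a <- as.numeric(values_a); b <- as.numeric(values_b)
  if (length(a) != length(b)) stop("paired vectors differ in length")
  if (length(a) < 3) stop("paired comparison requires n >= 3")
  d <- a - b
  n <- length(d)
  md <- mean(d)
  sdd <- stats::sd(d)
  ci <- md + c(-1, 1) * stats::qt(0.975, n - 1) * sdd / sqrt(n)
  if (sdd == 0) {
    p <- 1; test <- "paired_t"; sw <- NA_real_
    ci <- c(md, md)
  } else {
    sw <- stats::shapiro.test(d)$p.value
    if (sw > alpha) {
      p <- stats::t.test(a, b, paired = TRUE)$p.value
      test <- "paired_t"
    } else {
      p <- suppressWarnings(stats::wilcox.test(a, b, paired = TRUE)$p.value)
      test <- "wilcoxon"
    }
  }
  rel <- if (all(b != 0)) 100 * d / b else rep(NA_real_, n)
  rel_md <- mean(rel); rel_sdd <- stats::sd(rel)
  rel_ci <- if (!anyNA(rel) && rel_sdd > 0)
    rel_md + c(-1, 1) * stats::qt(0.975, n - 1) * rel_sdd / sqrt(n)
  else c(rel_md, rel_md)
  structure(list(n = n, MD = md, SDD = sdd, CI95 = ci, p = p,
                 test_used = test, normality_p = sw,
                 rel_md = rel_md, rel_sdd = rel_sdd, rel_CI95 = rel_ci,
                 rel_md_group = if (mean(b) != 0) 100 * md / mean(b)
                                else NA_real_),
            class = "paired_comparison")
}

#' @export
print.paired_comparison <- function(x, ...) {
  cat(sprintf(
    "paired comparison (n = %d, %s): MD = %.2f +/- %.2f [%.2f; %.2f], p = %.4g\n",
    x$n, x$test_used, x$MD, x$SDD, x$CI95[1], x$CI95[2], x$p))
  invisible(x)
}

# lumbar posture track of a trial: the trunk-relative-to-pelvis rotation
# from the sternum and sacrum orientations (constant mounting offsets drop
# out of posture *changes*, which is what the static criterion measures)
trial_posture_quat <- function(tr) {
  st <- tr$immu$sternum; sa <- tr$immu$sacrum
  if (is.null(st) || is.null(sa))
    stop(sprintf("trial '%s': posture metadata requires sternum and sacrum streams",
                 tr$id))
  quat_multiply(quat_conjugate(sa$quat), st$quat)
}

# posture excursion from the trial's first sample, degrees
trial_posture_angle <- function(tr) {
  q_rel <- trial_posture_quat(tr)
  quat_angle_deg(q_rel, q_rel[1, ])
}

# does the trial hold an (approximately) unchanged lumbar posture for at
# least min_s seconds?  A window is static when no sample departs from the
# window's first posture by more than tol_deg; the window must sit inside
# the task proper (the pre-trial stance is shorter than min_s anyway), and
# a held posture must differ from wherever the trial started (a working
# posture, not a return to quiet standing).
has_static_window <- function(tr, min_s = 4, tol_deg = 3) {
  q_rel <- trial_posture_quat(tr)
  w <- round(min_s / SAMPLE_DT)
  n <- nrow(q_rel)
  if (n <= w) return(FALSE)
  for (start in seq(1, n - w, by = 5L)) {
    idx <- start:(start + w)
    dev <- quat_angle_deg(q_rel[idx, ], q_rel[start, ])
    if (max(dev) <= tol_deg &&
        quat_angle_deg(q_rel[start, ], q_rel[1, ]) > tol_deg)
      return(TRUE)
  }
  FALSE
}

#' Select the light / heavy / static / dynamic work tasks
#'
#' Light and heavy tasks are the work tasks with the lowest and highest
#' physical-workload checklist rank (ties broken by Borg score, then trial
#' order).  The static task must hold the lumbar posture unchanged for at
#' least 4 s (lowest posture variability among candidates); the dynamic
#' task is the non-static task with the most varying lumbar posture.
#'
#' @param trials list of [trial()]s (work tasks are selected from them).
#' @param min_static_s minimum held-posture duration for a static task, s.
#' @param tol_deg posture tolerance defining "unchanged", degrees.
#' @return named list of trial ids: `light`, `heavy`, `static`, `dynamic`.
#' @export
select_tasks <- function(trials, min_static_s = 4, tol_deg = 3) {
  work <- Filter(function(tr) tr$kind == "work_task", trials)
  if (!length(work)) stop("no work tasks in trial list")
  ranks <- vapply(work, function(tr) as.numeric(tr$checklist_rank),
                  numeric(1))
  borg <- vapply(work, function(tr) as.numeric(tr$borg), numeric(1))
  if (anyNA(ranks)) stop("work tasks must carry checklist ranks")
  ids <- vapply(work, function(tr) tr$id, character(1))
  ord_light <- order(ranks, borg, seq_along(work))
  ord_heavy <- order(-ranks, -borg, seq_along(work))
  light <- ids[ord_light[1]]
  heavy <- ids[ord_heavy[1]]

  static_flag <- vapply(work, has_static_window, logical(1),
                        min_s = min_static_s, tol_deg = tol_deg)
  if (!any(static_flag)) stop("no static task (no >= 4 s held posture)")
  pv <- vapply(work, function(tr) stats::sd(trial_posture_angle(tr)),
               numeric(1))
  static <- ids[static_flag][which.min(pv[static_flag])]
  if (all(static_flag)) stop("no dynamic task (all postures held)")
  dyn_pool <- !static_flag
  dynamic <- ids[dyn_pool][which.max(pv[dyn_pool])]
  list(light = light, heavy = heavy, static = static, dynamic = dynamic)
}
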
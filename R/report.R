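# Report tables: per-subject agreement, error and task summaries plus the
# cohort-level paired comparisons, in the standard shapes used to report
# discriminant validity of ambulatory lumbar-load estimators.

#' Append row-wise mean and SD over subject columns
#'
#' Shared aggregation helper: every printed `mean` column of a report table
#' is the plain mean of its per-subject cells (missing subjects excluded),
#' and `sdd` the corresponding standard deviation.
#'
#' @param df data.frame whose per-subject cells sit in `cols`.
#' @param cols column names holding subject cells; default: all numeric
#'   columns.
#' @return `df` with `mean` and `sdd` columns appended.
#' @export
append_row_stats <- function(df, cols = NULL) {
  if (is.null(cols))
    cols <- names(df)[vapply(df, is.numeric, logical(1))]
  m <- as.matrix(df[, cols, drop = FALSE])
  df$mean <- rowMeans(m, na.rm = TRUE)
  df$sdd <- apply(m, 1, stats::sd, na.rm = TRUE)
  df
}

comparison_row <- function(pc) {
  if (is.null(pc))
    return(data.frame(n = NA_integer_, md = NA_real_, sdd = NA_real_,
                      ci_lo = NA_real_, ci_hi = NA_real_,
                      rel_md = NA_real_, rel_sdd = NA_real_,
                      rel_ci_lo = NA_real_, rel_ci_hi = NA_real_,
                      p = NA_real_, test = NA_character_,
                      normality_p = NA_real_, stringsAsFactors = FALSE))
  data.frame(n = pc$n, md = pc$MD, sdd = pc$SDD,
             ci_lo = pc$CI95[1], ci_hi = pc$CI95[2],
             rel_md = pc$rel_md, rel_sdd = pc$rel_sdd,
             rel_ci_lo = pc$rel_CI95[1], rel_ci_hi = pc$rel_CI95[2],
             p = pc$p, test = pc$test_used, normality_p = pc$normality_p,
             stringsAsFactors = FALSE)
}

# paired comparison across subjects of one per-subject statistic, NULL when
# the cohort is too small
cohort_comparison <- function(a, b) {
  ok <- is.finite(a) & is.finite(b)
  if (sum(ok) < 3) return(NULL)
  paired_comparison(a[ok], b[ok])
}

#' Assemble the validity report tables
#'
#' Builds, from per-subject pipeline results, the seven report tables:
#' movement-axis agreement per subject, RMSE per movement and axis, task
#' descriptives, light-vs-heavy and static-vs-dynamic paired comparisons of
#' the moment magnitude, and the two direction-split comparison tables.
#' Cohort comparisons require at least three subjects; with fewer they are
#' emitted with `NA` statistics.
#'
#' @param subject_results list of per-subject result sets as produced by
#'   [run_pipeline()].
#' @return object of class `validity_report` (list of data.frames in
#'   `$tables`, provenance in `$provenance`).
#' @export
build_report <- function(subject_results) {
  subs <- names(subject_results)
  first <- subject_results[[1]]

  wide <- function(get_rows, key_cols, value_col) {
    base <- get_rows(first)[, key_cols, drop = FALSE]
    for (s in subs) {
      rows <- get_rows(subject_results[[s]])
      stopifnot(nrow(rows) == nrow(base))
      base[[s]] <- rows[[value_col]]
    }
    append_row_stats(base, cols = subs)
  }

  agree_long <- function(res) {
    a <- res$agreement
    rbind(data.frame(movement = a$movement, axis = a$axis, metric = "r",
                     value = a$r, stringsAsFactors = FALSE),
          data.frame(movement = a$movement, axis = a$axis, metric = "r2",
                     value = a$r2, stringsAsFactors = FALSE))
  }
  tables <- list()
  tables$agreement_by_subject <-
    wide(agree_long, c("movement", "axis", "metric"), "value")
  tables$rmse_by_movement_axis <-
    wide(function(res) res$rmse, c("movement", "axis"), "rmse")

  sel_stat <- function(role, stat)
    vapply(subject_results,
           function(res) res$sel[res$sel$role == role, stat][1], numeric(1))
  task_rows <- lapply(c("light", "static", "heavy_dynamic"), function(cls) {
    roles <- if (cls == "heavy_dynamic") "heavy" else cls
    data.frame(
      task = cls,
      mean_mean = mean(sel_stat(roles, "mean")),
      mean_sd = stats::sd(sel_stat(roles, "mean")),
      peak_mean = mean(sel_stat(roles, "peak")),
      peak_sd = stats::sd(sel_stat(roles, "peak")),
      variance_mean = mean(sel_stat(roles, "variance")),
      variance_sd = stats::sd(sel_stat(roles, "variance")),
      rank_mean = mean(sel_stat(roles, "rank")),
      rank_sd = stats::sd(sel_stat(roles, "rank")),
      borg_mean = mean(sel_stat(roles, "borg")),
      borg_sd = stats::sd(sel_stat(roles, "borg")),
      stringsAsFactors = FALSE)
  })
  tables$task_descriptives <- do.call(rbind, task_rows)

  pair_table <- function(role_a, role_b) {
    rows <- lapply(c("mean", "peak", "variance", "borg"), function(par) {
      pc <- cohort_comparison(sel_stat(role_a, par), sel_stat(role_b, par))
      cbind(data.frame(parameter = par, stringsAsFactors = FALSE),
            comparison_row(pc))
    })
    do.call(rbind, rows)
  }
  tables$light_vs_heavy <- pair_table("heavy", "light")
  tables$static_vs_dynamic <- pair_table("dynamic", "static")

  dir_stat <- function(role, axis, direction, stat)
    vapply(subject_results, function(res) {
      d <- res$directions
      v <- d[d$role == role & d$axis == axis & d$direction == direction,
             stat]
      if (length(v)) v[1] else NA_real_
    }, numeric(1))
  dir_table <- function(role_a, role_b) {
    grid <- expand.grid(parameter = c("mean", "variance"),
                        direction = c("positive", "negative"),
                        axis = c("norm", "x", "y", "z"),
                        stringsAsFactors = FALSE)
    rows <- lapply(seq_len(nrow(grid)), function(i) {
      g <- grid[i, ]
      pc <- cohort_comparison(
        dir_stat(role_a, g$axis, g$direction, g$parameter),
        dir_stat(role_b, g$axis, g$direction, g$parameter))
      cbind(g, comparison_row(pc))
    })
    do.call(rbind, rows)
  }
  tables$direction_light_heavy <- dir_table("heavy", "light")
  tables$direction_static_dynamic <- dir_table("static", "dynamic")

  prov <- do.call(rbind, lapply(subs, function(s) {
    res <- subject_results[[s]]
    data.frame(subject = s,
               role = res$sel$role, trial = res$sel$trial,
               stringsAsFactors = FALSE)
  }))
  structure(list(tables = tables, provenance = prov,
                 n_subjects = length(subs), subjects = subs),
            class = "validity_report")
}

#' Write report tables as CSV files
#'
#' @param report a [build_report()] result.
#' @param dir output directory (created if needed).
#' @return invisibly, the written file paths.
#' @export
write_report <- function(report, dir) {
  stopifnot(inherits(report, "validity_report"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  files <- character(0)
  for (nm in names(report$tables)) {
    f <- file.path(dir, paste0(nm, ".csv"))
    utils::write.csv(report$tables[[nm]], f, row.names = FALSE)
    files <- c(files, f)
  }
  f <- file.path(dir, "provenance.csv")
  utils::write.csv(report$provenance, f, row.names = FALSE)
  invisible(c(files, f))
}

#' @export
print.validity_report <- function(x, ...) {
  cat(sprintf("validity_report: %d subject(s); tables: %s\n",
              x$n_subjects, paste(names(x$tables), collapse = ", ")))
  invisible(x)
}
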
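# Published reference values from a nine-subject field validation cohort of
# this estimation method (physically active workers performing their own
# work tasks).  Shipped as plain-text tables so that report arithmetic —
# row means, grand means, between-task differences — can be checked against
# the printed cohort summaries.

#' Reference cohort summary tables
#'
#' Returns the published per-subject and per-task summary values of a
#' nine-subject field validation cohort: movement-axis correlations between
#' the network-based and linked-segment-model moments (`agreement`),
#' per-movement per-axis RMSE values in Nm (`rmse`), and per-task-class
#' moment descriptives with checklist ranks and Borg CR-10 scores
#' (`tasks`).  One subject's known-load trial was unusable in the source
#' cohort; its cells are `NA` and are excluded from row means, as in the
#' original report.
#'
#' @return named list of three data.frames: `agreement`, `rmse`, `tasks`.
#' @export
reference_cohort_tables <- function() {
  dir <- system.file("extdata", "reference_cohort", package = "lumbarload")
  list(
    agreement = utils::read.csv(file.path(dir, "cohort_agreement.csv"),
                                stringsAsFactors = FALSE),
    rmse = utils::read.csv(file.path(dir, "cohort_rmse.csv"),
                           stringsAsFactors = FALSE),
    tasks = utils::read.csv(file.path(dir, "cohort_tasks.csv"),
                            stringsAsFactors = FALSE)
  )
}
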
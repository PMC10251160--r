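#' Full diagnostic report of a cohort
#'
#' Runs the complete pipeline — cycle-model tallies, both cost strategies
#' with their comparison, and accuracy under both reference standards — and
#' collects the results into one nested list ready for JSON serialisation.
#'
#' @param cohort A non-empty cohort tibble.
#' @param schedule A [cost_schedule()].
#' @param max_cycles Passed to [run_model()].
#' @return A list with sections `tallies`, `costs` (per-strategy reports,
#'   per-initial-state costs, comparison) and `accuracy` (confusion matrix
#'   and metrics per reference standard).
#' @seealso [write_report()]
#' @export
diagnostic_report <- function(cohort, schedule = cost_schedule(),
                              max_cycles = 3) {
  cohort <- as_cohort(cohort)
  stopifnot_cohort_nonempty(cohort, "diagnostic_report()")
  tally <- tally_cohort(cohort, max_cycles = max_cycles)
  fnac <- cost_fnac_first(cohort, schedule)
  sb <- cost_sb_only(cohort, schedule)

  report_of <- function(x) {
    list(
      strategy = x$strategy,
      total_cost = x$total_cost,
      cost_per_patient = x$cost_per_patient,
      sb_component_per_patient = x$sb_component_per_patient,
      sb_component_share = x$sb_component_share,
      per_initial_state_cost = stats::setNames(
        as.list(x$per_initial_state_cost$cost_per_patient),
        x$per_initial_state_cost$initial_state
      )
    )
  }
  accuracy_of <- function(reference) {
    cm <- confusion_matrix(cohort, reference)
    list(matrix = cm[c("tp", "fp", "tn", "fn")],
         metrics = as.list(accuracy_metrics(cm)[
           c("sensitivity", "specificity", "ppv", "npv", "fn_rate")]))
  }

  list(
    tallies = unclass(tally),
    costs = list(
      fnac_first = report_of(fnac),
      sb_only = report_of(sb),
      comparison = as.list(compare_strategies(cohort, schedule))
    ),
    accuracy = list(
      composite = accuracy_of("composite"),
      histology_only = accuracy_of("histology_only")
    )
  )
}

#' Write a diagnostic report as JSON
#'
#' @param report A list from [diagnostic_report()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_report <- function(report, path) {
  jsonlite::write_json(report, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
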
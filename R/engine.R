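#' Replay a cohort through the Markov cycle model
#'
#' The diagnostic work-up is modelled as a multistate transient (Markov
#' cohort) process: cycle 1 always starts with the first FNAC, which places
#' the lymphadenopathy in one of the four cytological states; each recorded
#' event (follow-up, repeat FNAC, surgical biopsy) closes a cycle and either
#' keeps the patient in the same state or moves them to the state returned by
#' the procedure.  Because the cohort records what actually happened, the
#' engine is a replay over recorded events with empirical (count-based)
#' transition rates; sampling lives in [simulate_cohort()].
#'
#' A trajectory concludes
#'
#' * at the cycle of its last recorded event (`histology` after a biopsy,
#'   `second_fnac` after a conclusive repeat aspiration, `follow_up_confirmed`
#'   after a follow-up visit);
#' * at cycle 1 with mode `fnac_sufficient` when there are no events and the
#'   first FNAC was malignant, or when the first FNAC was a metastasis (or
#'   lymphoma-relapse) call — cytology plus ICC is diagnostically definitive
#'   for these, and a subsequent biopsy only serves primary-site
#'   identification, not the diagnosis;
#' * at cycle 1 with mode `follow_up_confirmed` when a benign or ALUS first
#'   FNAC needed no further diagnostic procedure.
#'
#' @param cohort A cohort tibble (see [as_cohort()]).
#' @param max_cycles Maximum number of cycles a pathway may take (default 3).
#'   A pathway with events beyond this horizon is an error, not a silent
#'   truncation.
#' @return A tibble with one row per pathway: `id`, `initial_state`,
#'   `final_state` (after replaying all events), `concluded_at_cycle`,
#'   `conclusion_mode`, and `states` (list-column of the states occupied up to
#'   conclusion, one per cycle).
#' @examples
#' run_model(reference_cohort()) |> dplyr::count(concluded_at_cycle)
#' @export
run_model <- function(cohort, max_cycles = 3) {
  cohort <- as_cohort(cohort)
  if (max_cycles < 1) rlang::abort("max_cycles must be >= 1")
  feats <- pathway_features(cohort)
  if (any(feats$last_event_cycle > max_cycles)) {
    bad <- feats$id[feats$last_event_cycle > max_cycles]
    rlang::abort(paste0(
      "pathway(s) exceed max_cycles = ", max_cycles, ": ",
      paste(utils::head(bad, 5), collapse = ", ")
    ))
  }

  cytology_definitive <- feats$initial_state == "malignant" &
    !is.na(feats$malignant_subtype) &
    feats$malignant_subtype %in% cytology_definitive_subtypes()

  last_kind <- dplyr::if_else(feats$last_event_cycle == 3L,
                              feats$cycle3_event, feats$cycle2_event)

  concluded_at <- dplyr::if_else(cytology_definitive, 1L,
                                 feats$last_event_cycle)
  conclusion_mode <- dplyr::case_when(
    concluded_at == 1L & feats$initial_state == "malignant" ~ "fnac_sufficient",
    concluded_at == 1L ~ "follow_up_confirmed",
    last_kind == "surgical_biopsy" ~ "histology",
    last_kind == "repeat_fnac" ~ "second_fnac",
    .default = "follow_up_confirmed"
  )

  state2 <- advance_state(feats$initial_state, feats$cycle2_event,
                          feats$cycle2_result)
  states <- purrr::pmap(
    list(feats$initial_state, state2, feats$final_state, concluded_at),
    function(s1, s2, s3, k) c(s1, s2, s3)[seq_len(k)]
  )

  tibble::tibble(
    id = feats$id,
    initial_state = feats$initial_state,
    final_state = feats$final_state,
    concluded_at_cycle = concluded_at,
    conclusion_mode = conclusion_mode,
    states = states
  )
}

#' Tally a cohort after running the cycle model
#'
#' Aggregates a cohort (and its replayed trajectories) into the machine-
#' readable counts of the model: procedures performed, biopsy uptake by
#' initial state, state occupancy at entry and at conclusion, histological
#' outcome of the biopsied subset, and how many pathways concluded in each
#' cycle.
#'
#' @param cohort A cohort tibble.
#' @param trajectories Optional result of [run_model()] on the same cohort
#'   (recomputed when omitted); ids must align.
#' @param max_cycles Passed to [run_model()] when `trajectories` is omitted.
#' @return An object of class `cohort_tally`: a list of counts with
#'   [tidy()][generics::tidy] / [glance()][generics::glance] methods.
#' @examples
#' tally_cohort(reference_cohort())
#' @export
tally_cohort <- function(cohort, trajectories = NULL, max_cycles = 3) {
  cohort <- as_cohort(cohort)
  if (is.null(trajectories)) {
    trajectories <- run_model(cohort, max_cycles = max_cycles)
  }
  if (!setequal(trajectories$id, cohort$id) ||
      nrow(trajectories) != nrow(cohort)) {
    rlang::abort("trajectories and cohort ids do not match")
  }
  trajectories <- trajectories[match(cohort$id, trajectories$id), ]
  feats <- pathway_features(cohort)

  by_state <- function(x, values) {
    out <- tapply(values, factor(x, levels = dx_states()), sum, default = 0)
    stats::setNames(as.integer(out), dx_states())
  }
  concluded <- tabulate(trajectories$concluded_at_cycle, nbins = max_cycles)

  structure(list(
    n_lymphadenopathies = nrow(cohort),
    n_first_fnac = nrow(cohort),
    n_repeat_fnac = sum(feats$n_repeat_fnac),
    n_total_fnac = sum(feats$n_fnac),
    n_sb_patients = sum(feats$sb_patient),
    n_sb_procedures = sum(feats$n_sb_procedures),
    n_no_further_procedures = sum(feats$n_events == 0L),
    n_sb_malignant = sum(feats$sb_patient & feats$truth_label == "malignant"),
    n_sb_benign = sum(feats$sb_patient & feats$truth_label == "benign"),
    initial_state_counts = count_by_state(feats$initial_state),
    final_state_counts = count_by_state(feats$final_state),
    per_state_sb_counts = by_state(feats$initial_state, feats$sb_patient),
    per_state_fnac_counts = by_state(feats$initial_state, feats$n_fnac),
    concluded_by_cycle = stats::setNames(as.integer(concluded),
                                         paste0("cycle", seq_len(max_cycles)))
  ), class = "cohort_tally")
}

#' @export
print.cohort_tally <- function(x, ...) {
  n <- x$n_lymphadenopathies
  pct <- function(k) {
    if (n == 0) return("-")
    paste0(formatC(round_half_up(100 * k / n, 2), format = "f", digits = 2), "%")
  }
  cat("Cohort tally:", n, "lymphadenopathies\n")
  cat("  FNAC procedures:  ", x$n_total_fnac, " (", x$n_first_fnac, " first + ",
      x$n_repeat_fnac, " repeats)\n", sep = "")
  cat("  Biopsied:         ", x$n_sb_patients, " patients (", pct(x$n_sb_patients),
      "), ", x$n_sb_procedures, " procedures; histology ",
      x$n_sb_malignant, " malignant / ", x$n_sb_benign, " benign\n", sep = "")
  cat("  No further procedure after first FNAC: ",
      x$n_no_further_procedures, " (", pct(x$n_no_further_procedures), ")\n",
      sep = "")
  cat("  Initial states:   ",
      paste0(names(x$initial_state_counts), "=", x$initial_state_counts,
             collapse = " "), "\n", sep = "")
  cat("  Final states:     ",
      paste0(names(x$final_state_counts), "=", x$final_state_counts,
             collapse = " "), "\n", sep = "")
  cat("  Concluded by cycle: ",
      paste0(x$concluded_by_cycle, collapse = " / "), "\n", sep = "")
  invisible(x)
}

#' @export
tidy.cohort_tally <- function(x, ...) {
  per_state <- tibble::tibble(
    initial_state = dx_states(),
    n = as.integer(x$initial_state_counts),
    n_final = as.integer(x$final_state_counts),
    n_fnac = as.integer(x$per_state_fnac_counts),
    n_sb_patients = as.integer(x$per_state_sb_counts)
  )
  per_state
}

#' @export
glance.cohort_tally <- function(x, ...) {
  tibble::tibble(
    n_lymphadenopathies = x$n_lymphadenopathies,
    n_total_fnac = x$n_total_fnac,
    n_repeat_fnac = x$n_repeat_fnac,
    n_sb_patients = x$n_sb_patients,
    n_sb_procedures = x$n_sb_procedures,
    n_no_further_procedures = x$n_no_further_procedures,
    n_sb_malignant = x$n_sb_malignant,
    n_sb_benign = x$n_sb_benign
  )
}
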
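# Independent oracles, written in plain base R row-by-row loops so they share
# no code path with the package's vectorised dplyr pipelines.

# Total FNAC-first cost by iterating pathways and adding unit costs procedure
# by procedure, per the counting rules.
oracle_cost_fnac_first_total <- function(cohort, schedule) {
  total <- 0
  for (i in seq_len(nrow(cohort))) {
    row <- cohort[i, ]
    n_repeats <- 0L
    n_sb_events <- 0L
    for (cyc in c("cycle2", "cycle3")) {
      ev <- row[[paste0(cyc, "_event")]]
      if (!is.na(ev) && ev == "repeat_fnac") n_repeats <- n_repeats + 1L
      if (!is.na(ev) && ev == "surgical_biopsy") n_sb_events <- n_sb_events + 1L
    }
    n_fnac <- if (schedule$count_fnac_repeats) 1L + n_repeats else 1L
    n_sb <- if (schedule$count_sb_repeats) row$n_sb_procedures
            else as.integer(n_sb_events > 0)
    total <- total + schedule$fnac_unit_cost * n_fnac +
      schedule$sb_unit_cost * n_sb
  }
  total
}

# TP/FP/TN/FN counts by applying the classification rules row by row:
# the FNAC call is the last cytology category (positive when suspicious or
# malignant); truth is histology when biopsied, clinical follow-up otherwise.
oracle_confusion <- function(cohort, reference) {
  counts <- c(TP = 0L, FP = 0L, TN = 0L, FN = 0L)
  for (i in seq_len(nrow(cohort))) {
    row <- cohort[i, ]
    last_fnac <- row$initial_state
    last_sb <- NA_character_
    for (cyc in c("cycle2", "cycle3")) {
      ev <- row[[paste0(cyc, "_event")]]
      res <- row[[paste0(cyc, "_result")]]
      if (!is.na(ev) && ev == "repeat_fnac") last_fnac <- res
      if (!is.na(ev) && ev == "surgical_biopsy") last_sb <- res
    }
    biopsied <- !is.na(last_sb)
    if (reference == "histology_only" && !biopsied) next
    truth <- if (biopsied) last_sb else row$truth_label
    positive <- last_fnac %in% c("suspicious", "malignant")
    cls <- if (positive && truth == "malignant") "TP"
      else if (positive) "FP"
      else if (truth == "malignant") "FN"
      else "TN"
    counts[cls] <- counts[cls] + 1L
  }
  counts
}

# A small well-formed cohort used across validation tests.
tiny_cohort_df <- function() {
  tibble::tibble(
    id = c("a", "b", "c", "d"),
    initial_state = c("benign", "malignant", "alus", "benign"),
    malignant_subtype = c(NA, "nhl", NA, NA),
    cycle2_event = c(NA, "surgical_biopsy", NA, "repeat_fnac"),
    cycle2_result = c(NA, "malignant", NA, "suspicious"),
    cycle3_event = c(NA, NA, NA, "surgical_biopsy"),
    cycle3_result = c(NA, NA, NA, "benign"),
    truth_label = c("benign", "malignant", "benign", "benign"),
    truth_source = c("clinical_follow_up", "histology", "clinical_follow_up",
                     "histology"),
    n_sb_procedures = c(0L, 1L, 0L, 1L)
  )
}
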
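#' The built-in 535-lymphadenopathy reference cohort
#'
#' A consecutive 18-month series of 535 clinically suspicious
#' lymphadenopathies worked up with FNAC first (545 aspirations in total:
#' 535 first FNACs plus 10 repeats), 131 of which went on to surgical biopsy.
#' The cohort is reconstructed as disaggregated pathway records from the
#' published stratum counts, so the same one-row-per-lymphadenopathy table
#' drives the cycle model, the cost accumulation and the accuracy analysis.
#'
#' Composition by first-FNAC result:
#'
#' * **Malignant, 275** — 167 metastases (160 with the primary identified by
#'   cytology/ICC, needing no biopsy; 7 with unknown primary, biopsied),
#'   98 NHL and 10 HL (94 biopsied for primary histological confirmation, of
#'   which one needed the biopsy repeated because the wrong node was excised;
#'   14 relapses or surgery-contraindicated cases resolved by cytology alone).
#' * **Benign, 240** — 220 regressed on clinical follow-up; 10 repeated the
#'   FNAC (9 benign again, of which 1 was still biopsied and confirmed
#'   benign; 1 turned suspicious and the biopsy was benign — the series'
#'   single false positive); 10 went straight to biopsy on clinical/US
#'   suspicion (3 malignant — false negatives — and 7 benign).
#' * **Suspicious, 15** — all biopsied, all malignant.
#' * **ALUS, 5** — 2 resolved by follow-up; 3 biopsied (1 metastasis — a
#'   false negative — and 2 benign).
#'
#' Truth is histological for every biopsied pathway and clinical follow-up
#' otherwise (the composite reference standard).
#'
#' @return A validated cohort tibble with 535 rows (see [as_cohort()]).
#' @examples
#' tally_cohort(reference_cohort())
#' @export
reference_cohort <- function() {
  stratum <- function(n, initial_state, subtype = NA, c2e = NA, c2r = NA,
                      c3e = NA, c3r = NA, truth, source, n_sb = 0L) {
    tibble::tibble(
      initial_state = initial_state,
      malignant_subtype = as.character(subtype),
      cycle2_event = as.character(c2e), cycle2_result = as.character(c2r),
      cycle3_event = as.character(c3e), cycle3_result = as.character(c3r),
      truth_label = truth, truth_source = source,
      n_sb_procedures = as.integer(n_sb)
    )[rep(1L, n), ]
  }
  sb <- "surgical_biopsy"
  rf <- "repeat_fnac"
  fu <- "clinical_follow_up"
  hist <- "histology"

  strata <- list(
    # malignant first FNAC (275)
    stratum(160, "malignant", "metastasis_known_primary",
            truth = "malignant", source = fu),
    stratum(7, "malignant", "metastasis_unknown_primary",
            c2e = sb, c2r = "malignant", truth = "malignant", source = hist,
            n_sb = 1L),
    stratum(85, "malignant", "nhl",
            c2e = sb, c2r = "malignant", truth = "malignant", source = hist,
            n_sb = 1L),
    # the one biopsy repeated after excision of the wrong node
    stratum(1, "malignant", "nhl",
            c2e = sb, c2r = "malignant", truth = "malignant", source = hist,
            n_sb = 2L),
    stratum(8, "malignant", "hl",
            c2e = sb, c2r = "malignant", truth = "malignant", source = hist,
            n_sb = 1L),
    stratum(12, "malignant", "nhl", truth = "malignant", source = fu),
    stratum(2, "malignant", "hl", truth = "malignant", source = fu),
    # benign first FNAC (240)
    stratum(220, "benign", truth = "benign", source = fu),
    stratum(8, "benign", c2e = rf, c2r = "benign",
            truth = "benign", source = fu),
    stratum(1, "benign", c2e = rf, c2r = "benign",
            c3e = sb, c3r = "benign", truth = "benign", source = hist,
            n_sb = 1L),
    stratum(1, "benign", c2e = rf, c2r = "suspicious",
            c3e = sb, c3r = "benign", truth = "benign", source = hist,
            n_sb = 1L),
    stratum(7, "benign", c2e = sb, c2r = "benign",
            truth = "benign", source = hist, n_sb = 1L),
    stratum(3, "benign", c2e = sb, c2r = "malignant",
            truth = "malignant", source = hist, n_sb = 1L),
    # suspicious first FNAC (15)
    stratum(15, "suspicious", c2e = sb, c2r = "malignant",
            truth = "malignant", source = hist, n_sb = 1L),
    # ALUS first FNAC (5)
    stratum(2, "alus", truth = "benign", source = fu),
    stratum(1, "alus", c2e = sb, c2r = "malignant",
            truth = "malignant", source = hist, n_sb = 1L),
    stratum(2, "alus", c2e = sb, c2r = "benign",
            truth = "benign", source = hist, n_sb = 1L)
  )
  out <- dplyr::bind_rows(strata)
  out$id <- sprintf("LN%03d", seq_len(nrow(out)))
  as_cohort(out[c("id", setdiff(names(out), "id"))])
}
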
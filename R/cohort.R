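cohort_columns <- c(
  "id", "initial_state", "malignant_subtype",
  "cycle2_event", "cycle2_result", "cycle3_event", "cycle3_result",
  "truth_label", "truth_source", "n_sb_procedures"
)

#' Validate a cohort of lymphadenopathy pathways
#'
#' A cohort is a tibble with one row per lymphadenopathy describing its whole
#' diagnostic pathway: the first-FNAC result (`initial_state`, with a
#' `malignant_subtype` when malignant), up to two subsequent cycle events
#' (`cycle2_event`/`cycle3_event` with their procedure results), the
#' adjudicated truth (`truth_label` from `truth_source`), and the number of
#' surgical-biopsy procedures actually performed (`n_sb_procedures`, which can
#' exceed the number of biopsy events when a biopsy had to be repeated on the
#' correct node).
#'
#' `as_cohort()` checks every structural rule the downstream model relies on
#' and fails with row-level diagnostics when any is violated:
#'
#' * state, subtype, event, truth tokens must come from the model vocabulary;
#' * a `malignant_subtype` is present if and only if the first FNAC was
#'   malignant;
#' * `repeat_fnac`/`surgical_biopsy` events carry a result state, while
#'   `follow_up` (the patient "remains in the same state") and absent events
#'   carry none;
#' * a cycle-3 event requires a cycle-2 event (no gaps);
#' * surgical-biopsy results are histological, hence binary
#'   (`benign`/`malignant`), and the last biopsy result must agree with
#'   `truth_label`;
#' * `truth_source` is `histology` if and only if the pathway was biopsied,
#'   and `n_sb_procedures` is consistent with the biopsy events.
#'
#' @param x A data frame with the columns listed above (`n_sb_procedures` may
#'   be omitted; it then defaults to the number of biopsy events).
#' @return A validated tibble with class `fnac_cohort` prepended.
#' @seealso [load_cohort()], [reference_cohort()], [pathway_features()]
#' @export
as_cohort <- function(x) {
  x <- tibble::as_tibble(x)
  if (!"n_sb_procedures" %in% names(x)) {
    x$n_sb_procedures <- NA_integer_
  }
  missing_cols <- setdiff(cohort_columns, names(x))
  if (length(missing_cols) > 0) {
    rlang::abort(paste0("cohort is missing columns: ",
                        paste(missing_cols, collapse = ", ")))
  }
  x <- x[cohort_columns]
  chr_cols <- setdiff(cohort_columns, "n_sb_procedures")
  x[chr_cols] <- lapply(x[chr_cols], function(col) {
    col <- as.character(col)
    col[!is.na(col) & col == ""] <- NA_character_
    col
  })

  n_sb_events <- (!is.na(x$cycle2_event) & x$cycle2_event == "surgical_biopsy") +
    (!is.na(x$cycle3_event) & x$cycle3_event == "surgical_biopsy")
  x$n_sb_procedures <- as.integer(x$n_sb_procedures)
  x$n_sb_procedures[is.na(x$n_sb_procedures)] <- n_sb_events[is.na(x$n_sb_procedures)]

  problems <- character(0)
  flag <- function(bad, msg) {
    if (any(bad)) {
      rows <- which(bad)
      ids <- x$id[rows]
      shown <- utils::head(paste0(ids, " (row ", rows, ")"), 5)
      problems <<- c(problems, paste0(
        msg, ": ", paste(shown, collapse = ", "),
        if (sum(bad) > 5) paste0(" and ", sum(bad) - 5, " more") else ""
      ))
    }
  }

  if (nrow(x) > 0) {
    flag(is.na(x$id), "missing id")
    flag(duplicated(x$id) & !is.na(x$id), "duplicated id")
    flag(is.na(x$initial_state) | !x$initial_state %in% dx_states(),
         "unknown initial_state label")

    is_mal <- !is.na(x$initial_state) & x$initial_state == "malignant"
    flag(is_mal & is.na(x$malignant_subtype),
         "malignant first FNAC without malignant_subtype")
    flag(!is_mal & !is.na(x$malignant_subtype),
         "malignant_subtype on a non-malignant first FNAC")
    flag(!is.na(x$malignant_subtype) &
           !x$malignant_subtype %in% malignant_subtypes(),
         "unknown malignant_subtype")

    for (cyc in c("cycle2", "cycle3")) {
      ev <- x[[paste0(cyc, "_event")]]
      res <- x[[paste0(cyc, "_result")]]
      flag(!is.na(ev) & !ev %in% event_kinds(),
           paste0("unknown ", cyc, "_event kind"))
      needs <- !is.na(ev) & ev %in% c("repeat_fnac", "surgical_biopsy")
      flag(needs & is.na(res),
           paste0(cyc, " repeat_fnac/surgical_biopsy without a result"))
      flag(!needs & !is.na(res),
           paste0(cyc, " result on a follow-up or absent event"))
      flag(!is.na(res) & !res %in% dx_states(),
           paste0("unknown ", cyc, "_result state"))
      sb <- !is.na(ev) & ev == "surgical_biopsy"
      flag(sb & !is.na(res) & !res %in% truth_labels(),
           paste0(cyc, " biopsy result must be histological (benign/malignant)"))
    }
    flag(is.na(x$cycle2_event) & !is.na(x$cycle3_event),
         "cycle3 event without a cycle2 event")

    flag(is.na(x$truth_label) | !x$truth_label %in% truth_labels(),
         "unknown truth_label")
    flag(is.na(x$truth_source) | !x$truth_source %in% truth_sources(),
         "unknown truth_source")

    biopsied <- n_sb_events > 0
    flag(biopsied & x$truth_source != "histology",
         "biopsied pathway with truth_source other than histology")
    flag(!biopsied & x$truth_source == "histology",
         "truth_source histology without a surgical_biopsy event")
    flag(x$n_sb_procedures < n_sb_events,
         "n_sb_procedures smaller than the number of biopsy events")
    flag(!biopsied & x$n_sb_procedures > 0,
         "n_sb_procedures > 0 without a surgical_biopsy event")

    last_sb <- dplyr::if_else(
      !is.na(x$cycle3_event) & x$cycle3_event == "surgical_biopsy",
      x$cycle3_result,
      dplyr::if_else(!is.na(x$cycle2_event) & x$cycle2_event == "surgical_biopsy",
                     x$cycle2_result, NA_character_)
    )
    flag(!is.na(last_sb) & last_sb %in% truth_labels() &
           last_sb != x$truth_label,
         "truth_label disagrees with the last biopsy histology")
  }

  if (length(problems) > 0) {
    rlang::abort(c("invalid cohort pathway records", problems))
  }

  class(x) <- c("fnac_cohort", class(x))
  x
}

#' Read / write a cohort CSV
#'
#' The on-disk format is a plain UTF-8 CSV with one row per lymphadenopathy
#' and the columns documented in [as_cohort()]; absent events and subtypes are
#' empty cells.  `load_cohort()` validates on read and fails with row-level
#' diagnostics on malformed records; `write_cohort()` is its lossless inverse.
#'
#' @param path File path of the cohort CSV.
#' @param cohort A validated cohort tibble.
#' @return `load_cohort()` returns a validated cohort tibble;
#'   `write_cohort()` returns `cohort` invisibly.
#' @examples
#' path <- tempfile(fileext = ".csv")
#' write_cohort(reference_cohort(), path)
#' nrow(load_cohort(path))
#' @export
load_cohort <- function(path) {
  raw <- readr::read_csv(
    path,
    col_types = readr::cols(
      .default = readr::col_character(),
      n_sb_procedures = readr::col_integer()
    ),
    progress = FALSE
  )
  as_cohort(raw)
}

#' @rdname load_cohort
#' @export
write_cohort <- function(cohort, path) {
  cohort <- as_cohort(cohort)
  readr::write_csv(cohort, path, na = "")
  invisible(cohort)
}

#' Derived per-pathway features
#'
#' Augments a cohort with the quantities every downstream module consumes:
#'
#' * `n_fnac`: FNAC procedures (first aspiration plus repeats);
#' * `n_repeat_fnac`: repeat aspirations only;
#' * `sb_patient`: whether the lymphadenopathy was ever biopsied;
#' * `last_fnac_state`: the final cytology category (the last repeat-FNAC
#'   result when one exists, otherwise the first-FNAC result) — the "FNAC
#'   call" used for diagnostic accuracy;
#' * `final_state`: the state after replaying every recorded event through
#'   [advance_state()];
#' * `n_events`, `last_event_cycle`: pathway length bookkeeping (cycle 1 is
#'   the first FNAC; an event recorded for cycle *k* concluded cycle *k*).
#'
#' @param cohort A cohort tibble (validated with [as_cohort()] if needed).
#' @return The cohort with the derived columns appended.
#' @export
pathway_features <- function(cohort) {
  cohort <- as_cohort(cohort)
  rep2 <- !is.na(cohort$cycle2_event) & cohort$cycle2_event == "repeat_fnac"
  rep3 <- !is.na(cohort$cycle3_event) & cohort$cycle3_event == "repeat_fnac"
  sb2 <- !is.na(cohort$cycle2_event) & cohort$cycle2_event == "surgical_biopsy"
  sb3 <- !is.na(cohort$cycle3_event) & cohort$cycle3_event == "surgical_biopsy"

  state2 <- advance_state(cohort$initial_state, cohort$cycle2_event,
                          cohort$cycle2_result)
  state3 <- advance_state(state2, cohort$cycle3_event, cohort$cycle3_result)

  dplyr::mutate(
    cohort,
    n_repeat_fnac = as.integer(rep2) + as.integer(rep3),
    n_fnac = 1L + .data$n_repeat_fnac,
    sb_patient = sb2 | sb3,
    last_fnac_state = dplyr::case_when(
      rep3 ~ .data$cycle3_result,
      rep2 ~ .data$cycle2_result,
      .default = .data$initial_state
    ),
    final_state = state3,
    n_events = as.integer(!is.na(.data$cycle2_event)) +
      as.integer(!is.na(.data$cycle3_event)),
    last_event_cycle = dplyr::case_when(
      !is.na(.data$cycle3_event) ~ 3L,
      !is.na(.data$cycle2_event) ~ 2L,
      .default = 1L
    )
  )
}
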
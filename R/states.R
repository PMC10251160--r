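#' Diagnostic vocabulary of the lymph-node pathway model
#'
#' The model tracks each lymphadenopathy through four transient cytological
#' states following the Sydney System categories: `benign`, `alus` (atypical
#' lymphoid cells of uncertain significance), `suspicious` and `malignant`.
#' A malignant first cytology carries a subtype describing what the aspirate
#' showed.  Between cycles a lymphadenopathy experiences at most one event:
#' clinical follow-up, a repeat FNAC, or a surgical biopsy.
#'
#' @return A character vector of the valid tokens (lower-case, as used in the
#'   cohort CSV schema).
#' @seealso [advance_state()], [as_cohort()]
#' @export
dx_states <- function() {
  c("benign", "alus", "suspicious", "malignant")
}

#' @rdname dx_states
#' @export
malignant_subtypes <- function() {
  c("metastasis_known_primary", "metastasis_unknown_primary",
    "nhl", "hl", "lymphoma_relapse")
}

#' @rdname dx_states
#' @export
event_kinds <- function() {
  c("follow_up", "repeat_fnac", "surgical_biopsy")
}

#' @rdname dx_states
#' @export
truth_labels <- function() {
  c("benign", "malignant")
}

#' @rdname dx_states
#' @export
truth_sources <- function() {
  c("histology", "clinical_follow_up")
}

# States whose cytology call counts as "positive" for accuracy purposes.
positive_states <- function() c("suspicious", "malignant")

# Metastasis / relapse subtypes for which cytology (plus ICC) is considered
# diagnostically definitive even when a surgical biopsy follows.
cytology_definitive_subtypes <- function() {
  c("metastasis_known_primary", "metastasis_unknown_primary",
    "lymphoma_relapse")
}

#' Advance a diagnostic state through one cycle event
#'
#' The single transition rule of the cohort model: a repeat FNAC or a surgical
#' biopsy moves the lymphadenopathy into the state returned by that procedure,
#' while clinical follow-up (or no event) leaves it in its current state.
#'
#' Vectorised over all three arguments.
#'
#' @param state Character vector of current states (see [dx_states()]).
#' @param event_kind Character vector of event kinds (see [event_kinds()]);
#'   `NA` means no event occurred.
#' @param result_state Character vector of procedure results; required for
#'   `repeat_fnac` and `surgical_biopsy` events and must be `NA` otherwise.
#'
#' @return Character vector of the states after the event.
#' @examples
#' advance_state("benign", "surgical_biopsy", "malignant")
#' advance_state("benign", "follow_up")
#' @export
advance_state <- function(state, event_kind, result_state = NA_character_) {
  n <- max(length(state), length(event_kind), length(result_state))
  state <- rep_len(as.character(state), n)
  event_kind <- rep_len(as.character(event_kind), n)
  result_state <- rep_len(as.character(result_state), n)

  bad_state <- !is.na(state) & !state %in% dx_states()
  if (any(bad_state)) {
    rlang::abort(paste0("unknown state label: ",
                        paste(unique(state[bad_state]), collapse = ", ")))
  }
  bad_kind <- !is.na(event_kind) & !event_kind %in% event_kinds()
  if (any(bad_kind)) {
    rlang::abort(paste0("unknown event kind: ",
                        paste(unique(event_kind[bad_kind]), collapse = ", ")))
  }

  needs_result <- !is.na(event_kind) &
    event_kind %in% c("repeat_fnac", "surgical_biopsy")
  if (any(needs_result & is.na(result_state))) {
    rlang::abort("repeat_fnac and surgical_biopsy events require a result_state")
  }
  bad_result <- needs_result & !result_state %in% dx_states()
  if (any(bad_result)) {
    rlang::abort(paste0("unknown result state: ",
                        paste(unique(result_state[bad_result]), collapse = ", ")))
  }

  dplyr::if_else(needs_result, result_state, state)
}
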
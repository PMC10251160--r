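#' Classify pathways as TP/FP/TN/FN under a reference standard
#'
#' The cytology call of a pathway is its *final* FNAC category: positive when
#' the last FNAC (repeat if one was done, otherwise the first) read suspicious
#' or malignant, negative when it read benign or ALUS.  Truth comes from
#' histology whenever a biopsy was performed; under the `composite` reference
#' standard, unbiopsied pathways are adjudicated by clinical follow-up, while
#' the `histology_only` reference (the traditional gold standard) admits only
#' biopsied pathways and errors on any other — restricting accuracy to the
#' surgically verified subset is exactly the partial-verification bias the
#' composite standard mitigates.
#'
#' @param cohort A cohort tibble.
#' @param reference `"composite"` (default) or `"histology_only"`.
#' @return A tibble with `id`, `fnac_call` (`"positive"`/`"negative"`),
#'   `truth` and `class` (`"TP"`, `"FP"`, `"TN"`, `"FN"`).
#' @examples
#' classify_cases(reference_cohort()) |> dplyr::count(class)
#' @export
classify_cases <- function(cohort, reference = c("composite", "histology_only")) {
  reference <- rlang::arg_match(reference)
  cohort <- as_cohort(cohort)
  feats <- pathway_features(cohort)
  if (reference == "histology_only" && any(!feats$sb_patient)) {
    rlang::abort(paste0(
      "histology_only reference requested for unbiopsied pathway(s): ",
      paste(utils::head(feats$id[!feats$sb_patient], 5), collapse = ", ")
    ))
  }
  positive <- feats$last_fnac_state %in% positive_states()
  truly_malignant <- feats$truth_label == "malignant"
  tibble::tibble(
    id = feats$id,
    fnac_call = dplyr::if_else(positive, "positive", "negative"),
    truth = feats$truth_label,
    class = dplyr::case_when(
      positive & truly_malignant ~ "TP",
      positive & !truly_malignant ~ "FP",
      !positive & !truly_malignant ~ "TN",
      .default = "FN"
    )
  )
}

#' Confusion matrix of the cytology call against a reference standard
#'
#' Cross-tabulates [classify_cases()] over the evaluable pathways: the whole
#' cohort under the `composite` reference, or the biopsied subset under
#' `histology_only`.
#'
#' @inheritParams classify_cases
#' @return An object of class `confusion_matrix`: counts `tp`, `fp`, `tn`,
#'   `fn`, the `reference` used, and `n_evaluable`.
#' @examples
#' cm <- confusion_matrix(reference_cohort())
#' accuracy_metrics(cm)
#' @export
confusion_matrix <- function(cohort, reference = c("composite", "histology_only")) {
  reference <- rlang::arg_match(reference)
  cohort <- as_cohort(cohort)
  if (reference == "histology_only" && nrow(cohort) > 0) {
    feats <- pathway_features(cohort)
    cohort <- cohort[feats$sb_patient, ]
  }
  if (nrow(cohort) == 0) {
    cls <- character(0)
  } else {
    cls <- classify_cases(cohort, reference)$class
  }
  counts <- table(factor(cls, levels = c("TP", "FP", "TN", "FN")))
  structure(list(
    tp = as.integer(counts[["TP"]]),
    fp = as.integer(counts[["FP"]]),
    tn = as.integer(counts[["TN"]]),
    fn = as.integer(counts[["FN"]]),
    reference = reference,
    n_evaluable = length(cls)
  ), class = "confusion_matrix")
}

#' Diagnostic accuracy metrics
#'
#' Sensitivity `tp/(tp+fn)`, specificity `tn/(tn+fp)`, positive predictive
#' value `tp/(tp+fp)`, negative predictive value `tn/(tn+fn)` and the
#' false-negative rate `fn/(tp+fn) = 1 - sensitivity`, as unrounded
#' fractions.  A metric whose denominator is zero is undefined and reported
#' as `NA`, never as 0.
#'
#' @param cm A [confusion_matrix()].
#' @return A one-row tibble: `reference`, `n_evaluable`, `sensitivity`,
#'   `specificity`, `ppv`, `npv`, `fn_rate`.
#' @export
accuracy_metrics <- function(cm) {
  stopifnot(inherits(cm, "confusion_matrix"))
  ratio <- function(num, den) if (den > 0) num / den else NA_real_
  tibble::tibble(
    reference = cm$reference,
    n_evaluable = cm$n_evaluable,
    sensitivity = ratio(cm$tp, cm$tp + cm$fn),
    specificity = ratio(cm$tn, cm$tn + cm$fp),
    ppv = ratio(cm$tp, cm$tp + cm$fp),
    npv = ratio(cm$tn, cm$tn + cm$fn),
    fn_rate = ratio(cm$fn, cm$tp + cm$fn)
  )
}

#' @export
print.confusion_matrix <- function(x, ...) {
  cat("Confusion matrix (reference: ", x$reference, ", n = ", x$n_evaluable,
      ")\n", sep = "")
  m <- matrix(c(x$tp, x$fn, x$fp, x$tn), nrow = 2,
              dimnames = list(c("FNAC positive", "FNAC negative"),
                              c("malignant", "benign")))
  print(m)
  met <- accuracy_metrics(x)
  fmt <- function(v, d) {
    if (is.na(v)) "undefined" else
      paste0(formatC(round_half_up(100 * v, d), format = "f", digits = d), "%")
  }
  d <- if (x$reference == "composite") 1 else 2
  cat("  sensitivity ", fmt(met$sensitivity, d),
      ", specificity ", fmt(met$specificity, d),
      ", PPV ", fmt(met$ppv, d), ", NPV ", fmt(met$npv, d), "\n", sep = "")
  invisible(x)
}

#' @export
tidy.confusion_matrix <- function(x, ...) {
  tibble::tibble(
    reference = x$reference,
    class = c("TP", "FP", "TN", "FN"),
    count = c(x$tp, x$fp, x$tn, x$fn)
  )
}

#' @export
glance.confusion_matrix <- function(x, ...) {
  accuracy_metrics(x)
}
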
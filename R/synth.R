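#' Parameters of the synthetic-cohort generator
#'
#' [simulate_cohort()] emulates the statistical structure the analysis
#' assumes: initial states are multinomial with the observed initial
#' probabilities of the model; the post-initial event (none, follow-up
#' confirmation, repeat FNAC, surgical biopsy) is drawn from a per-state
#' conditional table; repeat-FNAC results come from a configurable cytology
#' table; and a planted ground truth drives every biopsy result (histology is
#' the gold standard in the simulation, so biopsies reveal the planted truth).
#' Truth is planted from the final cytology call through two mislabel rates,
#' which is what lets accuracy analyses on simulated cohorts recover known
#' error rates — including for unbiopsied cases that the composite reference
#' sees only through follow-up.
#'
#' Defaults are the empirical conditionals of the built-in reference cohort,
#' e.g. initial probabilities (0.5140, 0.4486, 0.0281, 0.0093) for
#' malignant/benign/suspicious/ALUS and, after a benign first FNAC,
#' follow-up 220/240, repeat FNAC 10/240, biopsy 10/240.
#'
#' @param n Cohort size.
#' @param initial_probs Named probabilities over [dx_states()] for the
#'   first-FNAC result; must sum to 1 (within 1e-12).
#' @param event_probs Named list, one distribution per state, over
#'   `c("none", "follow_up", "repeat_fnac", "surgical_biopsy")` (omitted
#'   kinds get probability 0); `"none"` means the first FNAC was sufficient
#'   and no further event was recorded.
#' @param repeat_result_probs Named list, one cytology distribution over
#'   [dx_states()] per pre-repeat state, for the result of a repeat FNAC.
#' @param post_repeat_sb_prob Named vector: probability, given the
#'   repeat-FNAC result state, that a surgical biopsy follows in the third
#'   cycle (default: 1/9 after a benign repeat, 1 after a suspicious repeat).
#' @param malignant_subtype_probs List with distributions `no_biopsy` and
#'   `biopsy` over [malignant_subtypes()] for the subtype of a malignant
#'   first FNAC, conditioned on whether the pathway is biopsied.
#' @param fnac_false_negative_rate Probability that a cytology-negative case
#'   (final call benign/ALUS) is truly malignant.  Default 4/244, the
#'   reference cohort's composite rate.
#' @param fnac_false_positive_rate Probability that a cytology-positive case
#'   (final call suspicious/malignant) is truly benign.  Default 1/291.
#' @param seed Optional integer seed; when given, [simulate_cohort()] is
#'   deterministic and leaves the global RNG state untouched.
#' @return An object of class `generator_params`.
#' @seealso [simulate_cohort()], [estimate_params()]
#' @export
generator_params <- function(
    n = 535,
    initial_probs = c(benign = 240, alus = 5, suspicious = 15,
                      malignant = 275) / 535,
    event_probs = list(
      benign = c(follow_up = 220, repeat_fnac = 10, surgical_biopsy = 10) / 240,
      alus = c(follow_up = 2, surgical_biopsy = 3) / 5,
      suspicious = c(surgical_biopsy = 1),
      malignant = c(none = 174, surgical_biopsy = 101) / 275
    ),
    repeat_result_probs = list(
      benign = c(benign = 0.9, suspicious = 0.1),
      alus = c(alus = 1),
      suspicious = c(suspicious = 1),
      malignant = c(malignant = 1)
    ),
    post_repeat_sb_prob = c(benign = 1 / 9, alus = 0, suspicious = 1,
                            malignant = 0),
    malignant_subtype_probs = list(
      no_biopsy = c(metastasis_known_primary = 160, nhl = 12, hl = 2) / 174,
      biopsy = c(metastasis_unknown_primary = 7, nhl = 86, hl = 8) / 101
    ),
    fnac_false_negative_rate = 4 / 244,
    fnac_false_positive_rate = 1 / 291,
    seed = NULL) {

  check_dist <- function(p, what, levels) {
    if (is.null(names(p)) || !all(names(p) %in% levels)) {
      rlang::abort(paste0(what, " must be named over: ",
                          paste(levels, collapse = ", ")))
    }
    if (any(p < 0 | p > 1)) {
      rlang::abort(paste0(what, " has probabilities outside [0, 1]"))
    }
    if (abs(sum(p) - 1) > 1e-12) {
      rlang::abort(paste0(what, " must sum to 1 (within 1e-12)"))
    }
    full <- stats::setNames(rep(0, length(levels)), levels)
    full[names(p)] <- p
    full
  }
  if (!is.numeric(n) || length(n) != 1 || n < 0 || n != round(n)) {
    rlang::abort("n must be a single non-negative integer")
  }
  kinds <- c("none", "follow_up", "repeat_fnac", "surgical_biopsy")
  initial_probs <- check_dist(initial_probs, "initial_probs", dx_states())
  event_probs <- purrr::imap(
    event_probs, ~ check_dist(.x, paste0("event_probs$", .y), kinds))
  if (!setequal(names(event_probs), dx_states())) {
    rlang::abort("event_probs needs one distribution per diagnostic state")
  }
  repeat_result_probs <- purrr::imap(
    repeat_result_probs,
    ~ check_dist(.x, paste0("repeat_result_probs$", .y), dx_states()))
  if (any(post_repeat_sb_prob < 0 | post_repeat_sb_prob > 1)) {
    rlang::abort("post_repeat_sb_prob must lie in [0, 1]")
  }
  malignant_subtype_probs <- purrr::imap(
    malignant_subtype_probs,
    ~ check_dist(.x, paste0("malignant_subtype_probs$", .y),
                 malignant_subtypes()))
  rates <- c(fnac_false_negative_rate, fnac_false_positive_rate)
  if (any(rates < 0 | rates > 1)) {
    rlang::abort("mislabel rates must lie in [0, 1]")
  }

  structure(list(
    n = as.integer(n),
    initial_probs = initial_probs,
    event_probs = event_probs[dx_states()],
    repeat_result_probs = repeat_result_probs,
    post_repeat_sb_prob = post_repeat_sb_prob,
    malignant_subtype_probs = malignant_subtype_probs,
    fnac_false_negative_rate = fnac_false_negative_rate,
    fnac_false_positive_rate = fnac_false_positive_rate,
    seed = seed
  ), class = "generator_params")
}

#' @export
print.generator_params <- function(x, ...) {
  cat("Synthetic-cohort generator parameters (n = ", x$n, ")\n", sep = "")
  cat("  initial probs: ",
      paste0(names(x$initial_probs), "=",
             formatC(x$initial_probs, format = "f", digits = 4),
             collapse = " "), "\n", sep = "")
  cat("  mislabel rates: false-negative ",
      formatC(x$fnac_false_negative_rate, format = "f", digits = 4),
      ", false-positive ",
      formatC(x$fnac_false_positive_rate, format = "f", digits = 4), "\n",
      sep = "")
  cat("  seed: ", if (is.null(x$seed)) "none" else x$seed, "\n", sep = "")
  invisible(x)
}

# Draw one category per row of `group`, using a per-group distribution table.
sample_by_group <- function(group, tables) {
  out <- rep(NA_character_, length(group))
  for (g in unique(group[!is.na(group)])) {
    idx <- which(!is.na(group) & group == g)
    p <- tables[[g]]
    keep <- p > 0
    out[idx] <- sample(names(p)[keep], length(idx), replace = TRUE,
                       prob = p[keep])
  }
  out
}

#' Simulate a synthetic cohort of diagnostic pathways
#'
#' Draws `params$n` pathways from the generative model described in
#' [generator_params()].  The output is a fully validated cohort tibble, so
#' it flows through [run_model()], the cost functions and
#' [confusion_matrix()] exactly like the reference cohort.
#'
#' @param params A [generator_params()] object.
#' @return A validated cohort tibble with `params$n` rows.
#' @examples
#' cohort <- simulate_cohort(generator_params(n = 200, seed = 1))
#' compare_strategies(cohort)
#' @export
simulate_cohort <- function(params) {
  stopifnot(inherits(params, "generator_params"))
  draw <- function() {
    n <- params$n
    states <- dx_states()
    init <- sample_by_group(rep("i", n), list(i = params$initial_probs))
    if (n == 0) init <- character(0)

    ev2 <- sample_by_group(init, params$event_probs)
    is_repeat <- ev2 == "repeat_fnac"
    res2_repeat <- rep(NA_character_, n)
    res2_repeat[is_repeat] <- sample_by_group(init[is_repeat],
                                              params$repeat_result_probs)

    sb3 <- rep(FALSE, n)
    if (any(is_repeat)) {
      p3 <- params$post_repeat_sb_prob[res2_repeat[is_repeat]]
      sb3[is_repeat] <- stats::runif(sum(is_repeat)) < p3
    }

    final_cyt <- dplyr::if_else(is_repeat, res2_repeat, init)
    positive <- final_cyt %in% positive_states()
    u <- stats::runif(n)
    truth <- dplyr::if_else(
      positive,
      dplyr::if_else(u < params$fnac_false_positive_rate, "benign", "malignant"),
      dplyr::if_else(u < params$fnac_false_negative_rate, "malignant", "benign")
    )

    sb2 <- ev2 == "surgical_biopsy"
    biopsied <- sb2 | sb3
    subtype <- rep(NA_character_, n)
    mal <- init == "malignant"
    subtype[mal & !biopsied] <- sample_by_group(
      rep("no_biopsy", sum(mal & !biopsied)), params$malignant_subtype_probs)
    subtype[mal & biopsied] <- sample_by_group(
      rep("biopsy", sum(mal & biopsied)), params$malignant_subtype_probs)

    tibble::tibble(
      id = sprintf("S%05d", seq_len(n)),
      initial_state = init,
      malignant_subtype = subtype,
      cycle2_event = dplyr::if_else(ev2 == "none", NA_character_, ev2),
      cycle2_result = dplyr::case_when(
        sb2 ~ truth,
        is_repeat ~ res2_repeat,
        .default = NA_character_
      ),
      cycle3_event = dplyr::if_else(sb3, "surgical_biopsy", NA_character_),
      cycle3_result = dplyr::if_else(sb3, truth, NA_character_),
      truth_label = truth,
      truth_source = dplyr::if_else(biopsied, "histology",
                                    "clinical_follow_up"),
      n_sb_procedures = as.integer(biopsied)
    )
  }
  out <- if (is.null(params$seed)) draw() else
    withr::with_seed(params$seed, draw())
  as_cohort(out)
}

#' Estimate generator parameters from a cohort
#'
#' Point estimates (empirical frequencies) of the generative parameters:
#' initial-state probabilities, per-state post-initial event distributions,
#' and the two mislabel rates — the probability that a cytology-negative
#' (resp. -positive) final call carries a malignant (resp. benign) truth
#' label.  This is the recovery harness for [simulate_cohort()]: estimating
#' from a large simulated cohort returns the generating values up to sampling
#' error.
#'
#' States never observed as an initial state get a degenerate `none` event
#' table, and a mislabel rate with no evaluable cases is `NA`.  Repeat-result
#' and subtype tables are left at their defaults (repeats are too rare to
#' estimate from a single cohort of realistic size).
#'
#' @param cohort A non-empty cohort tibble.
#' @return A [generator_params()] object with `n = nrow(cohort)` and
#'   `seed = NULL`.
#' @examples
#' estimate_params(reference_cohort())$initial_probs
#' @export
estimate_params <- function(cohort) {
  cohort <- as_cohort(cohort)
  stopifnot_cohort_nonempty(cohort, "estimate_params()")
  feats <- pathway_features(cohort)
  n <- nrow(feats)

  initial_probs <- count_by_state(feats$initial_state) / n

  ev <- dplyr::if_else(is.na(feats$cycle2_event), "none", feats$cycle2_event)
  kinds <- c("none", "follow_up", "repeat_fnac", "surgical_biopsy")
  event_probs <- purrr::map(stats::setNames(dx_states(), dx_states()),
    function(s) {
      sub <- ev[feats$initial_state == s]
      if (length(sub) == 0) return(c(none = 1))
      tab <- table(factor(sub, levels = kinds))
      stats::setNames(as.numeric(tab) / length(sub), kinds)
    })

  positive <- feats$last_fnac_state %in% positive_states()
  fnr <- if (any(!positive)) {
    mean(feats$truth_label[!positive] == "malignant")
  } else NA_real_
  fpr <- if (any(positive)) {
    mean(feats$truth_label[positive] == "benign")
  } else NA_real_

  params <- generator_params(
    n = n, initial_probs = initial_probs, event_probs = event_probs,
    fnac_false_negative_rate = if (is.na(fnr)) 0 else fnr,
    fnac_false_positive_rate = if (is.na(fpr)) 0 else fpr
  )
  params$fnac_false_negative_rate <- fnr
  params$fnac_false_positive_rate <- fpr
  params
}
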
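test_that("the generator is deterministic under a seed and leaves the RNG alone", {
  p <- generator_params(n = 250, seed = 42)
  a <- simulate_cohort(p)
  b <- simulate_cohort(p)
  expect_equal(a, b)

  set.seed(99)
  before <- runif(1)
  set.seed(99)
  invisible(simulate_cohort(p))
  expect_equal(runif(1), before)  # global stream untouched
})

test_that("simulated cohorts validate and flow through the whole pipeline", {
  co <- simulate_cohort(generator_params(n = 500, seed = 7))
  expect_s3_class(co, "fnac_cohort")
  expect_equal(nrow(co), 500L)
  expect_silent(run_model(co))
  expect_silent(cost_fnac_first(co))
  expect_silent(confusion_matrix(co, "composite"))
  biopsied <- pathway_features(co)$sb_patient
  expect_equal(co$truth_source == "histology", biopsied)
})

test_that("initial-state proportions match the multinomial within 3 binomial SE", {
  p <- generator_params(n = 535, seed = 2024)
  co <- simulate_cohort(p)
  obs <- table(factor(co$initial_state, levels = dx_states())) / 535
  for (s in dx_states()) {
    se <- sqrt(p$initial_probs[[s]] * (1 - p$initial_probs[[s]]) / 535)
    expect_lt(abs(obs[[s]] - p$initial_probs[[s]]), 3 * se + 1e-9)
  }
})

test_that("zero mislabel rates give a perfect classifier", {
  p <- generator_params(n = 2000, fnac_false_negative_rate = 0,
                        fnac_false_positive_rate = 0, seed = 5)
  co <- simulate_cohort(p)
  for (ref in c("composite", "histology_only")) {
    cm <- confusion_matrix(co, ref)
    expect_equal(cm$fp, 0L)
    expect_equal(cm$fn, 0L)
  }
})

test_that("invalid generator parameters are rejected", {
  expect_error(generator_params(initial_probs = c(benign = 0.6,
                                                  malignant = 0.5)),
               "sum to 1")
  expect_error(generator_params(fnac_false_negative_rate = 1.2), "\\[0, 1\\]")
  expect_error(generator_params(event_probs = list(
    benign = c(none = 1), alus = c(none = 1), suspicious = c(none = 1)
  )), "per diagnostic state")
  expect_error(generator_params(n = -1), "non-negative")
})

test_that("estimate_params recovers empirical frequencies exactly on the fixture", {
  est <- estimate_params(reference_cohort())
  expect_equal(est$initial_probs,
               c(benign = 240, alus = 5, suspicious = 15, malignant = 275) / 535)
  expect_equal(est$event_probs$benign[["follow_up"]], 0)  # regressors carry no event
  expect_equal(est$event_probs$benign[["none"]], 220 / 240)
  expect_equal(est$event_probs$malignant[["surgical_biopsy"]], 101 / 275)
  expect_equal(est$fnac_false_negative_rate, 4 / 244)
  expect_equal(est$fnac_false_positive_rate, 1 / 291)

  one <- estimate_params(as_cohort(tiny_cohort_df()[2, ]))
  expect_equal(one$initial_probs[["malignant"]], 1)  # degenerate one-hot
  expect_equal(one$event_probs$malignant[["surgical_biopsy"]], 1)
})

test_that("parameters are recovered from a large simulated cohort", {
  p <- generator_params(n = 50000, seed = 314)
  co <- simulate_cohort(p)
  est <- estimate_params(co)

  # initial probabilities and the well-populated event tables to 0.01
  expect_true(all(abs(est$initial_probs - p$initial_probs) < 0.01))
  for (s in c("benign", "malignant")) {
    expect_true(all(abs(est$event_probs[[s]] - p$event_probs[[s]]) < 0.01))
  }
  # sparse strata (ALUS, suspicious) within 3 binomial SE of their stratum size
  for (s in c("alus", "suspicious")) {
    n_s <- sum(co$initial_state == s)
    for (k in names(p$event_probs[[s]])) {
      pk <- p$event_probs[[s]][[k]]
      se <- sqrt(pk * (1 - pk) / n_s)
      expect_lt(abs(est$event_probs[[s]][[k]] - pk), 3 * se + 1e-9)
    }
  }

  # mislabel rates within 3 binomial SE of their denominators
  feats <- pathway_features(co)
  positive <- feats$last_fnac_state %in% c("suspicious", "malignant")
  se_fn <- sqrt(p$fnac_false_negative_rate *
                  (1 - p$fnac_false_negative_rate) / sum(!positive))
  se_fp <- sqrt(p$fnac_false_positive_rate *
                  (1 - p$fnac_false_positive_rate) / sum(positive))
  expect_lt(abs(est$fnac_false_negative_rate - p$fnac_false_negative_rate),
            3 * se_fn)
  expect_lt(abs(est$fnac_false_positive_rate - p$fnac_false_positive_rate),
            3 * se_fp)
})

test_that("simulated FNAC-first cost converges to its closed form", {
  p <- generator_params(n = 50000, seed = 2718)
  co <- simulate_cohort(p)
  got <- cost_fnac_first(co)$cost_per_patient

  # E[FNACs] = 1 + P(benign) x P(repeat | benign); P(biopsy) from the tables
  e_fnac <- 1 + p$initial_probs[["benign"]] *
    p$event_probs$benign[["repeat_fnac"]]
  p_sb_benign <- p$event_probs$benign[["surgical_biopsy"]] +
    p$event_probs$benign[["repeat_fnac"]] *
      (p$repeat_result_probs$benign[["benign"]] *
         p$post_repeat_sb_prob[["benign"]] +
       p$repeat_result_probs$benign[["suspicious"]] *
         p$post_repeat_sb_prob[["suspicious"]])
  p_sb <- p$initial_probs[["benign"]] * p_sb_benign +
    p$initial_probs[["alus"]] * p$event_probs$alus[["surgical_biopsy"]] +
    p$initial_probs[["suspicious"]] *
      p$event_probs$suspicious[["surgical_biopsy"]] +
    p$initial_probs[["malignant"]] *
      p$event_probs$malignant[["surgical_biopsy"]]
  expected <- 129.50 * e_fnac + 1666.64 * p_sb

  # 3 SE of the dominant (biopsy) component on n = 50,000
  tol <- 3 * 1666.64 * sqrt(p_sb * (1 - p_sb) / 50000)
  expect_lt(abs(got - expected), tol)
})
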
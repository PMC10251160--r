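test_that("the reference cohort reproduces every published stratum count", {
  co <- reference_cohort()
  feats <- pathway_features(co)
  expect_equal(nrow(co), 535L)

  # initial states and malignant subtypes
  expect_equal(sum(feats$initial_state == "malignant"), 275L)
  expect_equal(sum(feats$initial_state == "benign"), 240L)
  expect_equal(sum(feats$initial_state == "suspicious"), 15L)
  expect_equal(sum(feats$initial_state == "alus"), 5L)
  subtype <- feats$malignant_subtype[feats$initial_state == "malignant"]
  expect_equal(sum(grepl("^metastasis", subtype)), 167L)
  expect_equal(sum(subtype == "nhl"), 98L)
  expect_equal(sum(subtype == "hl"), 10L)

  # procedures
  expect_equal(sum(feats$n_fnac), 545L)
  expect_equal(sum(feats$n_repeat_fnac), 10L)
  expect_equal(sum(feats$sb_patient), 131L)
  expect_equal(sum(feats$n_sb_procedures), 132L)  # one biopsy repeated

  # malignant stratum: 7 + 94 biopsied, 160 metastases + 14 lymphomas
  # resolved by cytology alone
  mal <- feats[feats$initial_state == "malignant", ]
  expect_equal(sum(mal$sb_patient), 101L)
  expect_equal(sum(!mal$sb_patient & grepl("^metastasis", mal$malignant_subtype)),
               160L)
  expect_equal(sum(!mal$sb_patient & mal$malignant_subtype %in% c("nhl", "hl")),
               14L)
  expect_equal(sum(mal$n_sb_procedures == 2L), 1L)

  # benign stratum: 220 regressed, 10 repeats (9 benign / 1 suspicious),
  # 10 direct biopsies (3 malignant / 7 benign)
  ben <- feats[feats$initial_state == "benign", ]
  expect_equal(sum(ben$n_events == 0L), 220L)
  expect_equal(sum(ben$n_repeat_fnac), 10L)
  rep_res <- ben$cycle2_result[!is.na(ben$cycle2_event) &
                                 ben$cycle2_event == "repeat_fnac"]
  expect_equal(as.integer(table(rep_res)[c("benign", "suspicious")]), c(9L, 1L))
  direct_sb <- ben[!is.na(ben$cycle2_event) &
                     ben$cycle2_event == "surgical_biopsy", ]
  expect_equal(nrow(direct_sb), 10L)
  expect_equal(sum(direct_sb$truth_label == "malignant"), 3L)
  expect_equal(sum(ben$sb_patient), 12L)

  # suspicious: all biopsied malignant; ALUS: 2 follow-up, 3 biopsied (1 malignant)
  sus <- feats[feats$initial_state == "suspicious", ]
  expect_true(all(sus$sb_patient) && all(sus$truth_label == "malignant"))
  alus <- feats[feats$initial_state == "alus", ]
  expect_equal(sum(alus$sb_patient), 3L)
  expect_equal(sum(alus$truth_label == "malignant"), 1L)

  # truth source is histological exactly for the biopsied
  expect_equal(feats$truth_source == "histology", feats$sb_patient)
})

test_that("cohort CSV round-trips losslessly and tolerates an empty file", {
  co <- reference_cohort()
  path <- withr::local_tempfile(fileext = ".csv")
  write_cohort(co, path)
  back <- load_cohort(path)
  expect_equal(tibble::as_tibble(back), tibble::as_tibble(co))

  empty <- withr::local_tempfile(fileext = ".csv")
  writeLines(paste(names(co), collapse = ","), empty)
  expect_equal(nrow(load_cohort(empty)), 0L)
})

test_that("a minimal well-formed record loads with the expected features", {
  row <- tibble::tibble(
    id = "x", initial_state = "benign", malignant_subtype = NA,
    cycle2_event = "follow_up", cycle2_result = NA,
    cycle3_event = NA, cycle3_result = NA,
    truth_label = "benign", truth_source = "clinical_follow_up",
    n_sb_procedures = 0L
  )
  path <- withr::local_tempfile(fileext = ".csv")
  readr::write_csv(row, path, na = "")
  feats <- pathway_features(load_cohort(path))
  expect_equal(feats$n_fnac, 1L)
  expect_false(feats$sb_patient)
  expect_equal(feats$final_state, "benign")
})

test_that("malformed pathway records are rejected with row-level diagnostics", {
  base <- tiny_cohort_df()

  bad <- base; bad$initial_state[1] <- "weird"
  expect_error(as_cohort(bad), "unknown initial_state.*\\(row 1\\)")

  bad <- base; bad$cycle2_result[2] <- NA
  expect_error(as_cohort(bad), "without a result")

  bad <- base; bad$truth_source[2] <- "clinical_follow_up"
  expect_error(as_cohort(bad), "truth_source other than histology")

  bad <- base; bad$truth_source[1] <- "histology"
  expect_error(as_cohort(bad), "histology without a surgical_biopsy")

  bad <- base; bad$cycle2_result[1] <- "benign"
  expect_error(as_cohort(bad), "follow-up or absent event")

  bad <- base; bad$cycle3_event[1] <- "surgical_biopsy"
  bad$cycle3_result[1] <- "benign"
  expect_error(as_cohort(bad), "cycle3 event without a cycle2 event")

  bad <- base; bad$truth_label[4] <- "malignant"
  expect_error(as_cohort(bad), "disagrees with the last biopsy")

  bad <- base; bad$malignant_subtype[1] <- "nhl"
  expect_error(as_cohort(bad), "non-malignant first FNAC")

  bad <- base; bad$n_sb_procedures[2] <- 0L
  expect_error(as_cohort(bad), "smaller than the number of biopsy events")

  # biopsy histology must be binary
  bad <- base; bad$cycle2_result[2] <- "suspicious"
  expect_error(as_cohort(bad), "histological")
})

test_that("final state equals the initial state when no procedure changes it", {
  co <- reference_cohort()
  feats <- pathway_features(co)
  passive <- feats$n_events == 0L |
    (!is.na(feats$cycle2_event) & feats$cycle2_event == "follow_up" &
       is.na(feats$cycle3_event))
  expect_equal(feats$final_state[passive], feats$initial_state[passive])
})
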
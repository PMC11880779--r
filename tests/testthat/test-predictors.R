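# Predictor derivation: lookback windows, blood-test dual encoding, the
# missing-data policy and the symptomatic subcohort.

test_that("event-sourced binaries respect their half-open lookback windows", {
  p <- fixture_person(1)
  idx <- as.Date("2010-06-01")
  mk <- function(days_before, code = "rectal_bleed") {
    ev <- data.frame(person_id = 1, date = idx - days_before, code = code,
                     stringsAsFactors = FALSE)
    make_cohort(p, clinical_events = ev)
  }
  v <- derive_vector(1, idx, cohort = mk(100))
  expect_equal(v$rectal_bleed, 1L)
  expect_equal(derive_vector(1, idx, cohort = mk(800))$rectal_bleed, 0L)
  # the boundary: exactly 730 days before is inside, the index day is not
  expect_equal(derive_vector(1, idx, cohort = mk(730))$rectal_bleed, 1L)
  expect_equal(derive_vector(1, idx, cohort = mk(0))$rectal_bleed, 0L)

  # colonoscopy has a 10-year window; "ever" codes have none
  expect_equal(derive_vector(1, idx,
                             cohort = mk(5 * 365, "colonoscopy"))$colonoscopy_10y, 1L)
  expect_equal(derive_vector(1, idx,
                             cohort = mk(11 * 365, "colonoscopy"))$colonoscopy_10y, 0L)
  expect_equal(derive_vector(1, idx,
                             cohort = mk(11 * 365, "ibd"))$ibd_ever, 1L)
})

test_that("no events means all event-sourced binaries 0, baseline intact", {
  p <- fixture_person(1, bmi = 31.5, pgs = 1.25)
  v <- derive_vector(1, as.Date("2010-06-01"), cohort = make_cohort(p))
  cb <- default_codebook()
  ev_names <- cb$predictor[cb$source %in% c("events", "tests")]
  expect_true(all(unlist(v[ev_names]) == 0))
  expect_equal(v$bmi, 31.5)
  expect_equal(v$pgs, 1.25)
  expect_equal(v$age_at_index, 60)
  expect_equal(v$birth_year, 1950)
})

test_that("unknown event codes are reported and skipped", {
  p <- fixture_person(1)
  ev <- data.frame(person_id = 1, date = as.Date("2010-01-01"),
                   code = "made_up_code", stringsAsFactors = FALSE)
  coh <- make_cohort(p, clinical_events = ev)
  expect_message(v <- derive_vector(1, as.Date("2010-06-01"), cohort = coh),
                 "made_up_code")
  cb <- default_codebook()
  expect_true(all(unlist(v[cb$predictor[cb$source == "events"]]) == 0))
})

test_that("blood-test indicators use the measured/abnormal dual encoding", {
  idx <- as.Date("2010-06-01")
  tests <- data.frame(person_id = 1, date = idx - 100,
                      test_family = "inflammation", abnormal = 0L)
  expect_equal(blood_test_indicators(tests, idx),
               c(inflammation_measured = 1L, inflammation_abnormal = 0L,
                 iron_measured = 0L, iron_abnormal = 0L))
  tests2 <- data.frame(person_id = 1, date = idx - 50,
                       test_family = "iron", abnormal = 1L)
  out2 <- blood_test_indicators(tests2, idx)
  expect_equal(out2[["iron_measured"]], 1L)
  expect_equal(out2[["iron_abnormal"]], 1L)
  # abnormal outside the window counts for nothing
  tests3 <- data.frame(person_id = 1, date = idx - 800,
                       test_family = "iron", abnormal = 1L)
  expect_equal(unname(blood_test_indicators(tests3, idx)), rep(0L, 4))
  # a flagged result with no family label is a data error
  tests4 <- data.frame(person_id = 1, date = idx - 10,
                       test_family = NA_character_, abnormal = 1L)
  expect_error(blood_test_indicators(tests4, idx), "no test_family")
})

test_that("abnormal implies measured across a whole simulated cohort", {
  d <- medium_landmark()
  expect_true(all(d$inflammation_abnormal <= d$inflammation_measured))
  expect_true(all(d$iron_abnormal <= d$iron_measured))
})

test_that("missing policy: separate category for smoking/ethnicity, complete case otherwise", {
  p <- rbind(fixture_person(1, smoking_status = NA_character_),
             fixture_person(2, alcohol = NA_real_),
             fixture_person(3))
  coh <- make_cohort(p)
  rows <- data.frame(person_id = 1:3,
                     index_date = rep(as.Date("2010-06-01"), 3))
  pred <- derive_predictor_table(rows, coh)
  res <- apply_missing_policy(pred)
  expect_equal(res$keep_rows, c(TRUE, FALSE, TRUE))
  expect_equal(res$n_dropped, 1L)
  expect_equal(as.character(res$data$smoking_status[1]), "missing")
  # nothing missing: values unchanged
  expect_equal(as.character(res$data$ethnicity), c("white", "white"))
  expect_equal(res$data$bmi, c(25, 25))
})

test_that("derivation is pure: identical inputs give identical vectors", {
  p <- fixture_person(1)
  ev <- data.frame(person_id = 1, date = as.Date("2009-10-01"),
                   code = "constipation", stringsAsFactors = FALSE)
  coh <- make_cohort(p, clinical_events = ev)
  v1 <- derive_vector(1, as.Date("2010-06-01"), cohort = coh)
  v2 <- derive_vector(1, as.Date("2010-06-01"), cohort = coh)
  expect_identical(v1, v2)
})

test_that("symptomatic subcohort filters rows by qualifying symptoms", {
  d <- medium_landmark()
  sub <- symptomatic_subcohort(d, criteria = c("constipation",
                                               "rectal_bleed"))
  expect_true(all(sub$constipation == 1 | sub$rectal_bleed == 1))
  expect_true(all(rownames(sub) %in% rownames(d)))
  # every row with constipation recorded is retained
  expect_equal(sum(sub$constipation == 1), sum(d$constipation == 1))

  # widening the criteria can only grow the subcohort
  all_sym <- set_predictors(default_codebook(), "symptoms")
  sub_all <- symptomatic_subcohort(d, criteria = all_sym)
  expect_gte(nrow(sub_all), nrow(sub))
  expect_true(all(rownames(sub) %in% rownames(sub_all)))

  # fatigue alone does not qualify in the sensitivity definition
  sub2 <- symptomatic_subcohort(d, mode = "any_except_fatigue")
  others <- setdiff(intersect(all_sym, names(d)), "fatigue")
  only_fatigue <- d$fatigue == 1 &
    rowSums(as.matrix(d[, others])) == 0
  expect_false(any(rownames(d)[only_fatigue] %in% rownames(sub2)))

  expect_error(symptomatic_subcohort(d, criteria = character(0)),
               "non-empty")
  expect_error(symptomatic_subcohort(d, criteria = "bmi"), "symptom")
  no_sym <- d[rowSums(as.matrix(d[, intersect(all_sym, names(d))])) == 0, ]
  expect_warning(symptomatic_subcohort(no_sym, criteria = "rectal_bleed"),
                 "empty")
})

test_that("stepwise selection over symptoms finds the true signal symptom", {
  # rectal bleeding is the only symptom with a true effect in the default
  # generator; selection over the 16 symptom candidates should retain it
  d <- medium_landmark()
  sel <- select_symptom_criteria(d)
  expect_true("rectal_bleed" %in% sel)

  expect_error(select_symptom_criteria(d[d$event == 0, ][1:50, ]),
               "no events")
})

test_that("null symptom effects lead to empty or near-empty selection", {
  cfg <- sim_config(n_persons = 4000, seed = 19,
                    true_log_hrs = c(pgs = log(1.4)))
  d <- build_super_landmark(simulate_cohort(cfg), ages = 60:62)
  sel <- suppressWarnings(select_symptom_criteria(d))
  # under the null, AIC retains a term with probability P(chisq_1 > 2),
  # about 0.16, so of 16 noise candidates roughly 2-3 survive by chance
  expect_lte(length(sel), 5)
  expect_lt(length(sel), 16 / 2)
})
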
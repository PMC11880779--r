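# Landmark construction: coverage-run merging, index dates, eligibility,
# outcome ascertainment and stacking.

test_that("coverage runs merge across tolerated gaps and split on larger ones", {
  empty <- coverage_runs(data.frame(start_date = as.Date(character(0)),
                                    end_date = as.Date(character(0))))
  expect_equal(nrow(empty), 0)

  # gap of exactly 90 days (Mar 1 -> May 30) does not break continuity
  iv <- data.frame(start_date = as.Date(c("2010-01-01", "2010-05-30")),
                   end_date = as.Date(c("2010-03-01", "2010-12-01")))
  runs <- coverage_runs(iv)
  expect_equal(nrow(runs), 1)
  expect_equal(runs$start_date, as.Date("2010-01-01"))
  expect_equal(runs$end_date, as.Date("2010-12-01"))

  # 91-day gap splits
  iv$start_date[2] <- as.Date("2010-05-31")
  expect_equal(as.numeric(iv$start_date[2] - iv$end_date[1]), 91)
  expect_equal(nrow(coverage_runs(iv)), 2)

  bad <- data.frame(start_date = as.Date("2010-02-01"),
                    end_date = as.Date("2010-01-01"))
  expect_error(coverage_runs(bad), "end_date before start_date")
})

test_that("index date is the first of the month of the landmark birthday", {
  expect_equal(index_date(as.Date("1950-07-15"), 60), as.Date("2010-07-01"))
  expect_equal(index_date(as.Date("1950-07-01"), 60), as.Date("2010-07-01"))
  # leap-day birthday anniversaries on 1 March in non-leap years
  expect_equal(index_date(as.Date("1952-02-29"), 41), as.Date("1993-03-01"))
  expect_equal(index_date(as.Date("1952-02-29"), 40), as.Date("1992-02-01"))
})

test_that("eligibility follows the alive / coverage / prior-cancer rules", {
  # prior NMSC (at age 50) does not exclude at landmark 55; prior CRC does
  p <- rbind(fixture_person(1), fixture_person(2))
  reg <- reg_events(c(1, 2), c("2000-08-01", "2000-08-01"),
                    c("nmsc", "crc"))
  coh <- make_cohort(p, registry = reg)
  e1 <- is_eligible(1, 55, coh)
  expect_true(e1$eligible)
  e2 <- is_eligible(2, 55, coh)
  expect_false(e2$eligible)
  expect_equal(e2$reason, "prior_cancer")

  # 150 covered days in the lookback window fail the 183-day minimum
  p3 <- fixture_person(3)
  cov3 <- data.frame(person_id = 3,
                     start_date = as.Date("2004-06-01"),
                     end_date = as.Date("2004-10-29"))
  expect_equal(as.numeric(cov3$end_date - cov3$start_date) + 1, 151)
  coh3 <- make_cohort(p3, coverage = cov3)
  e3 <- is_eligible(3, 55, coh3)  # index 2005-06-01, window covers the run
  expect_false(e3$eligible)
  expect_equal(e3$reason, "coverage")

  # 183 covered days suffice
  cov4 <- data.frame(person_id = 3,
                     start_date = as.Date("2004-06-01"),
                     end_date = as.Date("2004-11-30"))
  e4 <- is_eligible(3, 55, make_cohort(p3, coverage = cov4))
  expect_true(e4$eligible)

  # the stricter rule also requires coverage up to the index date itself
  cov5 <- data.frame(person_id = 3,
                     start_date = as.Date("2003-09-01"),
                     end_date = as.Date("2004-09-01"))  # ends 9 months early
  expect_true(is_eligible(3, 55, make_cohort(p3, coverage = cov5))$eligible)
  e5b <- is_eligible(3, 55, make_cohort(p3, coverage = cov5),
                     require_coverage_to_index = TRUE)
  expect_false(e5b$eligible)
  expect_equal(e5b$reason, "coverage")

  # dead before the index date
  reg5 <- reg_events(1, "2004-01-01", "death")
  e5 <- is_eligible(1, 55, make_cohort(fixture_person(1), registry = reg5))
  expect_false(e5$eligible)
  expect_equal(e5$reason, "not_alive")

  expect_error(is_eligible(99, 55, coh), "person_id not present")
})

test_that("outcomes take the earliest of the five censoring candidates", {
  p <- fixture_person(1)  # index at age 60: 2010-06-01
  idx <- as.Date("2010-06-01")

  reg <- reg_events(1, idx + 400, "crc")
  o <- outcome_at(1, idx, make_cohort(p, registry = reg))
  expect_equal(o[c("event", "time_days", "censor_reason")],
               list(event = 1L, time_days = 400, censor_reason = "crc"))

  reg <- reg_events(1, c(idx + 300, idx + 500), c("other_cancer", "crc"))
  o <- outcome_at(1, idx, make_cohort(p, registry = reg))
  expect_equal(o[c("event", "time_days", "censor_reason")],
               list(event = 0L, time_days = 300,
                    censor_reason = "other_cancer"))

  # NMSC is ignored entirely
  reg <- reg_events(1, c(idx + 100, idx + 400), c("nmsc", "crc"))
  o <- outcome_at(1, idx, make_cohort(p, registry = reg))
  expect_equal(o$censor_reason, "crc")
  expect_equal(o$time_days, 400)

  # nothing happens, records ample: administrative censoring at 730
  o <- outcome_at(1, idx, make_cohort(p))
  expect_equal(o[c("event", "time_days", "censor_reason")],
               list(event = 0L, time_days = 730,
                    censor_reason = "admin_730"))

  # primary-care records ended before the index: censored at pc_end + 2y
  p2 <- fixture_person(1, pc_end_date = "2010-01-01")
  o <- outcome_at(1, idx, make_cohort(p2))
  expect_equal(o$censor_reason, "pc_end_plus_2y")
  expect_equal(o$time_days, as.numeric(as.Date("2010-01-01") - idx) + 730)

  # death within the window
  reg <- reg_events(1, idx + 200, "death")
  o <- outcome_at(1, idx, make_cohort(p, registry = reg))
  expect_equal(o$censor_reason, "death")
  expect_equal(o$time_days, 200)

  # same-day CRC diagnosis is an event at time 1, not a prior cancer
  reg <- reg_events(1, idx, "crc")
  o <- outcome_at(1, idx, make_cohort(p, registry = reg))
  expect_equal(o[c("event", "time_days")], list(event = 1L, time_days = 1))
})

test_that("stacking produces one row per eligible person-age", {
  # coverage only intersects the lookback windows of ages 60-64:
  # the age-59 window ends 2009-05-31, the age-65 window starts 2013-06-02
  p <- fixture_person(1)  # born 1950-06-15
  cov <- data.frame(person_id = 1, start_date = as.Date("2009-06-02"),
                    end_date = as.Date("2013-06-01"))
  coh <- make_cohort(p, coverage = cov)
  d <- build_super_landmark(coh, ages = 40:74, codebook = NULL)
  expect_equal(nrow(d), 5)
  expect_equal(d$landmark_age, 60:64)

  # CRC at age 62.5 (2012-12-15): rows at 60, 61, 62; event at 61 and 62
  p2 <- fixture_person(2, pc_end_date = "2018-06-30")
  reg <- reg_events(2, "2012-12-15", "crc")
  coh2 <- make_cohort(p2, registry = reg)
  d2 <- build_super_landmark(coh2, ages = 55:74, codebook = NULL)
  expect_true(all(d2$landmark_age <= 62))
  r61 <- d2[d2$landmark_age == 61, ]
  r62 <- d2[d2$landmark_age == 62, ]
  r60 <- d2[d2$landmark_age == 60, ]
  expect_equal(r61$event, 1L)
  expect_equal(r62$event, 1L)
  expect_equal(r60$event, 0L)  # CRC falls beyond 730 days from age-60 index
  expect_equal(r62$time_days,
               as.numeric(as.Date("2012-12-15") - as.Date("2012-06-01")))

  expect_equal(nrow(build_super_landmark(coh, ages = integer(0),
                                         codebook = NULL)), 0)
  expect_error(build_super_landmark(make_cohort(p[0, ]), ages = 60),
               "empty cohort")
})

test_that("landmark rows respect death, prior cancer and censoring minima", {
  cfg <- sim_config(n_persons = 500, seed = 41)
  coh <- simulate_cohort(cfg)
  d <- build_super_landmark(coh, ages = 55:70, codebook = NULL)
  reg <- coh$registry
  # no index date at/after death or after a prior non-NMSC cancer
  for (ty in c("death", "crc", "other_cancer")) {
    first <- stats::aggregate(date ~ person_id, reg[reg$event_type == ty, ],
                              min)
    m <- match(d$person_id, first$person_id)
    ok <- is.na(m) | d$index_date <= first$date[m]
    expect_true(all(ok))
  }
  # brute-force recomputation of (event, time, reason) for every row
  pc_end <- coh$persons$pc_end_date[match(d$person_id,
                                          coh$persons$person_id)]
  bf_time <- numeric(nrow(d))
  bf_reason <- character(nrow(d))
  for (k in seq_len(nrow(d))) {
    pid <- d$person_id[k]
    idx <- d$index_date[k]
    r <- reg[reg$person_id == pid & reg$event_type != "nmsc", ]
    cand <- c(crc = if (any(r$event_type == "crc"))
                as.numeric(min(r$date[r$event_type == "crc"]) - idx)
              else Inf,
              other_cancer = if (any(r$event_type == "other_cancer"))
                as.numeric(min(r$date[r$event_type == "other_cancer"]) - idx)
              else Inf,
              death = if (any(r$event_type == "death"))
                as.numeric(min(r$date[r$event_type == "death"]) - idx)
              else Inf,
              pc_end_plus_2y = as.numeric(pc_end[k] - idx) + 730,
              admin_730 = 730)
    cand <- pmax(cand, 1)
    bf_time[k] <- min(cand)
    bf_reason[k] <- names(cand)[which.min(cand)]
  }
  expect_equal(d$time_days, bf_time)
  expect_equal(d$censor_reason, bf_reason)
  expect_equal(d$event, as.integer(bf_reason == "crc"))
})

test_that("removing coverage gaps never removes rows", {
  cfg <- sim_config(n_persons = 400, seed = 43, coverage_gap_rate = 0.3)
  coh <- simulate_cohort(cfg)
  d1 <- build_super_landmark(coh, ages = 55:70, codebook = NULL)
  # collapse each person's coverage to one gap-free interval
  cov <- stats::aggregate(cbind(start = as.numeric(start_date),
                                end = as.numeric(end_date)) ~ person_id,
                          coh$coverage, function(x) x)
  gapless <- data.frame(
    person_id = unique(coh$coverage$person_id),
    start_date = as.Date(stats::aggregate(start_date ~ person_id,
                                          coh$coverage, min)$start_date),
    end_date = as.Date(stats::aggregate(end_date ~ person_id,
                                        coh$coverage, max)$end_date))
  coh2 <- coh
  coh2$coverage <- gapless
  d2 <- build_super_landmark(coh2, ages = 55:70, codebook = NULL)
  k1 <- paste(d1$person_id, d1$landmark_age)
  k2 <- paste(d2$person_id, d2$landmark_age)
  expect_true(all(k1 %in% k2))
  expect_gte(nrow(d2), nrow(d1))
  # person-age pairs unique in the stack
  expect_false(anyDuplicated(k2) > 0)
})
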
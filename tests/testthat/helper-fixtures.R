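# Hand-built cohort fixtures and cached simulated datasets shared across
# test files (the cache lives for one test run).

fixture_person <- function(person_id, birth_date = "1950-06-15",
                           pc_end_date = "2018-06-30", ...) {
  p <- data.frame(
    person_id = person_id, sex = "female",
    birth_date = as.Date(birth_date), baseline_date = as.Date("2008-01-01"),
    ethnicity = "white", smoking_status = "never", townsend = 0, bmi = 25,
    alcohol = 1, education = "gcse", fibre = 10, processed_meat = 1,
    red_meat = 2, pgs = 0, fam_hist_bowel = 0L, fam_hist_breast = 0L,
    fam_hist_lung = 0L, screening_eligible = 1L, multimorbidity_score = 0,
    pc_end_date = as.Date(pc_end_date), stringsAsFactors = FALSE)
  over <- list(...)
  for (nm in names(over)) p[[nm]] <- over[[nm]]
  p
}

# Assemble a raw_cohort from parts; coverage defaults to one unbroken run
# from well before any index date to the primary-care end date.
make_cohort <- function(persons, coverage = NULL, clinical_events = NULL,
                        blood_tests = NULL, registry = NULL) {
  if (is.null(coverage))
    coverage <- data.frame(person_id = persons$person_id,
                           start_date = rep(as.Date("1990-01-01"),
                                            nrow(persons)),
                           end_date = persons$pc_end_date)
  if (is.null(clinical_events))
    clinical_events <- data.frame(person_id = integer(0),
                                  date = as.Date(character(0)),
                                  code = character(0))
  if (is.null(blood_tests))
    blood_tests <- data.frame(person_id = integer(0),
                              date = as.Date(character(0)),
                              test_family = character(0),
                              abnormal = integer(0))
  if (is.null(registry))
    registry <- data.frame(person_id = integer(0),
                           date = as.Date(character(0)),
                           event_type = character(0))
  structure(list(persons = persons, coverage = coverage,
                 clinical_events = clinical_events,
                 blood_tests = blood_tests, registry = registry),
            class = "raw_cohort")
}

reg_events <- function(person_id, dates, types) {
  data.frame(person_id = person_id, date = as.Date(dates),
             event_type = types, stringsAsFactors = FALSE)
}

.fixture_cache <- new.env(parent = emptyenv())

cached_fixture <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache))
    assign(key, force(expr), envir = .fixture_cache)
  get(key, envir = .fixture_cache)
}

# Medium cohort under the default ground-truth configuration: used for
# selection, evaluation and calibration checks.
medium_landmark <- function() {
  cached_fixture("medium", {
    cfg <- sim_config(n_persons = 6000, seed = 77)
    build_super_landmark(simulate_cohort(cfg), ages = 60:62)
  })
}

# Large cohort for parameter recovery and calibration at scale.
big_landmark <- function() {
  cached_fixture("big", {
    cfg <- sim_config(n_persons = 20000, seed = 421)
    build_super_landmark(simulate_cohort(cfg), ages = 58:66)
  })
}

true_terms <- function() c("pgs", "iron_abnormal", "rectal_bleed",
                           "age_at_index")
true_betas <- function() c(pgs = log(1.4), iron_abnormal = log(3.9),
                           rectal_bleed = log(2.7),
                           age_at_index = log(1.06))
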
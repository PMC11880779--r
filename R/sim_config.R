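#' Default recurrent clinical-event rates
#'
#' Base recording rates (events per person-year at age 60) for recurrent
#' coded clinical events. Values are order-of-magnitude choices calibrated so
#' that two-year lookback prevalences in a simulated cohort land near
#' commonly reported primary-care frequencies (for example, roughly 17% of
#' person-landmarks with a recent constipation record and 4% with recent
#' rectal bleeding). Rectal bleeding and iron-deficiency anaemia are driven
#' by persistent disease states (see [sim_config()]) rather than these
#' recurrent rates.
#'
#' @return named numeric vector, events/person-year at age 60.
#' @export
default_event_rates <- function() {
  c(abdominal_bloating = 0.010,
    abdominal_pain     = 0.077,
    bowel_habit_change = 0.012,
    constipation       = 0.092,
    diarrhoea          = 0.083,
    diverticular_disease = 0.021,
    fatigue            = 0.045,
    haemorrhoids       = 0.054,
    ibs                = 0.013,
    stomach_disorders  = 0.021,
    symptom_extra_1 = 0.005, symptom_extra_2 = 0.005,
    symptom_extra_3 = 0.005, symptom_extra_4 = 0.005,
    symptom_extra_5 = 0.005,
    aspirin            = 0.025,
    colonoscopy        = 0.027,
    diabetes_t2        = 0.003,
    gallbladder        = 0.0012,
    ibd                = 0.0007,
    nsaids             = 0.080,
    history_extra_1    = 0.005)
}

#' Default ground-truth log hazard ratios
#'
#' The colorectal-cancer hazard in the simulator is proportional-hazards in
#' a small set of predictors with known coefficients: polygenic score
#' (HR 1.4 per SD), iron-deficiency anaemia (HR 3.9), rectal bleeding
#' (HR 2.7) and attained age (HR 1.06 per year, centred at 60). The first
#' three mirror the strongest reported associations in dynamic CRC models;
#' the age slope approximates registry incidence curves over ages 40--75.
#'
#' @return named numeric vector of log hazard ratios.
#' @export
default_true_log_hrs <- function() {
  c(pgs = log(1.4),
    iron_abnormal = log(3.9),
    rectal_bleed = log(2.7),
    age_at_index = log(1.06))
}

#' Simulation configuration
#'
#' Assembles and validates the configuration for [simulate_cohort()]. The
#' simulated world is: people born uniformly in `birth_year_range` register
#' with primary care at a uniform age in `registration_age_range`; their
#' records run to a per-person end date in `pc_end_year` interrupted by
#' Poisson registration gaps; recurrent coded events and blood tests occur
#' as Poisson processes whose log rate rises linearly with age; two
#' persistent disease states (iron-deficiency anaemia, rectal bleeding) can
#' switch on and then generate frequent abnormal records; and a CRC outcome
#' follows a piecewise-constant proportional-hazards process whose linear
#' predictor is evaluated on the person's current simulated state, with
#' independent competing other-cancer, non-melanoma skin cancer and death
#' processes resolved by earliest date.
#'
#' @param n_persons number of people to simulate (>= 1).
#' @param seed integer master seed; each person draws from an independent
#'   stream derived from `(seed, person_id)` so cohorts are reproducible.
#' @param birth_year_range,baseline_year_range integer length-2 ranges.
#' @param registration_age_range age range (years) at primary-care
#'   registration.
#' @param coverage_gap_rate registration gaps per person-year.
#' @param coverage_gap_length_days list with `mean`: exponential mean gap
#'   length (days).
#' @param event_rates named vector of recurrent event base rates per
#'   person-year at age 60 ([default_event_rates()]).
#' @param event_rate_age_slope slope of log event rate per year of age.
#' @param state_onset_rates named vector: onset rates per person-year at age
#'   60 for the persistent disease states `iron_anaemia` and `rectal_bleed`.
#' @param state_onset_age_slope slope of log onset rate per year of age.
#' @param state_record_rate while a state is active, rate of its coded
#'   record stream (rectal-bleed events; extra iron tests) per person-year.
#' @param test_rates named vector: background blood-test rates per
#'   person-year for families `inflammation` and `iron`.
#' @param abnormal_prob named vector: probability a background test of each
#'   family is flagged abnormal (`iron` background abnormality is rare noise;
#'   in-state iron tests are abnormal with `state_abnormal_prob`).
#' @param state_abnormal_prob abnormality probability for in-state iron tests.
#' @param true_log_hrs named log hazard ratios for the CRC process. Names
#'   must be person columns (e.g. `pgs`, `sex`), `age_at_index`, a
#'   persistent-state predictor (`iron_abnormal`, `rectal_bleed`), or a
#'   recurrent event code (indicator of a record in the last
#'   `hazard_lookback_days`).
#' @param crc_baseline_hazard CRC events/person-year at covariate reference
#'   (age 60, PGS 0, no active states). The default is deliberately above
#'   population CRC incidence so that cohorts of simulatable size carry
#'   enough events for model fitting.
#' @param other_cancer_rate,nmsc_rate,death_rate competing event rates per
#'   person-year at age 60.
#' @param hazard_lookback_days window defining "current" for recurrent-event
#'   predictors in the hazard.
#' @param pc_end_year calendar year in which primary-care data availability
#'   ends (per-person day drawn uniformly within the year).
#' @param linkage_end_year last calendar year of registry linkage.
#' @return object of class `sim_config` (a validated list).
#' @export
sim_config <- function(n_persons,
                       seed = 1L,
                       birth_year_range = c(1936L, 1970L),
                       baseline_year_range = c(2006L, 2010L),
                       registration_age_range = c(25, 45),
                       coverage_gap_rate = 0.08,
                       coverage_gap_length_days = list(mean = 120),
                       event_rates = default_event_rates(),
                       event_rate_age_slope = 0.02,
                       state_onset_rates = c(iron_anaemia = 0.006,
                                             rectal_bleed = 0.0028),
                       state_onset_age_slope = 0.03,
                       state_record_rate = 2.0,
                       test_rates = c(inflammation = 0.94, iron = 0.85),
                       abnormal_prob = c(inflammation = 0.13, iron = 0.002),
                       state_abnormal_prob = 0.9,
                       true_log_hrs = default_true_log_hrs(),
                       crc_baseline_hazard = 0.004,
                       other_cancer_rate = 0.006,
                       nmsc_rate = 0.002,
                       death_rate = 0.010,
                       hazard_lookback_days = 730,
                       pc_end_year = 2018L,
                       linkage_end_year = 2020L) {
  cfg <- list(n_persons = as.integer(n_persons), seed = as.integer(seed),
              birth_year_range = as.integer(birth_year_range),
              baseline_year_range = as.integer(baseline_year_range),
              registration_age_range = registration_age_range,
              coverage_gap_rate = coverage_gap_rate,
              coverage_gap_length_days = coverage_gap_length_days,
              event_rates = event_rates,
              event_rate_age_slope = event_rate_age_slope,
              state_onset_rates = state_onset_rates,
              state_onset_age_slope = state_onset_age_slope,
              state_record_rate = state_record_rate,
              test_rates = test_rates,
              abnormal_prob = abnormal_prob,
              state_abnormal_prob = state_abnormal_prob,
              true_log_hrs = true_log_hrs,
              crc_baseline_hazard = crc_baseline_hazard,
              other_cancer_rate = other_cancer_rate,
              nmsc_rate = nmsc_rate,
              death_rate = death_rate,
              hazard_lookback_days = hazard_lookback_days,
              pc_end_year = as.integer(pc_end_year),
              linkage_end_year = as.integer(linkage_end_year))
  class(cfg) <- "sim_config"
  validate_sim_config(cfg)
}

validate_sim_config <- function(cfg) {
  if (is.na(cfg$n_persons) || cfg$n_persons < 1L)
    stop("n_persons must be a positive integer")
  rates <- c(cfg$coverage_gap_rate, cfg$event_rates, cfg$state_onset_rates,
             cfg$test_rates, cfg$crc_baseline_hazard, cfg$other_cancer_rate,
             cfg$nmsc_rate, cfg$death_rate, cfg$state_record_rate)
  if (any(rates < 0)) stop("all rates must be >= 0")
  if (any(cfg$abnormal_prob < 0 | cfg$abnormal_prob > 1) ||
      cfg$state_abnormal_prob < 0 || cfg$state_abnormal_prob > 1)
    stop("abnormality probabilities must lie in [0, 1]")
  lh <- cfg$true_log_hrs
  if (length(lh) && is.null(names(lh)))
    stop("true_log_hrs must be a named vector")
  static_names <- c("pgs", "sex", "bmi", "townsend", "age_at_index")
  known <- c(static_names, "iron_abnormal", "rectal_bleed",
             names(cfg$event_rates))
  bad <- setdiff(names(lh), known)
  if (length(bad))
    stop("unknown predictor name(s) in true_log_hrs: ",
         paste(bad, collapse = ", "))
  invisible(cfg)
}

#' Read / write a simulation configuration as YAML
#'
#' Only fields present in the file override the defaults of [sim_config()].
#'
#' @param path file path.
#' @param cfg a `sim_config` object (for writing).
#' @return [read_sim_config()] returns a `sim_config`;
#'   [write_sim_config()] returns `path` invisibly.
#' @export
read_sim_config <- function(path) {
  raw <- yaml::read_yaml(path)
  for (nm in c("event_rates", "state_onset_rates", "test_rates",
               "abnormal_prob", "true_log_hrs"))
    if (!is.null(raw[[nm]])) raw[[nm]] <- unlist(raw[[nm]])
  if (!is.null(raw$coverage_gap_length_days) &&
      !is.list(raw$coverage_gap_length_days))
    raw$coverage_gap_length_days <- as.list(raw$coverage_gap_length_days)
  do.call(sim_config, raw)
}

#' @rdname read_sim_config
#' @export
write_sim_config <- function(cfg, path) {
  stopifnot(inherits(cfg, "sim_config"))
  out <- unclass(cfg)
  for (nm in names(out))
    if (!is.null(names(out[[nm]])) && !is.list(out[[nm]]))
      out[[nm]] <- as.list(out[[nm]])
  yaml::write_yaml(out, path, precision = 15)
  invisible(path)
}
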
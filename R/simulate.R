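# Synthetic longitudinal cohort generator.
#
# Each person is simulated from an independent RNG stream derived from
# (seed, person_id). Event processes are homogeneous Poisson within yearly
# age bands with a linear age slope on the log rate; the CRC outcome is a
# piecewise-constant proportional-hazards process whose linear predictor is
# re-evaluated whenever the person's simulated state changes (state onsets,
# recurrent-event lookback windows opening/closing, birthdays for the age
# term). Competing other-cancer, NMSC and death processes are simulated
# independently and resolved by earliest date.

# Internal age slopes (per year of age, log scale) for the competing
# processes; death and cancer incidence rise faster with age than symptom
# recording does.
.DEATH_AGE_SLOPE <- 0.07
.OTHER_CANCER_AGE_SLOPE <- 0.05
.NMSC_AGE_SLOPE <- 0.03

.ETHNICITY_LEVELS <- c("white", "se_asian", "black", "mixed", "other")
.SMOKING_LEVELS <- c("never", "current", "former")
.EDUCATION_LEVELS <- c("higher_ed", "a_level", "gcse", "cse", "vocational",
                       "professional", "none")

person_seed <- function(seed, pid) {
  as.integer((as.numeric(seed) * 1000003 + as.numeric(pid) * 7919) %%
               2147483629)
}

days_of_year_range <- function(yr) {
  c(as.numeric(as.Date(sprintf("%d-01-01", yr[1]))),
    as.numeric(as.Date(sprintf("%d-12-31", yr[2]))))
}

# First event time (in days) of a Poisson process with rate
# base * exp(slope * (age - 60)), piecewise constant within yearly age bands.
first_event_sloped <- function(t0, t1, base, slope, birth) {
  if (t1 <= t0 || base <= 0) return(NA_real_)
  a0 <- floor((t0 - birth) / 365.25)
  a1 <- floor((t1 - birth) / 365.25)
  bnd <- birth + round(365.25 * (a0:(a1 + 1)))
  starts <- pmax(bnd[-length(bnd)], t0)
  ends <- pmin(bnd[-1], t1)
  keep <- ends > starts
  if (!any(keep)) return(NA_real_)
  starts <- starts[keep]; ends <- ends[keep]
  mid_age <- ((starts + ends) / 2 - birth) / 365.25
  h <- base * exp(slope * (mid_age - 60))
  cum <- cumsum(h * (ends - starts) / 365.25)
  E <- rexp(1)
  j <- which(cum >= E)[1]
  if (is.na(j)) return(NA_real_)
  prev <- if (j == 1) 0 else cum[j - 1]
  starts[j] + (E - prev) / h[j] * 365.25
}

# All events of banded-rate Poisson processes for several codes at once.
# Returns a two-column matrix (day, code index).
recurrent_events <- function(t0, t1, base_rates, slope, birth) {
  if (t1 <= t0 || !length(base_rates)) return(NULL)
  a0 <- floor((t0 - birth) / 365.25)
  a1 <- floor((t1 - birth) / 365.25)
  bnd <- birth + round(365.25 * (a0:(a1 + 1)))
  starts <- pmax(bnd[-length(bnd)], t0)
  ends <- pmin(bnd[-1], t1)
  keep <- ends > starts
  starts <- starts[keep]; ends <- ends[keep]
  if (!length(starts)) return(NULL)
  mid_age <- ((starts + ends) / 2 - birth) / 365.25
  exposure <- (ends - starts) / 365.25          # band exposure, years
  age_fac <- exp(slope * (mid_age - 60))
  mu <- outer(base_rates, age_fac * exposure)   # codes x bands
  counts <- rpois(length(mu), mu)
  if (sum(counts) == 0) return(NULL)
  code_idx <- rep(rep(seq_along(base_rates), length(starts)), counts)
  band_idx <- rep(rep(seq_along(starts), each = length(base_rates)), counts)
  day <- floor(runif(sum(counts), starts[band_idx], ends[band_idx]))
  cbind(day, code_idx)
}

# Homogeneous Poisson event days over [t0, t1].
homog_events <- function(t0, t1, rate) {
  if (t1 <= t0 || rate <= 0) return(numeric(0))
  n <- rpois(1, rate * (t1 - t0) / 365.25)
  if (n == 0) return(numeric(0))
  floor(runif(n, t0, t1))
}

# First CRC event under the piecewise-constant proportional-hazards model.
crc_first_event <- function(t0, t1, birth, base, lhr, static_lp,
                            state_onset, event_days_by_code, lookback) {
  if (t1 <= t0 || base <= 0) return(NA_real_)
  bps <- c(t0, t1)
  has_age <- "age_at_index" %in% names(lhr)
  if (has_age) {
    a0 <- floor((t0 - birth) / 365.25)
    a1 <- floor((t1 - birth) / 365.25)
    bps <- c(bps, birth + round(365.25 * (a0:(a1 + 1))))
  }
  states <- intersect(names(lhr), names(state_onset))
  for (s in states)
    if (!is.na(state_onset[[s]])) bps <- c(bps, state_onset[[s]])
  for (k in names(event_days_by_code)) {
    ev <- event_days_by_code[[k]]
    bps <- c(bps, ev, ev + lookback)
  }
  bps <- sort(unique(pmin(pmax(bps, t0), t1)))
  starts <- bps[-length(bps)]
  ends <- bps[-1]
  keep <- ends > starts
  starts <- starts[keep]; ends <- ends[keep]
  if (!length(starts)) return(NA_real_)
  mid <- (starts + ends) / 2
  lp <- rep(static_lp, length(mid))
  if (has_age)
    lp <- lp + lhr[["age_at_index"]] * ((mid - birth) / 365.25 - 60)
  for (s in states) {
    on <- state_onset[[s]]
    if (!is.na(on)) lp <- lp + lhr[[s]] * (mid >= on)
  }
  for (k in names(event_days_by_code)) {
    ev <- event_days_by_code[[k]]
    if (length(ev)) {
      active <- vapply(mid, function(m) any(ev > m - lookback & ev <= m),
                       logical(1))
      lp <- lp + lhr[[k]] * active
    }
  }
  h <- base * exp(lp)
  cum <- cumsum(h * (ends - starts) / 365.25)
  E <- rexp(1)
  j <- which(cum >= E)[1]
  if (is.na(j)) return(NA_real_)
  prev <- if (j == 1) 0 else cum[j - 1]
  starts[j] + (E - prev) / h[j] * 365.25
}

#' Ground-truth linear predictor
#'
#' Evaluates the simulator's log-hazard offset `sum(beta_k * x_k)` for a
#' given state of predictor values, using the configured true log hazard
#' ratios. Serves as the oracle risk score in parameter-recovery and
#' discrimination tests. Note the CRC hazard centres the `age_at_index`
#' term at 60 years; pass centred age when reproducing the hazard, or raw
#' age when only ranks matter.
#'
#' @param person_state named numeric vector (or single-row data.frame) of
#'   predictor values; must contain every name in `config$true_log_hrs`.
#' @param config a [sim_config()].
#' @return numeric scalar log-hazard offset.
#' @export
true_linear_predictor <- function(person_state, config) {
  lhr <- config$true_log_hrs
  if (!length(lhr)) return(0)
  if (is.data.frame(person_state))
    person_state <- unlist(person_state[1, , drop = FALSE])
  miss <- setdiff(names(lhr), names(person_state))
  if (length(miss))
    stop("person_state is missing predictor value(s): ",
         paste(miss, collapse = ", "))
  sum(lhr * as.numeric(person_state[names(lhr)]))
}

#' Simulate a synthetic longitudinal cohort
#'
#' Generates the five linked record streams the landmark analysis consumes:
#' a person table (static demographics, lifestyle, polygenic score,
#' primary-care end date), coverage intervals with registration gaps, dated
#' coded clinical events, dated blood tests with abnormality flags, and a
#' registry of cancer and death events. The CRC outcome follows a
#' proportional-hazards process with the configured ground-truth log hazard
#' ratios, so fitted models can be checked against known truth. Output is
#' deterministic given `config$seed`.
#'
#' @param config a [sim_config()].
#' @return object of class `raw_cohort`: list with data.frames `persons`,
#'   `coverage`, `clinical_events`, `blood_tests`, `registry`; the
#'   configuration is attached as attribute `config`.
#' @export
simulate_cohort <- function(config) {
  cfg <- validate_sim_config(config)
  n <- cfg$n_persons
  lhr <- cfg$true_log_hrs

  birth_rng <- days_of_year_range(cfg$birth_year_range)
  base_rng <- days_of_year_range(cfg$baseline_year_range)
  pc_rng <- days_of_year_range(rep(cfg$pc_end_year, 2))
  linkage_end <- as.numeric(as.Date(sprintf("%d-12-31", cfg$linkage_end_year)))

  ev_codes <- names(cfg$event_rates)
  ev_rates <- unname(cfg$event_rates)
  # recurrent codes that carry a hazard effect
  hz_codes <- intersect(names(lhr), ev_codes)
  static_hr_names <- intersect(names(lhr), c("pgs", "sex", "bmi", "townsend"))

  # preallocated person columns
  p_sex <- character(n); p_birth <- numeric(n); p_base <- numeric(n)
  p_eth <- character(n); p_smoke <- character(n)
  p_town <- numeric(n); p_bmi <- numeric(n); p_alc <- numeric(n)
  p_edu <- character(n); p_fibre <- numeric(n); p_pmeat <- numeric(n)
  p_rmeat <- numeric(n); p_pgs <- numeric(n)
  p_fhb <- integer(n); p_fhbr <- integer(n); p_fhl <- integer(n)
  p_scr <- integer(n); p_multi <- numeric(n); p_pcend <- numeric(n)

  cov_list <- vector("list", n)
  ev_list <- vector("list", n)
  bt_list <- vector("list", n)
  reg_list <- vector("list", n)

  for (i in seq_len(n)) {
    set.seed(person_seed(cfg$seed, i))

    ## --- static person fields -------------------------------------------
    p_sex[i] <- if (runif(1) < 0.473) "male" else "female"
    birth <- floor(runif(1, birth_rng[1], birth_rng[2] + 1))
    p_birth[i] <- birth
    p_base[i] <- floor(runif(1, base_rng[1], base_rng[2] + 1))
    p_eth[i] <- sample(c(.ETHNICITY_LEVELS, NA), 1,
                       prob = c(0.950, 0.020, 0.011, 0.005, 0.011, 0.003))
    p_smoke[i] <- sample(c(.SMOKING_LEVELS, NA), 1,
                         prob = c(0.553, 0.104, 0.340, 0.003))
    p_town[i] <- rnorm(1, -1.6, 3.0)
    p_bmi[i] <- rnorm(1, 27.1, 4.2)
    p_alc[i] <- if (runif(1) < 0.02) NA_real_ else
      rgamma(1, shape = 1.0, scale = 2.4)
    p_edu[i] <- sample(c(.EDUCATION_LEVELS, NA), 1,
                       prob = c(0.330, 0.111, 0.212, 0.052, 0.067, 0.053,
                                0.165, 0.010))
    p_fibre[i] <- pmax(0, rnorm(1, 13.8, 5.6))
    p_pmeat[i] <- rgamma(1, shape = 1.5, scale = 1.2)
    p_rmeat[i] <- rgamma(1, shape = 4, scale = 0.5)
    p_pgs[i] <- rnorm(1)
    p_fhb[i] <- rbinom(1, 1, 0.108)
    p_fhbr[i] <- rbinom(1, 1, 0.101)
    p_fhl[i] <- rbinom(1, 1, 0.123)
    p_scr[i] <- rbinom(1, 1, 0.647)
    p_multi[i] <- rnorm(1, 0, 0.35)

    ## --- coverage --------------------------------------------------------
    reg_age <- runif(1, cfg$registration_age_range[1],
                     cfg$registration_age_range[2])
    reg_start <- birth + floor(reg_age * 365.25)
    pc_end <- floor(runif(1, pc_rng[1], pc_rng[2] + 1))
    if (pc_end < reg_start) pc_end <- reg_start
    cov_years <- (pc_end - reg_start) / 365.25
    n_gaps <- rpois(1, cfg$coverage_gap_rate * cov_years)
    if (n_gaps > 0) {
      gs <- floor(runif(n_gaps, reg_start, pc_end))
      gl <- ceiling(rexp(n_gaps, 1 / cfg$coverage_gap_length_days$mean))
      ge <- pmin(gs + gl, pc_end)
      o <- order(gs)
      gs <- gs[o]; ge <- ge[o]
      # merge overlapping gaps
      ms <- gs[1]; me <- ge[1]; gaps <- NULL
      if (n_gaps > 1) {
        for (g in 2:n_gaps) {
          if (gs[g] <= me) me <- max(me, ge[g]) else {
            gaps <- rbind(gaps, c(ms, me)); ms <- gs[g]; me <- ge[g]
          }
        }
      }
      gaps <- rbind(gaps, c(ms, me))
      cs <- c(reg_start, gaps[, 2]); ce <- c(gaps[, 1], pc_end)
      keep <- ce > cs
      cov <- cbind(cs[keep], ce[keep])
    } else {
      cov <- cbind(reg_start, pc_end)
    }

    ## --- persistent disease states --------------------------------------
    onset <- c(iron_anaemia = NA_real_, rectal_bleed = NA_real_)
    for (s in names(cfg$state_onset_rates)) {
      onset[[s]] <- first_event_sloped(
        birth + round(30 * 365.25), linkage_end,
        cfg$state_onset_rates[[s]], cfg$state_onset_age_slope, birth)
    }

    ## --- recurrent clinical events ---------------------------------------
    ev <- recurrent_events(reg_start, pc_end, ev_rates,
                           cfg$event_rate_age_slope, birth)
    # rectal-bleed records while the bleeding state is active
    rb_on <- onset[["rectal_bleed"]]
    rb_code_idx <- length(ev_codes) + 1L
    if (!is.na(rb_on) && rb_on < pc_end) {
      d <- homog_events(max(rb_on, reg_start), pc_end, cfg$state_record_rate)
      if (length(d)) ev <- rbind(ev, cbind(d, rb_code_idx))
    }

    ## --- blood tests ------------------------------------------------------
    fam <- names(cfg$test_rates)
    bt <- NULL
    for (f in seq_along(fam)) {
      d <- homog_events(reg_start, pc_end, cfg$test_rates[[fam[f]]])
      if (length(d)) {
        ab <- rbinom(length(d), 1, cfg$abnormal_prob[[fam[f]]])
        bt <- rbind(bt, cbind(d, f, ab))
      }
    }
    ir_on <- onset[["iron_anaemia"]]
    iron_f <- match("iron", fam)
    if (!is.na(ir_on) && !is.na(iron_f) && ir_on < pc_end) {
      d <- homog_events(max(ir_on, reg_start), pc_end, cfg$state_record_rate)
      if (length(d)) {
        ab <- rbinom(length(d), 1, cfg$state_abnormal_prob)
        bt <- rbind(bt, cbind(d, iron_f, ab))
      }
    }

    ## --- registry processes ----------------------------------------------
    death <- floor(first_event_sloped(reg_start, linkage_end, cfg$death_rate,
                                      .DEATH_AGE_SLOPE, birth))
    oth <- floor(first_event_sloped(reg_start, linkage_end,
                                    cfg$other_cancer_rate,
                                    .OTHER_CANCER_AGE_SLOPE, birth))
    nmsc <- floor(first_event_sloped(reg_start, linkage_end, cfg$nmsc_rate,
                                     .NMSC_AGE_SLOPE, birth))

    static_lp <- 0
    if (length(static_hr_names)) {
      vals <- c(pgs = p_pgs[i], sex = as.numeric(p_sex[i] == "male"),
                bmi = p_bmi[i], townsend = p_town[i])
      static_lp <- sum(lhr[static_hr_names] * vals[static_hr_names])
    }
    ev_by_code <- NULL
    if (length(hz_codes)) {
      ev_by_code <- lapply(hz_codes, function(k) {
        ki <- match(k, ev_codes)
        if (is.null(ev)) numeric(0) else ev[ev[, 2] == ki, 1]
      })
      names(ev_by_code) <- hz_codes
    }
    state_onset_pred <- c(iron_abnormal = onset[["iron_anaemia"]],
                          rectal_bleed = onset[["rectal_bleed"]])
    crc <- floor(crc_first_event(reg_start, linkage_end, birth,
                                 cfg$crc_baseline_hazard, lhr, static_lp,
                                 state_onset_pred, ev_by_code,
                                 cfg$hazard_lookback_days))

    ## --- truncation at death, assembly -----------------------------------
    if (!is.na(death)) {
      if (!is.na(crc) && crc > death) crc <- NA_real_
      if (!is.na(oth) && oth > death) oth <- NA_real_
      if (!is.na(nmsc) && nmsc > death) nmsc <- NA_real_
      if (!is.null(ev)) ev <- ev[ev[, 1] <= death, , drop = FALSE]
      if (!is.null(bt)) bt <- bt[bt[, 1] <= death, , drop = FALSE]
      cov[, 2] <- pmin(cov[, 2], death)
      cov <- cov[cov[, 1] <= cov[, 2], , drop = FALSE]
      pc_end <- min(pc_end, death)
    }
    p_pcend[i] <- pc_end

    cov_list[[i]] <- cbind(i, cov)
    if (!is.null(ev) && nrow(ev)) ev_list[[i]] <- cbind(i, ev)
    if (!is.null(bt) && nrow(bt)) bt_list[[i]] <- cbind(i, bt)
    reg <- NULL
    if (!is.na(crc)) reg <- rbind(reg, c(floor(crc), 1))
    if (!is.na(oth)) reg <- rbind(reg, c(floor(oth), 2))
    if (!is.na(nmsc)) reg <- rbind(reg, c(floor(nmsc), 3))
    if (!is.na(death)) reg <- rbind(reg, c(floor(death), 4))
    if (!is.null(reg)) {
      reg <- reg[order(reg[, 1]), , drop = FALSE]
      reg_list[[i]] <- cbind(i, reg)
    }
  }

  to_date <- function(x) as.Date(x, origin = "1970-01-01")
  persons <- data.frame(
    person_id = seq_len(n), sex = p_sex, birth_date = to_date(p_birth),
    baseline_date = to_date(p_base), ethnicity = p_eth,
    smoking_status = p_smoke, townsend = p_town, bmi = p_bmi,
    alcohol = p_alc, education = p_edu, fibre = p_fibre,
    processed_meat = p_pmeat, red_meat = p_rmeat, pgs = p_pgs,
    fam_hist_bowel = p_fhb, fam_hist_breast = p_fhbr, fam_hist_lung = p_fhl,
    screening_eligible = p_scr, multimorbidity_score = p_multi,
    pc_end_date = to_date(p_pcend), stringsAsFactors = FALSE)

  covm <- do.call(rbind, cov_list)
  coverage <- data.frame(person_id = as.integer(covm[, 1]),
                         start_date = to_date(covm[, 2]),
                         end_date = to_date(covm[, 3]))

  code_labels <- c(ev_codes, "rectal_bleed")
  if (length(ev_list) && !all(vapply(ev_list, is.null, logical(1)))) {
    evm <- do.call(rbind, ev_list)
    clinical_events <- data.frame(person_id = as.integer(evm[, 1]),
                                  date = to_date(evm[, 2]),
                                  code = code_labels[evm[, 3]],
                                  stringsAsFactors = FALSE)
  } else {
    clinical_events <- data.frame(person_id = integer(0),
                                  date = to_date(numeric(0)),
                                  code = character(0))
  }

  fam <- names(cfg$test_rates)
  if (length(bt_list) && !all(vapply(bt_list, is.null, logical(1)))) {
    btm <- do.call(rbind, bt_list)
    blood_tests <- data.frame(person_id = as.integer(btm[, 1]),
                              date = to_date(btm[, 2]),
                              test_family = fam[btm[, 3]],
                              abnormal = as.integer(btm[, 4]),
                              stringsAsFactors = FALSE)
  } else {
    blood_tests <- data.frame(person_id = integer(0),
                              date = to_date(numeric(0)),
                              test_family = character(0),
                              abnormal = integer(0))
  }

  reg_types <- c("crc", "other_cancer", "nmsc", "death")
  if (length(reg_list) && !all(vapply(reg_list, is.null, logical(1)))) {
    regm <- do.call(rbind, reg_list)
    registry <- data.frame(person_id = as.integer(regm[, 1]),
                           date = to_date(regm[, 2]),
                           event_type = reg_types[regm[, 3]],
                           stringsAsFactors = FALSE)
  } else {
    registry <- data.frame(person_id = integer(0), date = to_date(numeric(0)),
                           event_type = character(0))
  }

  structure(list(persons = persons, coverage = coverage,
                 clinical_events = clinical_events,
                 blood_tests = blood_tests, registry = registry),
            config = cfg, class = "raw_cohort")
}

#' @export
print.raw_cohort <- function(x, ...) {
  cat("<raw_cohort>", nrow(x$persons), "persons,",
      nrow(x$clinical_events), "clinical events,",
      nrow(x$blood_tests), "blood tests,",
      nrow(x$registry), "registry events\n")
  invisible(x)
}
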
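# Super-landmark dataset construction: eligibility at each landmark age,
# index dates, outcome ascertainment with censoring, and stacking.

.CENSOR_REASONS <- c("crc", "other_cancer", "death", "pc_end_plus_2y",
                     "admin_730")

#' Merge coverage intervals into continuous runs
#'
#' Registration intervals separated by gaps of at most `max_gap_days` days
#' are treated as one continuous period of record coverage (a gap of exactly
#' `max_gap_days` does not break continuity: the continuity rule is "no gaps
#' strictly greater than the threshold"). Overlapping intervals are merged.
#'
#' @param intervals data.frame with `start_date`, `end_date` (Date), any
#'   order; an empty data.frame yields an empty result.
#' @param max_gap_days maximum tolerated gap, in days (default 90).
#' @return data.frame with `start_date`, `end_date`, sorted by start.
#' @export
coverage_runs <- function(intervals, max_gap_days = 90) {
  if (!is.data.frame(intervals))
    intervals <- data.frame(start_date = as.Date(vapply(intervals, `[[`,
                                                        "", 1)),
                            end_date = as.Date(vapply(intervals, `[[`,
                                                      "", 2)))
  if (nrow(intervals) == 0)
    return(data.frame(start_date = as.Date(character(0)),
                      end_date = as.Date(character(0))))
  s <- as.numeric(intervals$start_date)
  e <- as.numeric(intervals$end_date)
  if (any(e < s)) stop("coverage interval with end_date before start_date")
  o <- order(s)
  s <- s[o]; e <- e[o]
  rs <- s[1]; re <- e[1]
  out_s <- numeric(0); out_e <- numeric(0)
  if (length(s) > 1) {
    for (k in 2:length(s)) {
      if (s[k] - re <= max_gap_days) {
        re <- max(re, e[k])
      } else {
        out_s <- c(out_s, rs); out_e <- c(out_e, re)
        rs <- s[k]; re <- e[k]
      }
    }
  }
  out_s <- c(out_s, rs); out_e <- c(out_e, re)
  data.frame(start_date = as.Date(out_s, origin = "1970-01-01"),
             end_date = as.Date(out_e, origin = "1970-01-01"))
}

# Vectorized run construction for all persons at once.
merge_runs_all <- function(coverage, max_gap_days = 90) {
  cov <- data.table::as.data.table(coverage)
  if (nrow(cov) == 0)
    return(data.table::data.table(person_id = integer(0),
                                  run_start = numeric(0),
                                  run_end = numeric(0)))
  cov[, `:=`(s = as.numeric(start_date), e = as.numeric(end_date))]
  if (cov[, any(e < s)])
    stop("coverage interval with end_date before start_date")
  data.table::setorder(cov, person_id, s)
  cov[, prev_max_end := data.table::shift(cummax(e)), by = person_id]
  cov[, new_run := is.na(prev_max_end) | s - prev_max_end > max_gap_days]
  cov[, run_id := cumsum(new_run), by = person_id]
  cov[, .(run_start = min(s), run_end = max(e)),
      by = .(person_id, run_id)][, run_id := NULL][]
}

# Per-person summaries used by eligibility and outcomes.
registry_summaries <- function(cohort) {
  reg <- data.table::as.data.table(cohort$registry)
  persons <- data.table::as.data.table(cohort$persons)
  base <- persons[, .(person_id)]
  if (nrow(reg)) {
    # suppressWarnings: data.table evaluates j once on an empty subset for
    # type inference, which makes min() warn harmlessly
    dd <- suppressWarnings(
      reg[event_type == "death", .(death = min(as.numeric(date))),
          by = person_id])
    ca <- suppressWarnings(
      reg[event_type %in% c("crc", "other_cancer"),
          .(first_cancer = min(as.numeric(date))), by = person_id])
    crc <- suppressWarnings(
      reg[event_type == "crc", .(crc = min(as.numeric(date))),
          by = person_id])
    oth <- suppressWarnings(
      reg[event_type == "other_cancer",
          .(other = min(as.numeric(date))), by = person_id])
  } else {
    dd <- ca <- crc <- oth <- NULL
  }
  out <- base
  for (tb in list(dd, ca, crc, oth))
    if (!is.null(tb)) out <- merge(out, tb, by = "person_id", all.x = TRUE)
  for (nm in c("death", "first_cancer", "crc", "other"))
    if (!nm %in% names(out)) out[, (nm) := NA_real_]
  out[, pc_end := as.numeric(persons$pc_end_date[match(person_id,
                                                       persons$person_id)])]
  out
}

# Eligibility and outcome for a grid of (person_id, landmark_age, index)
# candidate rows. Returns the grid with eligibility flag, failure reason,
# and for eligible rows the (event, time_days, censor_reason) outcome.
evaluate_grid <- function(grid, cohort, max_gap_days, min_coverage_days,
                          lookback_days, require_coverage_to_index) {
  g <- data.table::as.data.table(grid)
  g[, idx := as.numeric(index_date)]
  summ <- registry_summaries(cohort)
  g <- merge(g, summ, by = "person_id", all.x = TRUE, sort = FALSE)

  g[, alive := is.na(death) | death >= idx]
  g[, no_prior := is.na(first_cancer) | first_cancer >= idx]

  runs <- merge_runs_all(cohort$coverage, max_gap_days)
  g[, `:=`(win_lo = idx - lookback_days, win_hi = idx - 1)]
  g[, row_id := .I]
  if (nrow(runs)) {
    ov <- runs[g, on = .(person_id, run_start <= win_hi, run_end >= win_lo),
               .(row_id = i.row_id, r_start = x.run_start, r_end = x.run_end),
               nomatch = NULL]
    if (nrow(ov)) {
      # most recent run = latest end date among runs intersecting the window
      data.table::setorder(ov, row_id, -r_end)
      ov <- ov[!duplicated(row_id)]
      ov[, win_lo := g$win_lo[row_id]]
      ov[, win_hi := g$win_hi[row_id]]
      ov[, covered := pmin(r_end, win_hi) - pmax(r_start, win_lo) + 1]
      g[ov$row_id, `:=`(covered = ov$covered, run_end = ov$r_end)]
    }
  }
  if (!"covered" %in% names(g)) g[, `:=`(covered = NA_real_,
                                         run_end = NA_real_)]
  g[, cov_ok := !is.na(covered) & covered >= min_coverage_days]
  if (require_coverage_to_index)
    g[, cov_ok := cov_ok & !is.na(run_end) & run_end >= win_hi]

  g[, eligible := alive & cov_ok & no_prior]
  g[, reason := data.table::fcase(!alive, "not_alive",
                                  !cov_ok, "coverage",
                                  !no_prior, "prior_cancer",
                                  default = NA_character_)]

  # outcomes for eligible rows: earliest of the five censoring candidates
  cand <- cbind(
    crc = ifelse(!is.na(g$crc) & g$crc >= g$idx,
                 pmax(1, g$crc - g$idx), Inf),
    other_cancer = ifelse(!is.na(g$other) & g$other >= g$idx,
                          pmax(1, g$other - g$idx), Inf),
    death = ifelse(!is.na(g$death) & g$death >= g$idx,
                   pmax(1, g$death - g$idx), Inf),
    pc_end_plus_2y = pmax(1, g$pc_end + 730 - g$idx),
    admin_730 = rep(730, nrow(g)))
  # row-wise first minimum in fixed priority order; candidates beyond the
  # 730-day horizon lose to administrative censoring
  cand[is.na(cand)] <- Inf
  tmin <- do.call(pmin, as.data.frame(cand))
  which_first <- max.col(-as.matrix(cand), ties.method = "first")
  g[, time_days := tmin]
  g[, censor_reason := .CENSOR_REASONS[which_first]]
  g[, event := as.integer(censor_reason == "crc")]
  g[]
}

#' Eligibility of one person at one landmark age
#'
#' A person is eligible if, at the index date, they are (i) alive, (ii) have
#' at least `min_coverage_days` consecutive days of record coverage within
#' the most recent continuous coverage run intersecting the 2-year lookback
#' window `[index - lookback, index)`, and (iii) have no prior cancer
#' diagnosis (non-melanoma skin cancer excepted) strictly before the index
#' date.
#'
#' @param person a person_id present in `cohort$persons`.
#' @param landmark_age landmark age in years.
#' @param cohort a `raw_cohort`.
#' @param max_gap_days gap tolerance for continuity of coverage.
#' @param min_coverage_days minimum consecutive covered days ("6 months" =
#'   183 days).
#' @param lookback_days lookback window length in days.
#' @param require_coverage_to_index if `TRUE`, the qualifying coverage run
#'   must also extend to the day before the index date.
#' @return list with `eligible` (logical) and `reason` (`NA` if eligible,
#'   otherwise the first failed criterion: `not_alive`, `coverage`,
#'   `prior_cancer`).
#' @export
is_eligible <- function(person, landmark_age, cohort, max_gap_days = 90,
                        min_coverage_days = 183, lookback_days = 730,
                        require_coverage_to_index = FALSE) {
  p <- cohort$persons[cohort$persons$person_id == person, , drop = FALSE]
  if (nrow(p) == 0) stop("person_id not present in cohort: ", person)
  grid <- data.frame(person_id = person, landmark_age = landmark_age,
                     index_date = index_date(p$birth_date, landmark_age))
  g <- evaluate_grid(grid, cohort, max_gap_days, min_coverage_days,
                     lookback_days, require_coverage_to_index)
  list(eligible = g$eligible[1], reason = g$reason[1])
}

#' Outcome and censoring at an index date
#'
#' Follow-up runs from the index date to the earliest of: first CRC
#' diagnosis (the event), first other incident cancer (non-melanoma skin
#' cancer ignored), death, two years after the end of primary-care data
#' availability, or two years after the index date. A diagnosis on the index
#' date itself is assigned time 1 day. Ties are resolved in that priority
#' order.
#'
#' @param person a person_id.
#' @param at_date the index date (Date).
#' @param cohort a `raw_cohort`.
#' @return list with `event` (0/1), `time_days` in (0, 730], and
#'   `censor_reason` (one of `crc`, `other_cancer`, `death`,
#'   `pc_end_plus_2y`, `admin_730`).
#' @export
outcome_at <- function(person, at_date, cohort) {
  p <- cohort$persons[cohort$persons$person_id == person, , drop = FALSE]
  if (nrow(p) == 0) stop("person_id not present in cohort: ", person)
  grid <- data.frame(person_id = person, landmark_age = NA_integer_,
                     index_date = as.Date(at_date))
  g <- evaluate_grid(grid, cohort, 90, 183, 730, FALSE)
  list(event = g$event[1], time_days = g$time_days[1],
       censor_reason = g$censor_reason[1])
}

#' Build the super-landmark dataset
#'
#' Stacks one row per eligible (person, landmark age) pair: the index date
#' is the first of the month in which the person reaches the landmark age;
#' predictors are derived from records strictly before the index date; the
#' outcome is the first CRC diagnosis within two years, with censoring at
#' any other incident cancer, death, two years after the end of record
#' availability, or administratively at 730 days. People appear at several
#' landmark ages, so downstream models must treat `person_id` as a cluster.
#'
#' @param cohort a `raw_cohort` (or any list of tables in the same shape).
#' @param ages integer vector of landmark ages (default 40:74).
#' @param codebook predictor codebook; `NULL` skips predictor derivation.
#' @param max_gap_days,min_coverage_days,lookback_days,require_coverage_to_index
#'   eligibility parameters, see [is_eligible()].
#' @return data.frame of class `super_landmark` with identifier, outcome and
#'   predictor columns; attributes `ages`, `codebook` and
#'   `n_dropped_missing` (complete-case removals).
#' @export
build_super_landmark <- function(cohort, ages = 40:74,
                                 codebook = default_codebook(),
                                 max_gap_days = 90, min_coverage_days = 183,
                                 lookback_days = 730,
                                 require_coverage_to_index = FALSE) {
  if (nrow(cohort$persons) == 0) stop("empty cohort")
  ages <- as.integer(ages)
  if (length(ages) == 0) {
    out <- data.frame(person_id = integer(0), landmark_age = integer(0),
                      index_date = as.Date(character(0)), event = integer(0),
                      time_days = numeric(0), censor_reason = character(0))
    attr(out, "ages") <- ages
    class(out) <- c("super_landmark", "data.frame")
    return(out)
  }
  persons <- cohort$persons
  grid <- data.table::CJ(person_id = persons$person_id, landmark_age = ages)
  bd <- persons$birth_date[match(grid$person_id, persons$person_id)]
  idx <- lapply(ages, function(a)
    index_date(bd[grid$landmark_age == a], a))
  grid[, index_date := as.Date(NA)]
  for (k in seq_along(ages))
    grid[landmark_age == ages[k], index_date := idx[[k]]]

  g <- evaluate_grid(grid, cohort, max_gap_days, min_coverage_days,
                     lookback_days, require_coverage_to_index)
  g <- g[eligible == TRUE]
  rows <- data.frame(person_id = g$person_id, landmark_age = g$landmark_age,
                     index_date = as.Date(g$idx, origin = "1970-01-01"),
                     event = g$event, time_days = as.numeric(g$time_days),
                     censor_reason = g$censor_reason,
                     stringsAsFactors = FALSE)
  rows <- rows[order(rows$person_id, rows$landmark_age), , drop = FALSE]
  rownames(rows) <- NULL

  n_dropped <- 0L
  if (!is.null(codebook)) {
    pred <- derive_predictor_table(rows, cohort, codebook)
    keep <- apply_missing_policy(pred, codebook)
    n_dropped <- nrow(pred) - nrow(keep$data)
    rows <- cbind(rows[keep$keep_rows, , drop = FALSE], keep$data)
    rownames(rows) <- NULL
  }
  attr(rows, "ages") <- ages
  attr(rows, "codebook") <- codebook
  attr(rows, "n_dropped_missing") <- n_dropped
  class(rows) <- c("super_landmark", "data.frame")
  rows
}
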
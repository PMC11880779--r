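# Predictor derivation at index dates: lookback-window indicators from coded
# events and blood tests, time-fixed baseline fields, and the missing-data
# policy (separate "missing" category for smoking and ethnicity, complete
# case otherwise).

.FACTOR_LEVELS <- list(
  sex = c("female", "male"),
  ethnicity = c("white", "se_asian", "black", "mixed", "other"),
  smoking_status = c("never", "current", "former"),
  education = c("higher_ed", "a_level", "gcse", "cse", "vocational",
                "professional", "none"))

# Predictors allowed to carry a "missing" category instead of triggering
# complete-case removal.
.MISSING_CATEGORY_PREDICTORS <- c("smoking_status", "ethnicity")

#' Derive the predictor table for a set of landmark rows
#'
#' For each (person, index date) row, event-sourced binary predictors are 1
#' iff at least one matching coded event falls in the half-open lookback
#' window `[index - lookback, index)` (events on the index date itself are
#' future, not history); "ever" predictors use the full prior history and
#' colonoscopy a 10-year window. Blood-test indicators encode, per test
#' family, whether any test was taken in the window and whether any result
#' was abnormal. Baseline-sourced values are copied time-fixed; derived
#' fields (`age_at_index`, `birth_year`, `baseline_age`) come from dates.
#' Events with codes not in the codebook are reported and skipped.
#'
#' No missing-data handling is applied here; see [apply_missing_policy()].
#'
#' @param rows data.frame with `person_id`, `index_date` and optionally
#'   `landmark_age`.
#' @param cohort a `raw_cohort`.
#' @param codebook predictor codebook ([default_codebook()]).
#' @return data.frame with one column per codebook predictor, in codebook
#'   order, `nrow(rows)` rows.
#' @export
derive_predictor_table <- function(rows, cohort, codebook = default_codebook()) {
  validate_codebook(codebook)
  n <- nrow(rows)
  persons <- cohort$persons
  pi <- match(rows$person_id, persons$person_id)
  if (anyNA(pi)) stop("rows contain person_ids absent from cohort")
  idx <- as.numeric(as.Date(rows$index_date))
  birth <- as.numeric(persons$birth_date[pi])

  out <- vector("list", nrow(codebook))
  names(out) <- codebook$predictor

  ## derived fields
  if ("age_at_index" %in% codebook$predictor) {
    age <- if ("landmark_age" %in% names(rows) &&
               !anyNA(rows$landmark_age)) as.numeric(rows$landmark_age)
           else round((idx - birth) / 365.25)
    out[["age_at_index"]] <- age
  }
  if ("birth_year" %in% codebook$predictor)
    out[["birth_year"]] <- as.numeric(format(persons$birth_date[pi], "%Y"))
  if ("baseline_age" %in% codebook$predictor)
    out[["baseline_age"]] <-
      as.numeric(persons$baseline_date[pi] - persons$birth_date[pi]) / 365.25

  ## baseline fields copied time-fixed
  for (k in which(codebook$source == "baseline")) {
    nm <- codebook$predictor[k]
    if (!nm %in% names(persons))
      stop("baseline predictor not found in persons table: ", nm)
    out[[nm]] <- persons[[nm]][pi]
  }

  ## event-sourced indicators
  ev_entries <- codebook[codebook$source == "events", , drop = FALSE]
  if (nrow(ev_entries)) {
    for (nm in ev_entries$predictor) out[[nm]] <- integer(n)
    ev <- data.table::as.data.table(cohort$clinical_events)
    if (nrow(ev)) {
      unknown <- setdiff(unique(ev$code), ev_entries$code)
      if (length(unknown))
        message("skipping events with codes not in codebook: ",
                paste(unknown, collapse = ", "))
      ev <- ev[code %in% ev_entries$code]
      ev[, day := as.numeric(date)]
      rdt <- data.table::data.table(person_id = rows$person_id, idx = idx,
                                    row_id = seq_len(n))
      hits <- ev[rdt, on = "person_id", allow.cartesian = TRUE,
                 nomatch = NULL]
      if (nrow(hits)) {
        hits[, lb := ev_entries$lookback_days[match(code, ev_entries$code)]]
        hits <- hits[day < idx & (is.infinite(lb) | day >= idx - lb)]
        if (nrow(hits)) {
          hits <- unique(hits[, .(row_id, code)])
          for (k in seq_len(nrow(ev_entries))) {
            rid <- hits$row_id[hits$code == ev_entries$code[k]]
            if (length(rid)) {
              v <- out[[ev_entries$predictor[k]]]
              v[rid] <- 1L
              out[[ev_entries$predictor[k]]] <- v
            }
          }
        }
      }
    }
  }

  ## blood-test indicators
  bt_entries <- codebook[codebook$source == "tests", , drop = FALSE]
  if (nrow(bt_entries)) {
    for (nm in bt_entries$predictor) out[[nm]] <- integer(n)
    bt <- data.table::as.data.table(cohort$blood_tests)
    if (nrow(bt)) {
      if (anyNA(bt$test_family))
        stop("blood test with abnormal flag but no test_family label")
      bt[, day := as.numeric(date)]
      rdt <- data.table::data.table(person_id = rows$person_id, idx = idx,
                                    row_id = seq_len(n))
      hits <- bt[rdt, on = "person_id", allow.cartesian = TRUE,
                 nomatch = NULL]
      if (nrow(hits)) {
        for (k in seq_len(nrow(bt_entries))) {
          nm <- bt_entries$predictor[k]
          famk <- bt_entries$code[k]
          lbk <- bt_entries$lookback_days[k]
          sel <- hits$test_family == famk & hits$day < hits$idx &
            (is.infinite(lbk) | hits$day >= hits$idx - lbk)
          if (grepl("abnormal", nm)) sel <- sel & hits$abnormal == 1
          rid <- unique(hits$row_id[sel])
          if (length(rid)) {
            v <- out[[nm]]
            v[rid] <- 1L
            out[[nm]] <- v
          }
        }
      }
    }
  }

  missing_def <- setdiff(codebook$predictor, names(out)[!vapply(out, is.null,
                                                                logical(1))])
  if (length(missing_def))
    stop("codebook predictors with no derivation rule: ",
         paste(missing_def, collapse = ", "))
  as.data.frame(out[codebook$predictor], stringsAsFactors = FALSE)
}

#' Derive the predictor vector for one person at one index date
#'
#' Single-row convenience wrapper around [derive_predictor_table()]; no
#' missing-data policy is applied.
#'
#' @param person a person_id.
#' @param at_date index date (Date).
#' @param codebook predictor codebook.
#' @param cohort a `raw_cohort`.
#' @return one-row data.frame of predictor values.
#' @export
derive_vector <- function(person, at_date, codebook = default_codebook(),
                          cohort) {
  rows <- data.frame(person_id = person, index_date = as.Date(at_date))
  derive_predictor_table(rows, cohort, codebook)
}

#' Blood-test indicators for one person
#'
#' Four binaries per the measured/abnormal dual encoding: for each test
#' family (inflammation, iron), whether any test was taken in the lookback
#' window and whether any result in the window was abnormal. `abnormal`
#' implies `measured` by construction.
#'
#' @param tests data.frame of one person's blood tests (`date`,
#'   `test_family`, `abnormal`).
#' @param at_date index date.
#' @param lookback_days window length (days), default 730.
#' @return named integer vector: `inflammation_measured`,
#'   `inflammation_abnormal`, `iron_measured`, `iron_abnormal`.
#' @export
blood_test_indicators <- function(tests, at_date, lookback_days = 730) {
  if (nrow(tests) && anyNA(tests$test_family))
    stop("blood test with abnormal flag but no test_family label")
  idx <- as.numeric(as.Date(at_date))
  day <- as.numeric(as.Date(tests$date))
  inwin <- day < idx & day >= idx - lookback_days
  out <- integer(4)
  names(out) <- c("inflammation_measured", "inflammation_abnormal",
                  "iron_measured", "iron_abnormal")
  for (fam in c("inflammation", "iron")) {
    sel <- inwin & tests$test_family == fam
    out[paste0(fam, "_measured")] <- as.integer(any(sel))
    out[paste0(fam, "_abnormal")] <- as.integer(any(sel &
                                                      tests$abnormal == 1))
  }
  out
}

#' Apply the missing-data policy
#'
#' Smoking status and ethnicity keep their missing values as an explicit
#' `missing` category; any other baseline-sourced predictor with a missing
#' value marks the row for complete-case removal. Event- and test-sourced
#' predictors are never missing (absence of a record means 0). Categorical
#' predictors are converted to factors with a fixed reference level (first
#' listed level).
#'
#' @param pred predictor data.frame from [derive_predictor_table()].
#' @param codebook the codebook used to derive it.
#' @return list with `data` (filtered data.frame, factors encoded),
#'   `keep_rows` (logical vector over input rows) and `n_dropped`.
#' @export
apply_missing_policy <- function(pred, codebook = default_codebook()) {
  keep <- rep(TRUE, nrow(pred))
  for (k in seq_len(nrow(codebook))) {
    nm <- codebook$predictor[k]
    if (!nm %in% names(pred)) next
    x <- pred[[nm]]
    if (nm %in% .MISSING_CATEGORY_PREDICTORS) {
      x[is.na(x)] <- "missing"
      pred[[nm]] <- x
    } else if (codebook$source[k] %in% c("baseline", "derived")) {
      keep <- keep & !is.na(x)
    }
    if (codebook$encoding[k] == "categorical") {
      base_lv <- .FACTOR_LEVELS[[nm]]
      if (is.null(base_lv)) base_lv <- sort(unique(stats::na.omit(pred[[nm]])))
      lv <- if (nm %in% .MISSING_CATEGORY_PREDICTORS)
        c(base_lv, "missing") else base_lv
      pred[[nm]] <- factor(pred[[nm]], levels = lv)
    }
  }
  out <- droplevels(pred[keep, , drop = FALSE])
  list(data = out, keep_rows = keep, n_dropped = sum(!keep))
}
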
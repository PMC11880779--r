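#' Predictor sets
#'
#' Canonical order of the six predictor sets used throughout the package:
#' core demographics, polygenic score, presenting symptoms, medical history,
#' common blood tests and other lifestyle factors.
#'
#' @return character vector of length 6.
#' @export
predictor_sets <- function() {
  c("core", "pgs", "symptoms", "medical_history", "blood_tests", "lifestyle")
}

#' Default predictor codebook
#'
#' Declarative map from raw record streams to named predictors. Each row
#' defines one predictor: which of the six sets it belongs to, where its
#' value comes from (`baseline` questionnaire fields, coded clinical
#' `events`, blood `tests`, or `derived` from dates), the lookback window in
#' days for event-sourced predictors (`Inf` means "ever recorded"), and its
#' encoding.
#'
#' Set sizes follow the study design: core 8, polygenic score 1, symptoms 16
#' (eleven named gastrointestinal symptoms plus five configurable
#' placeholders), medical history 12, blood tests 4 (measured/abnormal
#' indicator pairs for inflammation and iron markers), lifestyle 5. The
#' `code` column names the clinical-event code an event-sourced predictor
#' counts; colonoscopy uses a 10-year window, "ever" conditions the full
#' prior history, and all other event-sourced predictors a 2-year window.
#'
#' @param symptom_lookback_days lookback for symptom predictors (days).
#' @return data.frame with columns `predictor`, `set`, `source`, `code`,
#'   `lookback_days`, `encoding`.
#' @export
default_codebook <- function(symptom_lookback_days = 730) {
  cb <- function(predictor, set, source, code = NA_character_,
                 lookback_days = NA_real_, encoding = "binary") {
    data.frame(predictor = predictor, set = set, source = source,
               code = code, lookback_days = lookback_days,
               encoding = encoding, stringsAsFactors = FALSE)
  }
  symptoms <- c("abdominal_bloating", "abdominal_pain", "bowel_habit_change",
                "constipation", "diarrhoea", "diverticular_disease",
                "fatigue", "haemorrhoids", "ibs", "rectal_bleed",
                "stomach_disorders",
                paste0("symptom_extra_", 1:5))
  rbind(
    # core (8)
    cb("age_at_index", "core", "derived", encoding = "continuous"),
    cb("sex", "core", "baseline", encoding = "categorical"),
    cb("birth_year", "core", "derived", encoding = "continuous"),
    cb("bmi", "core", "baseline", encoding = "continuous"),
    cb("ethnicity", "core", "baseline", encoding = "categorical"),
    cb("smoking_status", "core", "baseline", encoding = "categorical"),
    cb("townsend", "core", "baseline", encoding = "continuous"),
    cb("baseline_age", "core", "derived", encoding = "continuous"),
    # polygenic score (1), standardized to unit variance at simulation time
    cb("pgs", "pgs", "baseline", encoding = "continuous"),
    # symptoms (16)
    cb(symptoms, "symptoms", "events", code = symptoms,
       lookback_days = symptom_lookback_days),
    # medical history (12)
    cb("aspirin", "medical_history", "events", "aspirin", 730),
    cb("colonoscopy_10y", "medical_history", "events", "colonoscopy", 3650),
    cb("diabetes_t2_ever", "medical_history", "events", "diabetes_t2", Inf),
    cb("screening_eligible", "medical_history", "baseline"),
    cb("fam_hist_bowel", "medical_history", "baseline"),
    cb("fam_hist_breast", "medical_history", "baseline"),
    cb("fam_hist_lung", "medical_history", "baseline"),
    cb("gallbladder_ever", "medical_history", "events", "gallbladder", Inf),
    cb("ibd_ever", "medical_history", "events", "ibd", Inf),
    cb("multimorbidity_score", "medical_history", "baseline",
       encoding = "continuous"),
    cb("nsaids", "medical_history", "events", "nsaids", 730),
    cb("history_extra_1", "medical_history", "events", "history_extra_1", 730),
    # blood tests (4)
    cb("inflammation_measured", "blood_tests", "tests", "inflammation", 730),
    cb("inflammation_abnormal", "blood_tests", "tests", "inflammation", 730),
    cb("iron_measured", "blood_tests", "tests", "iron", 730),
    cb("iron_abnormal", "blood_tests", "tests", "iron", 730),
    # lifestyle (5)
    cb("alcohol", "lifestyle", "baseline", encoding = "continuous"),
    cb("education", "lifestyle", "baseline", encoding = "categorical"),
    cb("fibre", "lifestyle", "baseline", encoding = "continuous"),
    cb("processed_meat", "lifestyle", "baseline", encoding = "continuous"),
    cb("red_meat", "lifestyle", "baseline", encoding = "continuous")
  )
}

#' Predictor names belonging to one set
#'
#' @param codebook a codebook data.frame (see [default_codebook()]).
#' @param set one of [predictor_sets()].
#' @return character vector of predictor names.
#' @export
set_predictors <- function(codebook, set) {
  stopifnot(set %in% codebook$set)
  codebook$predictor[codebook$set == set]
}

#' Mapping from each predictor set to its predictors
#'
#' @param codebook a codebook data.frame.
#' @return named list, one character vector per set, in canonical set order.
#' @export
set_map <- function(codebook = default_codebook()) {
  sets <- intersect(predictor_sets(), unique(codebook$set))
  setNames(lapply(sets, set_predictors, codebook = codebook), sets)
}

validate_codebook <- function(codebook) {
  need <- c("predictor", "set", "source", "code", "lookback_days", "encoding")
  if (!all(need %in% names(codebook)))
    stop("codebook must have columns: ", paste(need, collapse = ", "))
  if (anyDuplicated(codebook$predictor))
    stop("codebook predictor names must be unique")
  if (!all(codebook$source %in% c("baseline", "events", "tests", "derived")))
    stop("unknown codebook source")
  invisible(codebook)
}
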
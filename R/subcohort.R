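# Symptomatic subcohort: data-driven selection of qualifying symptoms and
# the row filter they induce.

#' Select symptomatic-subcohort criteria by stepwise AIC
#'
#' Runs AIC-based bidirectional stepwise selection of a Cox model over the
#' symptom predictors only, and returns the selected symptom names. These
#' define the symptomatic subcohort: people with at least one selected
#' symptom recorded in the two years before a landmark age.
#'
#' @param data a `super_landmark` data.frame with outcome columns and
#'   symptom binaries.
#' @param codebook the codebook defining the symptom set.
#' @param ... passed to [stepwise_aic()].
#' @return character vector of selected symptom predictor names.
#' @export
select_symptom_criteria <- function(data, codebook = default_codebook(),
                                    ...) {
  if (sum(data$event) == 0) stop("no events in dataset")
  candidates <- set_predictors(codebook, "symptoms")
  candidates <- intersect(candidates, names(data))
  stepwise_aic(data, candidates, ...)
}

#' Restrict a super-landmark dataset to the symptomatic subcohort
#'
#' Keeps rows with at least one qualifying symptom indicator equal to 1.
#' In `selected` mode the qualifying symptoms are the `criteria` argument
#' (typically from [select_symptom_criteria()]); in `any_except_fatigue`
#' mode they are every symptom predictor except fatigue, which is not
#' specific enough to define symptomatic status.
#'
#' @param data a `super_landmark` data.frame.
#' @param criteria character vector of symptom predictor names (required in
#'   `selected` mode).
#' @param mode `"selected"` or `"any_except_fatigue"`.
#' @param codebook the codebook defining the symptom set.
#' @return the filtered data.frame (possibly empty, with a warning).
#' @export
symptomatic_subcohort <- function(data, criteria = NULL,
                                  mode = c("selected", "any_except_fatigue"),
                                  codebook = default_codebook()) {
  mode <- match.arg(mode)
  symptoms <- set_predictors(codebook, "symptoms")
  if (mode == "selected") {
    if (is.null(criteria) || length(criteria) == 0)
      stop("criteria must be a non-empty set of symptom names in selected mode")
    if (!all(criteria %in% symptoms))
      stop("criteria must be symptom predictors: ",
           paste(setdiff(criteria, symptoms), collapse = ", "))
  } else {
    criteria <- setdiff(symptoms, "fatigue")
  }
  criteria <- intersect(criteria, names(data))
  if (length(criteria) == 0) stop("no criteria columns present in data")
  any_sym <- Reduce(`|`, lapply(criteria, function(nm) data[[nm]] == 1))
  out <- data[any_sym, , drop = FALSE]
  if (nrow(out) == 0)
    warning("symptomatic subcohort is empty under the given criteria")
  out
}
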
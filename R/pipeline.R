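#' Run the full dynamic-risk analysis pipeline
#'
#' Convenience driver chaining the whole analysis on a synthetic cohort:
#' simulate records, build the super-landmark dataset, select predictors by
#' bidirectional stepwise AIC, fit the cluster-robust Cox model, evaluate
#' the C-index over all predictor-set combinations with a person-level
#' bootstrap, and decompose discrimination into per-set Shapley values.
#' Deterministic given `config$seed` and `grid_seed`.
#'
#' @param config a [sim_config()].
#' @param ages landmark ages to include.
#' @param B bootstrap replicates for the combination grid.
#' @param selection selection mode for the grid ([combination_grid()]).
#' @param candidates candidate terms for stepwise selection (default: all
#'   codebook predictors present in the data).
#' @param codebook predictor codebook.
#' @param grid_seed seed for the bootstrap replication stream (defaults to
#'   `config$seed + 1`).
#' @param min_replicates minimum usable replicates for the decomposition.
#' @return list with `cohort`, `data`, `selected`, `fit`, `grid`,
#'   `shapley`.
#' @export
run_pipeline <- function(config, ages = 40:74, B = 200,
                         selection = "frozen", candidates = NULL,
                         codebook = default_codebook(),
                         grid_seed = NULL, min_replicates = 10) {
  cohort <- simulate_cohort(config)
  data <- build_super_landmark(cohort, ages = ages, codebook = codebook)
  sets <- lapply(set_map(codebook), intersect, y = names(data))
  if (is.null(candidates)) candidates <- unname(unlist(sets))
  selected <- stepwise_aic(data, candidates)
  fit <- fit_cox(data, selected, cluster = "person_id")
  if (is.null(grid_seed)) grid_seed <- config$seed + 1L
  set.seed(grid_seed)
  grid <- combination_grid(data, sets = sets, B = B, selection = selection,
                           selected_terms = selected)
  shap <- decompose_grid(grid, min_replicates = min_replicates)
  list(cohort = cohort, data = data, selected = selected, fit = fit,
       grid = grid, shapley = shap)
}
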
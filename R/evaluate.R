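# Person-level bootstrap evaluation: out-of-bag train/test partitions and
# Harrell's C-index over all combinations of the predictor sets.

#' Person-level bootstrap partition
#'
#' Default scheme (`out_of_bag`): draws a with-replacement sample of person
#' IDs (same size as the number of distinct persons) as the training
#' multiset; the test set is the persons never sampled (out of bag), so
#' train and test are ID-disjoint by construction and the expected test
#' fraction is about `exp(-1)`. The alternative `split` scheme partitions
#' the distinct IDs into disjoint train/test halves without replacement
#' (`train_fraction` controls the split). Uses the current RNG state.
#'
#' @param person_ids vector of person IDs (duplicates allowed; partitioning
#'   is over distinct IDs).
#' @param scheme `"out_of_bag"` or `"split"`.
#' @param train_fraction train share under the `split` scheme.
#' @param max_tries resample attempts before giving up when the out-of-bag
#'   set comes up empty (only possible for tiny ID sets).
#' @return list with `train` (multiset of IDs; with repeats under
#'   `out_of_bag`) and `test` (disjoint vector of test IDs).
#' @export
bootstrap_partition <- function(person_ids,
                                scheme = c("out_of_bag", "split"),
                                train_fraction = 0.5, max_tries = 100) {
  scheme <- match.arg(scheme)
  ids <- unique(person_ids)
  if (scheme == "split") {
    if (length(ids) < 2) stop("need at least 2 distinct ids to split")
    n_train <- max(1, min(length(ids) - 1,
                          round(train_fraction * length(ids))))
    train <- sample(ids, n_train)
    return(list(train = train, test = setdiff(ids, train)))
  }
  for (k in seq_len(max_tries)) {
    train <- sample(ids, length(ids), replace = TRUE)
    test <- setdiff(ids, train)
    if (length(test) > 0) {
      if (k > 1)
        warning("resampled ", k - 1, " time(s) to obtain a non-empty ",
                "out-of-bag test set")
      return(list(train = train, test = test))
    }
  }
  stop("could not obtain a non-empty out-of-bag test set in ", max_tries,
       " tries")
}

all_subsets <- function(set_names) {
  n <- length(set_names)
  ids <- 0:(2^n - 1)
  members <- lapply(ids, function(m) set_names[bitwAnd(m, 2^(seq_len(n) - 1))
                                               > 0])
  labels <- vapply(members, function(s)
    if (length(s)) paste(s, collapse = "+") else "(none)", "")
  list(id = ids, members = members, labels = labels)
}

# Linear predictor on new rows; factor levels never seen in the training
# fold (possible for rare categories under bootstrap resampling) are mapped
# to the fold's reference level rather than failing the replicate.
score_lp <- function(fit, newdata) {
  out <- tryCatch(unname(stats::predict(fit, newdata = newdata,
                                        type = "lp")),
                  error = function(e) NULL)
  if (!is.null(out)) return(out)
  for (nm in names(fit$xlevels)) {
    x <- as.character(newdata[[nm]])
    lv <- fit$xlevels[[nm]]
    x[!x %in% lv] <- lv[1]
    newdata[[nm]] <- factor(x, levels = lv)
  }
  tryCatch(unname(stats::predict(fit, newdata = newdata, type = "lp")),
           error = function(e) NULL)
}

# Cox fit for grid scoring: drops terms constant in the training rows
# (they cannot contribute to discrimination) and returns NULL if nothing
# fittable remains or the fit fails.
grid_fit <- function(train, terms, ties = "efron") {
  keep <- vapply(terms, function(tm) {
    x <- train[[tm]]
    if (is.factor(x)) length(unique(as.character(x))) > 1 else
      length(unique(x)) > 1
  }, logical(1))
  terms <- terms[keep]
  if (length(terms) == 0) return(NULL)
  fit <- tryCatch(suppressWarnings(fit_cox(train, terms, cluster = NULL,
                                           ties = ties)),
                  error = function(e) NULL)
  if (is.null(fit)) return(NULL)
  if (anyNA(fit$coefficients)) {
    # separated groups (no events in the fold) carry no usable signal;
    # score their rows at the reference level
    fit$fit$coefficients[is.na(fit$fit$coefficients)] <- 0
    fit$coefficients <- fit$fit$coefficients
  }
  fit
}

#' C-index grid over all predictor-set combinations
#'
#' For each of `B` person-level bootstrap replicates, fits a Cox model for
#' every subset of the predictor sets on the training rows and records
#' Harrell's C-index of its linear predictor on the out-of-bag test rows.
#' The empty subset is assigned chance discrimination `v_empty`. With
#' `selection = "frozen"` (the default), stepwise selection is run once on
#' the full dataset and each subset uses the selected terms intersected with
#' the subset's predictors; `"per_fit"` re-runs selection inside every
#' training fit; `"none"` uses every predictor of the subset.
#'
#' A subset whose term list is empty after intersection scores `v_empty`
#' (its model carries no information). Failed sub-fits or test folds with no
#' comparable pairs are recorded as `NA`.
#'
#' @param data a `super_landmark` data.frame (or any data.frame with
#'   `person_id`, `time_days`, `event` and predictor columns).
#' @param sets named list mapping each predictor set to its predictor names
#'   (default: [set_map()] of the attached codebook, restricted to columns
#'   present).
#' @param B number of bootstrap replicates (200 in the reference design).
#' @param selection `"frozen"`, `"per_fit"` or `"none"`.
#' @param selected_terms term list to freeze (computed by [stepwise_aic()]
#'   over all set predictors when `NULL` and `selection = "frozen"`).
#' @param v_empty value of the empty subset (0.5 = chance).
#' @param ties tie handling for the Cox fits.
#' @param scheme person-partition scheme, see [bootstrap_partition()].
#' @return object of class `combination_grid`: data.frame with columns
#'   `replicate`, `subset_id`, `subset`, `size`, `cindex`; attributes
#'   `sets`, `B`, `v_empty`, `selected_terms`.
#' @export
combination_grid <- function(data, sets = NULL, B = 200,
                             selection = c("frozen", "per_fit", "none"),
                             selected_terms = NULL, v_empty = 0.5,
                             ties = "efron",
                             scheme = c("out_of_bag", "split")) {
  scheme <- match.arg(scheme)
  selection <- match.arg(selection)
  if (is.null(sets)) {
    cb <- attr(data, "codebook")
    if (is.null(cb)) stop("sets not given and data carries no codebook")
    sets <- set_map(cb)
  }
  sets <- lapply(sets, intersect, y = names(data))
  if (any(lengths(sets) == 0)) stop("predictor set with no columns in data")
  all_terms <- unname(unlist(sets))

  if (selection == "frozen" && is.null(selected_terms))
    selected_terms <- stepwise_aic(data, all_terms, ties = ties)

  sub <- all_subsets(names(sets))
  n_sub <- length(sub$id)
  subset_terms <- lapply(sub$members, function(s) {
    tms <- unname(unlist(sets[s]))
    if (selection == "frozen") intersect(tms, selected_terms) else tms
  })

  rows_by_person <- split(seq_len(nrow(data)), data$person_id)
  ids <- names(rows_by_person)

  res <- matrix(NA_real_, nrow = B, ncol = n_sub)
  for (b in seq_len(B)) {
    part <- bootstrap_partition(ids, scheme = scheme)
    train_idx <- unlist(rows_by_person[part$train], use.names = FALSE)
    test_idx <- unlist(rows_by_person[part$test], use.names = FALSE)
    train <- data[train_idx, , drop = FALSE]
    test <- data[test_idx, , drop = FALSE]
    for (k in seq_len(n_sub)) {
      if (length(sub$members[[k]]) == 0) {
        res[b, k] <- v_empty
        next
      }
      terms_k <- subset_terms[[k]]
      if (selection == "per_fit" && length(terms_k))
        terms_k <- tryCatch(stepwise_aic(train, terms_k, ties = ties),
                            error = function(e) character(0))
      if (length(terms_k) == 0) {
        res[b, k] <- v_empty
        next
      }
      fit <- grid_fit(train, terms_k, ties)
      if (is.null(fit)) next
      lp <- score_lp(fit$fit, test)
      if (is.null(lp)) next
      res[b, k] <- tryCatch(harrells_c(lp, test$time_days, test$event),
                            error = function(e) NA_real_)
    }
  }

  out <- data.frame(
    replicate = rep(seq_len(B), each = n_sub),
    subset_id = rep(sub$id, B),
    subset = rep(sub$labels, B),
    size = rep(lengths(sub$members), B),
    cindex = as.vector(t(res)),
    stringsAsFactors = FALSE)
  attr(out, "sets") <- sets
  attr(out, "B") <- B
  attr(out, "v_empty") <- v_empty
  attr(out, "selected_terms") <- selected_terms
  class(out) <- c("combination_grid", "data.frame")
  out
}

#' Mean C-index per predictor-set combination
#'
#' Summarizes a [combination_grid()] across replicates: mean and percentile
#' interval of the C-index for each subset of predictor sets.
#'
#' @param grid a `combination_grid`.
#' @param conf_level confidence level for the percentile interval.
#' @return data.frame: subset_id, subset, size, mean_cindex, lower, upper,
#'   n_replicates (non-missing).
#' @export
summarize_grid <- function(grid, conf_level = 0.95) {
  a <- (1 - conf_level) / 2
  sp <- split(grid$cindex, grid$subset_id)
  ids <- as.integer(names(sp))
  o <- order(ids)
  first <- !duplicated(grid$subset_id)
  lab <- grid$subset[first][match(ids[o], grid$subset_id[first])]
  sz <- grid$size[first][match(ids[o], grid$subset_id[first])]
  vals <- sp[o]
  data.frame(
    subset_id = ids[o], subset = lab, size = sz,
    mean_cindex = vapply(vals, function(v) mean(v, na.rm = TRUE), 0),
    lower = vapply(vals, function(v)
      stats::quantile(v, a, na.rm = TRUE, names = FALSE), 0),
    upper = vapply(vals, function(v)
      stats::quantile(v, 1 - a, na.rm = TRUE, names = FALSE), 0),
    n_replicates = vapply(vals, function(v) sum(!is.na(v)), 0L),
    row.names = NULL)
}
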
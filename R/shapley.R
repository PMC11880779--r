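# Order-agnostic Shapley decomposition of model discrimination over
# predictor sets. The value function maps every subset of sets to a C-index;
# the empty set is worth chance discrimination (0.5) so contributions are
# "to the C-index above 0.5".

#' Construct a value function over predictor-set subsets
#'
#' @param v numeric vector of length `2^n` with `v[mask + 1]` the value of
#'   the subset encoded by bitmask `mask` over `players` (bit `j` set means
#'   player `j` present); `v[1]` is the empty set.
#' @param players character vector of player (predictor-set) names.
#' @return object of class `value_function`.
#' @export
value_function <- function(v, players) {
  n <- length(players)
  if (length(v) != 2^n)
    stop("v must have length 2^n; missing subset values")
  if (anyNA(v)) stop("value function has missing subset values")
  structure(list(v = as.numeric(v), players = players, n = n),
            class = "value_function")
}

subset_sizes <- function(n) {
  ids <- 0:(2^n - 1)
  vapply(ids, function(m) sum(bitwAnd(m, 2^(0:(n - 1))) > 0), 0)
}

#' Shapley values by the subset-weight formula
#'
#' For each player `j`, the weighted average of its marginal contributions
#' `v(S + j) - v(S)` over all subsets `S` not containing `j`, with weight
#' `|S|! (n - |S| - 1)! / n!`. This equals the average marginal contribution
#' over all `n!` join orders (see [shapley_permutation_oracle()]).
#'
#' @param vf a [value_function()].
#' @return named numeric vector of Shapley values, one per player.
#' @export
shapley_values <- function(vf) {
  stopifnot(inherits(vf, "value_function"))
  n <- vf$n
  v <- vf$v
  sizes <- subset_sizes(n)
  w <- factorial(0:(n - 1)) * factorial(n - 1 - 0:(n - 1)) / factorial(n)
  phi <- numeric(n)
  ids <- 0:(2^n - 1)
  for (j in seq_len(n)) {
    bit <- 2^(j - 1)
    s_wo <- ids[bitwAnd(ids, bit) == 0]
    phi[j] <- sum(w[sizes[s_wo + 1] + 1] * (v[s_wo + bit + 1] - v[s_wo + 1]))
  }
  names(phi) <- vf$players
  phi
}

all_permutations <- function(n) {
  if (n == 1) return(matrix(1L))
  p <- all_permutations(n - 1)
  out <- vector("list", n)
  for (k in seq_len(n)) {
    q <- p
    q[q >= k] <- q[q >= k] + 1L
    out[[k]] <- cbind(rep(k, nrow(q)), q)
  }
  do.call(rbind, out)
}

#' Shapley values by exhaustive ordering enumeration
#'
#' Independent oracle for [shapley_values()]: averages each player's
#' marginal contribution over every one of the `n!` join orders. Exact but
#' exponential; limited to `n <= 8`.
#'
#' @param vf a [value_function()].
#' @return named numeric vector of Shapley values.
#' @export
shapley_permutation_oracle <- function(vf) {
  stopifnot(inherits(vf, "value_function"))
  n <- vf$n
  if (n > 8) stop("permutation oracle limited to 8 players")
  v <- vf$v
  perms <- all_permutations(n)
  phi <- numeric(n)
  for (r in seq_len(nrow(perms))) {
    mask <- 0
    for (k in seq_len(n)) {
      j <- perms[r, k]
      nxt <- mask + 2^(j - 1)
      phi[j] <- phi[j] + v[nxt + 1] - v[mask + 1]
      mask <- nxt
    }
  }
  phi <- phi / nrow(perms)
  names(phi) <- vf$players
  phi
}

#' Percentage contributions to discrimination above chance
#'
#' Expresses Shapley values as percentages of the full model's C-index gain
#' over the empty-model value: `100 * phi_j / (v_full - v_empty)`. Negative
#' percentages are legitimate (a set can lower out-of-sample
#' discrimination); they sum to 100 with the positive ones.
#'
#' @param phi Shapley values.
#' @param v_full value of the grand coalition (full-model C-index).
#' @param v_empty value of the empty set (default 0.5, chance).
#' @return named numeric vector of percentages.
#' @export
shapley_percentages <- function(phi, v_full, v_empty = 0.5) {
  if (v_full == v_empty)
    stop("v_full equals v_empty; percentage contributions undefined")
  100 * phi / (v_full - v_empty)
}

#' Shapley decomposition of a bootstrap C-index grid
#'
#' Computes Shapley values and percentage contributions per bootstrap
#' replicate from that replicate's subset C-indices, then aggregates:
#' point estimates are replicate means (or medians) and confidence
#' intervals are percentile intervals over replicates. Computing
#' percentages per replicate (rather than from the averaged grid) is what
#' makes the percentile intervals valid. Replicates with any missing subset
#' value are dropped whole; fewer than `min_replicates` usable replicates is
#' an error. The efficiency axiom, `sum(phi) = v(full) - v_empty`, is
#' asserted per replicate to 1e-12.
#'
#' @param grid a [combination_grid()].
#' @param v_empty value of the empty subset (defaults to the grid's).
#' @param point `"mean"` or `"median"` point estimate.
#' @param conf_level confidence level for percentile intervals.
#' @param min_replicates minimum usable replicates (default 10).
#' @return object of class `shapley_result`: `sets`, `phi`, `phi_ci`,
#'   `pct`, `pct_ci`, `v_full`, `v_full_ci`, `n_replicates`, and the
#'   per-replicate `phi_replicates` / `pct_replicates` matrices.
#' @export
decompose_grid <- function(grid, v_empty = NULL,
                           point = c("mean", "median"), conf_level = 0.95,
                           min_replicates = 10) {
  point <- match.arg(point)
  if (is.null(v_empty)) v_empty <- attr(grid, "v_empty")
  if (is.null(v_empty)) v_empty <- 0.5
  sets <- names(attr(grid, "sets"))
  if (is.null(sets))
    sets <- attr(grid, "set_names")
  n <- length(sets)
  if (n == 0) stop("grid carries no predictor-set names")
  full_id <- 2^n - 1

  reps <- split(grid, grid$replicate)
  usable <- Filter(function(g) !anyNA(g$cindex) && nrow(g) == 2^n, reps)
  if (length(usable) < min_replicates)
    stop("fewer than ", min_replicates, " usable replicates (",
         length(usable), ")")

  phi_mat <- matrix(NA_real_, length(usable), n,
                    dimnames = list(NULL, sets))
  pct_mat <- phi_mat
  v_full <- numeric(length(usable))
  for (b in seq_along(usable)) {
    g <- usable[[b]]
    v <- g$cindex[order(g$subset_id)]
    v[1] <- v_empty
    vf <- value_function(v, sets)
    phi_b <- shapley_values(vf)
    vf_full <- v[full_id + 1]
    if (abs(sum(phi_b) - (vf_full - v_empty)) > 1e-12)
      stop("efficiency violated in replicate ", b)
    phi_mat[b, ] <- phi_b
    pct_mat[b, ] <- shapley_percentages(phi_b, vf_full, v_empty)
    v_full[b] <- vf_full
  }

  agg <- if (point == "mean") colMeans else
    function(m) apply(m, 2, stats::median)
  a <- (1 - conf_level) / 2
  ci <- function(m) apply(m, 2, stats::quantile, probs = c(a, 1 - a),
                          names = FALSE)
  out <- list(sets = sets,
              phi = agg(phi_mat), phi_ci = ci(phi_mat),
              pct = agg(pct_mat), pct_ci = ci(pct_mat),
              v_full = if (point == "mean") mean(v_full) else
                stats::median(v_full),
              v_full_ci = stats::quantile(v_full, probs = c(a, 1 - a),
                                          names = FALSE),
              v_empty = v_empty,
              n_replicates = length(usable),
              phi_replicates = phi_mat, pct_replicates = pct_mat)
  class(out) <- "shapley_result"
  out
}

#' @export
print.shapley_result <- function(x, ...) {
  cat("Shapley decomposition of the C-index over", length(x$sets),
      "predictor sets\n")
  cat(sprintf("Full-model C-index: %.3f (%.3f to %.3f), %d replicates\n",
              x$v_full, x$v_full_ci[1], x$v_full_ci[2], x$n_replicates))
  tab <- data.frame(
    set = x$sets,
    phi = sprintf("%.4f", x$phi),
    phi_ci = sprintf("(%.4f, %.4f)", x$phi_ci[1, ], x$phi_ci[2, ]),
    pct = sprintf("%.1f%%", x$pct),
    pct_ci = sprintf("(%.1f%%, %.1f%%)", x$pct_ci[1, ], x$pct_ci[2, ]))
  print(tab, row.names = FALSE)
  invisible(x)
}

#' Tabulate a Shapley decomposition
#'
#' @param x a `shapley_result`.
#' @return data.frame with one row per predictor set: phi, phi CI, pct,
#'   pct CI.
#' @export
shapley_table <- function(x) {
  stopifnot(inherits(x, "shapley_result"))
  data.frame(set = x$sets, phi = unname(x$phi),
             phi_lower = x$phi_ci[1, ], phi_upper = x$phi_ci[2, ],
             pct = unname(x$pct),
             pct_lower = x$pct_ci[1, ], pct_upper = x$pct_ci[2, ],
             row.names = NULL)
}
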
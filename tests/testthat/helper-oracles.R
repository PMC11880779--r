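# Independent oracles: deliberately simple implementations kept separate
# from the package code paths they check.

# Exhaustive pairwise concordance: loop over all ordered pairs, count a pair
# when the strictly shorter time has the event.
oracle_cindex <- function(scores, time_days, events) {
  n <- length(scores)
  conc <- 0
  comp <- 0
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i == j) next
      if (time_days[i] < time_days[j] && events[i] == 1) {
        comp <- comp + 1
        if (scores[i] > scores[j]) conc <- conc + 1
        else if (scores[i] == scores[j]) conc <- conc + 0.5
      }
    }
  }
  if (comp == 0) stop("no comparable pairs")
  conc / comp
}

# Hand-coded Cox partial log-likelihood for a single covariate with no tied
# event times (Breslow/Efron/exact coincide in that case).
oracle_partial_loglik <- function(beta, x, time_days, events) {
  ll <- 0
  for (i in which(events == 1)) {
    risk <- time_days >= time_days[i]
    ll <- ll + beta * x[i] - log(sum(exp(beta * x[risk])))
  }
  ll
}

# Grid-search maximizer of the oracle partial likelihood.
oracle_cox_beta <- function(x, time_days, events, lo = -5, hi = 5) {
  coarse <- seq(lo, hi, by = 0.01)
  ll <- vapply(coarse, oracle_partial_loglik, 0, x = x,
               time_days = time_days, events = events)
  b0 <- coarse[which.max(ll)]
  fine <- seq(b0 - 0.01, b0 + 0.01, by = 1e-5)
  llf <- vapply(fine, oracle_partial_loglik, 0, x = x,
                time_days = time_days, events = events)
  fine[which.max(llf)]
}

# Random value function over n players with v(empty) fixed.
random_value_function <- function(n, v_empty = 0.5) {
  v <- runif(2^n)
  v[1] <- v_empty
  value_function(v, players = paste0("set", seq_len(n)))
}

# Random censored survival data, including heavy score/time ties.
random_survival_data <- function(n) {
  list(scores = sample(1:5, n, replace = TRUE) + ifelse(runif(n) < 0.5,
                                                        0, runif(n)),
       time_days = sample(1:50, n, replace = TRUE),
       events = rbinom(n, 1, 0.6))
}
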
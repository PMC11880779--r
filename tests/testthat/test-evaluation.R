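# Evaluation: Harrell's C against the exhaustive-pair oracle, out-of-bag
# bootstrap partitions, the combination grid and calibration deciles.

test_that("harrells_c matches hand-worked examples", {
  # perfect ranking, all events
  expect_equal(harrells_c(5:1, 1:5, rep(1, 5)), 1)
  # all scores tied
  expect_equal(harrells_c(rep(2, 6), 1:6, rep(1, 6)), 0.5)
  # worked example: one concordant, one discordant, one incomparable pair
  expect_equal(harrells_c(c(2, 1, 3), c(5, 10, 7), c(1, 1, 0)), 0.5)
  # censored-only data has no comparable pairs
  expect_error(harrells_c(1:4, 1:4, rep(0, 4)), "no comparable pairs")
  expect_error(harrells_c(1:3, 1:2, c(1, 0)), "equal length")
})

test_that("harrells_c equals the exhaustive pairwise oracle with ties", {
  set.seed(301)
  for (r in 1:60) {
    n <- sample(5:120, 1)
    d <- random_survival_data(n)
    if (sum(d$events) == 0) next
    got <- tryCatch(harrells_c(d$scores, d$time_days, d$events),
                    error = function(e) NULL)
    want <- tryCatch(oracle_cindex(d$scores, d$time_days, d$events),
                     error = function(e) NULL)
    expect_identical(is.null(got), is.null(want))
    if (!is.null(got)) expect_equal(got, want, tolerance = 1e-12)
  }
})

test_that("bootstrap partitions are ID-disjoint with e^-1 out-of-bag mass", {
  set.seed(11)
  fr <- replicate(200, {
    p <- bootstrap_partition(1:1000)
    expect_length(intersect(p$train, p$test), 0)
    expect_length(p$train, 1000)
    length(p$test) / 1000
  })
  expect_lt(abs(mean(fr) - exp(-1)), 0.03)
  # degenerate single-ID input can never produce an out-of-bag set
  expect_error(bootstrap_partition("A"), "out-of-bag")

  # alternative scheme: disjoint half-split without replacement
  p <- bootstrap_partition(1:100, scheme = "split")
  expect_length(p$train, 50)
  expect_length(p$test, 50)
  expect_length(intersect(p$train, p$test), 0)
  expect_false(anyDuplicated(p$train) > 0)
  expect_error(bootstrap_partition("A", scheme = "split"), "2 distinct")
})

test_that("combination grid has the subset-lattice shape", {
  set.seed(5)
  n <- 400
  toy <- data.frame(person_id = rep(1:(n / 2), each = 2),
                    time_days = ceiling(rexp(n, 1 / 500)),
                    event = rbinom(n, 1, 0.3),
                    a1 = rnorm(n), b1 = rnorm(n))
  g <- combination_grid(toy, sets = list(a = "a1", b = "b1"), B = 2,
                        selection = "none")
  expect_equal(nrow(g), 2 * 4)
  expect_equal(sort(unique(g$subset_id)), 0:3)
  expect_true(all(g$cindex[g$subset_id == 0] == 0.5))
  expect_true(all(g$cindex >= 0 & g$cindex <= 1, na.rm = TRUE))
  expect_equal(attr(g, "B"), 2)

  # per-fit re-selection and the split scheme both run end to end
  g2 <- combination_grid(toy, sets = list(a = "a1", b = "b1"), B = 2,
                         selection = "per_fit", scheme = "split")
  expect_equal(nrow(g2), 2 * 4)
  expect_true(all(g2$cindex[g2$subset_id == 0] == 0.5))
})

test_that("signal sets dominate noise sets in expected C-index", {
  set.seed(9)
  n <- 3000
  x1 <- rnorm(n)
  x2 <- rnorm(n)
  lam <- 0.001 * exp(0.9 * x1)
  t_ev <- rexp(n, lam)
  toy <- data.frame(person_id = 1:n,
                    time_days = pmin(ceiling(t_ev), 730),
                    event = as.integer(t_ev <= 730),
                    x1 = x1, x2 = x2)
  g <- combination_grid(toy, sets = list(s1 = "x1", s2 = "x2"), B = 20,
                        selection = "none")
  m <- tapply(g$cindex, g$subset, mean, na.rm = TRUE)
  expect_gt(m[["s1"]], m[["s2"]] + 0.05)
  expect_gt(m[["s1"]], 0.65)
  expect_lt(abs(m[["s2"]] - 0.5), 0.05)
  # adding a signal-bearing set never hurts in expectation
  expect_gt(m[["s1+s2"]], m[["s2"]] + 0.05)
})

test_that("out-of-bag C of the fitted model approaches the oracle C", {
  d <- medium_landmark()
  sets <- list(pgs = "pgs", bloods = "iron_abnormal",
               symptoms = "rectal_bleed", core = "age_at_index")
  set.seed(21)
  g <- combination_grid(d, sets = sets, B = 30, selection = "none")
  full <- g$cindex[g$subset_id == 15]
  # oracle: score every row by the true data-generating linear predictor
  cfg <- sim_config(n_persons = 10, seed = 1)  # carries the default truth
  lp_true <- as.matrix(d[, names(cfg$true_log_hrs)]) %*% cfg$true_log_hrs
  c_true <- harrells_c(as.vector(lp_true), d$time_days, d$event)
  expect_lt(abs(mean(full, na.rm = TRUE) - c_true), 0.02)
})

test_that("frozen selection restricts subset fits to selected terms", {
  d <- medium_landmark()
  sets <- list(pgs = "pgs", bloods = c("iron_abnormal", "iron_measured"))
  set.seed(3)
  g <- combination_grid(d, sets = sets, B = 3, selection = "frozen",
                        selected_terms = c("pgs"))
  # the bloods set has no selected terms, so it scores exactly v_empty
  expect_true(all(g$cindex[g$subset == "bloods"] == 0.5))
  expect_false(all(g$cindex[g$subset == "pgs"] == 0.5))
  s <- summarize_grid(g)
  expect_equal(nrow(s), 4)
  expect_true(all(s$lower <= s$mean_cindex & s$mean_cindex <= s$upper))
})

test_that("calibration deciles partition rows and degrade gracefully on ties", {
  d <- medium_landmark()
  f <- fit_cox(d, c("pgs", "iron_abnormal", "rectal_bleed", "age_at_index"))
  pr <- predict_risk(f, d)
  tab <- calibration_deciles(pr, d$time_days, d$event)
  expect_equal(sum(tab$n), nrow(d))
  expect_true(all(tab$observed >= 0 & tab$observed <= 1))
  expect_true(all(diff(tab$mean_predicted) > 0))
  # all-equal risks collapse into one group matching the overall KM risk
  expect_warning(tab1 <- calibration_deciles(rep(0.1, nrow(d)),
                                             d$time_days, d$event),
                 "tied predicted risks")
  expect_equal(nrow(tab1), 1)
  km <- 1 - summary(survival::survfit(survival::Surv(time_days, event) ~ 1,
                                      data = d), times = 730,
                    extend = TRUE)$surv
  expect_equal(tab1$observed, km, tolerance = 1e-10)
})
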
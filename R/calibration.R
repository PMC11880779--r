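# Calibration of absolute risk at the 2-year horizon: decile plots of
# observed (Kaplan-Meier complement) against mean predicted risk.

km_risk_at <- function(time_days, events, horizon) {
  sf <- survival::survfit(survival::Surv(time_days, events) ~ 1)
  s <- summary(sf, times = horizon, extend = TRUE)$surv
  1 - s
}

#' Calibration deciles
#'
#' Partitions rows into groups by predicted risk (deciles by default) and
#' compares the mean predicted risk in each group with the observed risk,
#' `1 - KM(horizon)`, within the group. When predicted risks are heavily
#' tied, quantile breaks coincide and adjacent groups are merged with a
#' warning.
#'
#' @param predicted predicted absolute risks (see [predict_risk()]).
#' @param time_days follow-up times.
#' @param events event indicators `{0, 1}`.
#' @param horizon_days horizon at which observed risk is evaluated.
#' @param n_groups number of risk groups (default 10).
#' @return data.frame of class `calibration_table`: `group`, `n`,
#'   `mean_predicted`, `observed`.
#' @export
calibration_deciles <- function(predicted, time_days, events,
                                horizon_days = 730, n_groups = 10) {
  stopifnot(length(predicted) == length(time_days),
            length(predicted) == length(events))
  br <- unique(stats::quantile(predicted, probs = seq(0, 1,
                                                      length.out = n_groups
                                                      + 1)))
  if (length(br) < n_groups + 1)
    warning("tied predicted risks: ", n_groups + 1 - length(br),
            " group boundaries merged")
  if (length(br) == 1) br <- c(br - 1e-12, br + 1e-12)
  grp <- cut(predicted, breaks = br, include.lowest = TRUE, labels = FALSE)
  gs <- sort(unique(grp))
  out <- data.frame(
    group = seq_along(gs),
    n = vapply(gs, function(g) sum(grp == g), 0L),
    mean_predicted = vapply(gs, function(g) mean(predicted[grp == g]), 0),
    observed = vapply(gs, function(g)
      km_risk_at(time_days[grp == g], events[grp == g], horizon_days), 0))
  class(out) <- c("calibration_table", "data.frame")
  out
}

#' Calibration slope across risk groups
#'
#' Slope of the least-squares regression of observed on mean predicted risk
#' over the groups of a calibration table; 1 indicates calibration in the
#' large and correct risk spread.
#'
#' @param tab a `calibration_table`.
#' @return numeric slope.
#' @export
calibration_slope <- function(tab) {
  unname(stats::coef(stats::lm(observed ~ mean_predicted, data = tab))[2])
}

#' Bootstrap calibration deciles with percentile intervals
#'
#' For each of `B` person-level bootstrap replicates: fit the model terms on
#' the training rows, predict absolute risk on the out-of-bag test rows,
#' form risk deciles and record observed vs predicted per decile. Reports
#' per-decile means over replicates with percentile confidence intervals
#' for the observed risk.
#'
#' @param data a `super_landmark` data.frame.
#' @param terms model terms to fit.
#' @param B number of bootstrap replicates.
#' @param horizon_days prediction horizon.
#' @param n_groups number of risk groups.
#' @param conf_level confidence level for the percentile intervals.
#' @return data.frame: group, mean_predicted, observed, obs_lower,
#'   obs_upper, n_replicates.
#' @export
calibration_deciles_boot <- function(data, terms, B = 200,
                                     horizon_days = 730, n_groups = 10,
                                     conf_level = 0.95) {
  rows_by_person <- split(seq_len(nrow(data)), data$person_id)
  ids <- names(rows_by_person)
  pred_mat <- matrix(NA_real_, B, n_groups)
  obs_mat <- matrix(NA_real_, B, n_groups)
  for (b in seq_len(B)) {
    part <- bootstrap_partition(ids)
    train <- data[unlist(rows_by_person[part$train], use.names = FALSE), ,
                  drop = FALSE]
    test <- data[unlist(rows_by_person[part$test], use.names = FALSE), ,
                 drop = FALSE]
    fit <- grid_fit(train, terms)
    if (is.null(fit)) next
    pr <- tryCatch(predict_risk(fit, test, horizon_days),
                   error = function(e) NULL)
    if (is.null(pr)) next
    tab <- suppressWarnings(
      calibration_deciles(pr, test$time_days, test$event, horizon_days,
                          n_groups))
    pred_mat[b, tab$group] <- tab$mean_predicted
    obs_mat[b, tab$group] <- tab$observed
  }
  a <- (1 - conf_level) / 2
  data.frame(
    group = seq_len(n_groups),
    mean_predicted = colMeans(pred_mat, na.rm = TRUE),
    observed = colMeans(obs_mat, na.rm = TRUE),
    obs_lower = apply(obs_mat, 2, stats::quantile, probs = a,
                      na.rm = TRUE, names = FALSE),
    obs_upper = apply(obs_mat, 2, stats::quantile, probs = 1 - a,
                      na.rm = TRUE, names = FALSE),
    n_replicates = apply(obs_mat, 2, function(v) sum(!is.na(v))))
}
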
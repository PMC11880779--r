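# Cox proportional-hazards fitting on the stacked super-landmark dataset:
# cluster-robust (sandwich) variance over persons, partial-likelihood AIC,
# bidirectional stepwise selection, and absolute risk at a horizon.

check_terms <- function(data, terms) {
  for (tm in terms) {
    if (!tm %in% names(data)) stop("term not found in data: ", tm)
    x <- data[[tm]]
    nuniq <- if (is.factor(x)) length(unique(as.character(x[!is.na(x)])))
             else length(unique(x[!is.na(x)]))
    if (nuniq < 2) stop("constant term: ", tm)
  }
  invisible(TRUE)
}

cox_formula <- function(terms) {
  rhs <- if (length(terms)) paste(terms, collapse = " + ") else "1"
  stats::as.formula(paste("survival::Surv(time_days, event) ~", rhs))
}

#' Fit a Cox proportional-hazards model with cluster-robust errors
#'
#' Fits the partial likelihood with Efron tie handling (index dates are
#' month starts, so event-time ties are heavy) and, by default, computes the
#' cluster-robust sandwich covariance with clusters defined by `person_id`,
#' accounting for people contributing rows at several landmark ages. AIC is
#' `-2 * log partial likelihood + 2 * p` with `p` the number of estimated
#' coefficients.
#'
#' @param data data.frame with `time_days`, `event`, the term columns and
#'   (if `cluster` is used) `person_id`.
#' @param terms character vector of predictor names; `character(0)` fits the
#'   null model.
#' @param cluster column name to cluster the sandwich variance on, or `NULL`
#'   for the naive (model-based) variance only.
#' @param ties tie-handling method, default `"efron"`.
#' @return object of class `cox_fit`: coefficients, `robust_cov`,
#'   `naive_cov`, `loglik`, `aic`, `n`, `n_events`, `terms`, `converged`,
#'   and the underlying `coxph` fit as `$fit`.
#' @export
fit_cox <- function(data, terms, cluster = "person_id", ties = "efron") {
  if (sum(data$event) < 1) stop("dataset has zero events")
  check_terms(data, terms)
  # unused factor levels (possible in bootstrap folds) would give all-zero
  # design columns; drop them so they are not mistaken for collinearity
  for (tm in terms) {
    x <- data[[tm]]
    if (is.factor(x) && any(tabulate(x, nbins = nlevels(x)) == 0))
      data[[tm]] <- droplevels(x)
  }
  # collinearity among terms: detected post-fit via undetermined coefficients
  f <- cox_formula(terms)
  ctl <- survival::coxph.control(iter.max = 100, eps = 1e-9)
  converged <- TRUE
  withCallingHandlers({
    if (!is.null(cluster)) {
      if (!cluster %in% names(data))
        stop("cluster column not found in data: ", cluster)
      # coxph evaluates `cluster` inside `data`, so splice the column name in
      fit <- eval(substitute(
        survival::coxph(f, data = data, cluster = CL, ties = ties,
                        control = ctl, x = TRUE, model = TRUE),
        list(CL = as.name(cluster))))
    } else {
      fit <- survival::coxph(f, data = data, ties = ties, control = ctl,
                             x = TRUE, model = TRUE)
    }
  }, warning = function(w) {
    if (grepl("infinite|converge|iterations|singular",
              conditionMessage(w))) {
      converged <<- FALSE
      invokeRestart("muffleWarning")
    }
  })
  beta <- stats::coef(fit)
  if (length(beta) && anyNA(beta)) {
    # NA coefficients mean either a singular design (error) or a monotone
    # partial likelihood, e.g. a level with no events (flag, keep fit)
    if (qr(fit$x)$rank < ncol(fit$x))
      stop("collinear terms, coefficients undetermined: ",
           paste(names(beta)[is.na(beta)], collapse = ", "))
    converged <- FALSE
    warning("separation: no finite estimate for ",
            paste(names(beta)[is.na(beta)], collapse = ", "), call. = FALSE)
  }
  p <- length(beta)
  ll <- fit$loglik[length(fit$loglik)]
  robust_cov <- fit$var
  naive_cov <- if (!is.null(fit$naive.var)) fit$naive.var else fit$var
  if (p) {
    dimnames(robust_cov) <- list(names(beta), names(beta))
    dimnames(naive_cov) <- list(names(beta), names(beta))
  }
  out <- list(coefficients = beta,
              robust_cov = robust_cov,
              naive_cov = naive_cov,
              loglik = ll,
              aic = -2 * ll + 2 * p,
              n = fit$n, n_events = fit$nevent,
              terms = terms, converged = converged, fit = fit)
  class(out) <- "cox_fit"
  out
}

#' @export
print.cox_fit <- function(x, ...) {
  cat("<cox_fit>", length(x$terms), "terms,", x$n, "rows,", x$n_events,
      "events, AIC", format(x$aic, digits = 8), "\n")
  if (length(x$coefficients)) print(summary(x))
  invisible(x)
}

#' Summarize a Cox fit as a hazard-ratio table
#'
#' @param object a `cox_fit`.
#' @param conf_level confidence level for the robust Wald interval.
#' @param ... unused.
#' @return data.frame: term, coef, hr, robust_se, hr_lower, hr_upper, z, p.
#' @export
summary.cox_fit <- function(object, conf_level = 0.95, ...) {
  beta <- object$coefficients
  se <- sqrt(diag(object$robust_cov))
  zq <- stats::qnorm(1 - (1 - conf_level) / 2)
  data.frame(term = names(beta), coef = unname(beta),
             hr = exp(unname(beta)), robust_se = unname(se),
             hr_lower = exp(unname(beta) - zq * se),
             hr_upper = exp(unname(beta) + zq * se),
             z = unname(beta / se),
             p = 2 * stats::pnorm(-abs(unname(beta / se))),
             row.names = NULL)
}

# AIC of a candidate model during stepwise search; NA when the fit fails.
step_aic_of <- function(data, terms, ties) {
  tryCatch(suppressWarnings(fit_cox(data, terms, cluster = NULL,
                                    ties = ties))$aic,
           error = function(e) {
             warning("stepwise candidate fit failed (", e$message,
                     "); move skipped", call. = FALSE)
             NA_real_
           })
}

#' Bidirectional stepwise selection by AIC
#'
#' Starting from the full candidate model (or the null model with
#' `start = "null"`), repeatedly applies the single add-or-drop move that
#' most decreases the partial-likelihood AIC, until no move decreases it.
#' Ties are broken by candidate order, so the result is deterministic given
#' the dataset and candidate ordering. Moves whose sub-fit fails are skipped
#' with a warning.
#'
#' @param data data.frame with `time_days`, `event` and candidate columns.
#' @param candidates character vector of candidate predictor names.
#' @param direction `"both"`, `"backward"` or `"forward"`.
#' @param start starting model, `"full"` or `"null"`.
#' @param protect terms never considered for removal.
#' @param ties tie-handling method for the Cox fits.
#' @param trace if TRUE, prints each accepted move.
#' @return character vector of selected terms, in candidate order.
#' @export
stepwise_aic <- function(data, candidates, direction = c("both", "backward",
                                                         "forward"),
                         start = c("full", "null"), protect = character(),
                         ties = "efron", trace = FALSE) {
  direction <- match.arg(direction)
  start <- match.arg(start)
  if (length(candidates) == 0) stop("candidates must be non-empty")
  current <- if (start == "full") candidates else
    intersect(candidates, protect)
  cur_aic <- step_aic_of(data, current, ties)
  if (is.na(cur_aic)) stop("starting model failed to fit")
  repeat {
    moves <- list()
    if (direction %in% c("both", "backward"))
      for (tm in setdiff(current, protect))
        moves[[length(moves) + 1]] <- list(op = "drop", term = tm,
                                           terms = setdiff(current, tm))
    if (direction %in% c("both", "forward"))
      for (tm in setdiff(candidates, current))
        moves[[length(moves) + 1]] <- list(op = "add", term = tm,
                                           terms = intersect(candidates,
                                                             c(current, tm)))
    if (length(moves) == 0) break
    best <- NULL
    best_aic <- cur_aic
    for (mv in moves) {
      a <- step_aic_of(data, mv$terms, ties)
      if (!is.na(a) && a < best_aic) {
        best <- mv
        best_aic <- a
      }
    }
    if (is.null(best)) break
    if (trace)
      cat(sprintf("%s %s: AIC %.3f -> %.3f\n", best$op, best$term,
                  cur_aic, best_aic))
    current <- best$terms
    cur_aic <- best_aic
  }
  intersect(candidates, current)
}

#' Absolute risk at a horizon from a Cox fit
#'
#' Predicted probability of the event by `horizon_days`, using the Breslow
#' baseline cumulative hazard from the training data:
#' `1 - exp(-H0(h) * exp(lp))`, with the linear predictor centred on the
#' training covariate means (so a row at the training mean gets the baseline
#' risk `1 - S0(h)`).
#'
#' @param fit a `cox_fit`.
#' @param newdata data.frame of rows to score (all term columns present).
#' @param horizon_days prediction horizon in days (default 730); must not
#'   exceed the last observed follow-up time in the training data.
#' @return numeric vector of absolute risks in `[0, 1]`.
#' @export
predict_risk <- function(fit, newdata, horizon_days = 730) {
  stopifnot(inherits(fit, "cox_fit"))
  bh <- survival::basehaz(fit$fit, centered = TRUE)
  if (horizon_days > max(bh$time))
    stop("horizon beyond observed follow-up (max ", max(bh$time), " days)")
  H0 <- bh$hazard[max(which(bh$time <= horizon_days))]
  lp <- if (length(fit$coefficients) == 0) rep(0, nrow(newdata)) else
    unname(stats::predict(fit$fit, newdata = newdata, type = "lp"))
  1 - exp(-H0 * exp(lp))
}
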
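#' Harrell's concordance index
#'
#' A pair of observations is comparable when the strictly shorter follow-up
#' time ends in an event (pairs with tied times are not comparable). A
#' comparable pair scores 1 when the shorter-time member has the higher risk
#' score, 0.5 when the scores are tied, and 0 otherwise; the C-index is the
#' average over comparable pairs. 0.5 is chance-level discrimination.
#'
#' @param scores numeric risk scores (higher = higher predicted risk).
#' @param time_days follow-up times.
#' @param events event indicators in `{0, 1}`.
#' @return C-index in `[0, 1]`.
#' @export
harrells_c <- function(scores, time_days, events) {
  n <- length(scores)
  if (length(time_days) != n || length(events) != n)
    stop("scores, time_days and events must have equal length")
  if (!all(events %in% c(0, 1))) stop("events must be 0/1")
  ev <- which(events == 1)
  concordant <- 0
  comparable <- 0
  for (i in ev) {
    longer <- time_days > time_days[i]
    comparable <- comparable + sum(longer)
    concordant <- concordant + sum(longer & scores[i] > scores) +
      0.5 * sum(longer & scores[i] == scores)
  }
  if (comparable == 0) stop("no comparable pairs")
  concordant / comparable
}
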
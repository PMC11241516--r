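#' Classify treatment response from time to progression
#'
#' Responders have TTP strictly greater than 24 months, non-responders
#' strictly less than 4 months, and everything in between (4-24 months
#' inclusive) is an intermediate response.
#'
#' @param ttp_months non-negative time(s) to progression, in months.
#' @return character vector in `{"responder", "intermediate", "non_responder"}`.
#' @export
classify_response <- function(ttp_months) {
  if (any(!is.finite(ttp_months) | ttp_months < 0)) {
    stop("TTP must be non-negative and finite", call. = FALSE)
  }
  ifelse(ttp_months > 24, "responder",
         ifelse(ttp_months < 4, "non_responder", "intermediate"))
}

#' Pearson chi-square test of independence
#'
#' `chi2 = sum (O - E)^2 / E` with expected counts from the marginal products
#' and `df = (r - 1)(c - 1)`. A warning is emitted when any expected count is
#' below 5 (the approximation is then questionable). Yates continuity
#' correction is available for 2x2 tables.
#'
#' @param table matrix of non-negative integer counts, at least 2x2, with
#'   positive row and column marginals.
#' @param yates apply the continuity correction (2x2 only).
#' @return list with `chi2`, `df`, `p`, `expected` and `small_expected` flag.
#' @export
chi_square <- function(table, yates = FALSE) {
  table <- as.matrix(table)
  if (any(table < 0) || any(table != floor(table))) {
    stop("counts must be non-negative integers", call. = FALSE)
  }
  if (nrow(table) < 2L || ncol(table) < 2L) {
    stop("table must be at least 2x2", call. = FALSE)
  }
  if (any(rowSums(table) == 0) || any(colSums(table) == 0)) {
    stop("zero row or column marginal", call. = FALSE)
  }
  if (yates && !(nrow(table) == 2L && ncol(table) == 2L)) {
    stop("Yates correction applies to 2x2 tables only", call. = FALSE)
  }
  expected <- outer(rowSums(table), colSums(table)) / sum(table)
  small <- any(expected < 5)
  if (small) warning("expected count(s) below 5; chi-square approximation may be poor")
  res <- suppressWarnings(stats::chisq.test(table, correct = yates))
  list(chi2 = unname(res$statistic), df = unname(res$parameter),
       p = unname(res$p.value), expected = expected, small_expected = small)
}

#' Positivity rate as a printed percentage
#'
#' `100 * positive / total`, rounded half-up to the requested number of
#' decimals (the convention used in clinical reporting, where 55.63% prints
#' as 56%).
#'
#' @param positive count of positive cases.
#' @param total total cases (>= 1).
#' @param decimals decimal places (default 0).
#' @return percentage.
#' @export
positivity_rate <- function(positive, total, decimals = 0) {
  stop_if_not_count(positive, "positive")
  stop_if_not_count(total, "total", min = 1)
  if (positive > total) stop("'positive' cannot exceed 'total'", call. = FALSE)
  round_half_up(100 * positive / total, decimals)
}
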
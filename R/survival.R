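#' Kaplan-Meier estimate
#'
#' Product-limit estimator of the survival function, with the median defined
#' as the smallest event time at which `S(t) <= 0.5` (undefined — `NA` — when
#' the curve never reaches 0.5). Records censored at an event time are counted
#' at risk for that time.
#'
#' @param time positive times (months).
#' @param event event indicator (1 = death from disease, 0 = censored).
#' @return a `km_estimate`: list with `time`, `n_risk`, `n_event`, `surv`
#'   (all at the distinct observed times), `median` and `n`.
#' @export
km_estimate <- function(time, event) {
  if (length(time) == 0L) stop("at least one record required", call. = FALSE)
  if (any(!is.finite(time) | time <= 0)) {
    stop("times must be finite and positive", call. = FALSE)
  }
  if (!all(event %in% c(0, 1))) stop("event must be 0/1", call. = FALSE)
  fit <- survival::survfit(survival::Surv(time, event) ~ 1)
  s <- fit$surv
  ev <- fit$n.event
  med_idx <- which(ev > 0 & s <= 0.5 + 1e-12)
  structure(
    list(time = fit$time, n_risk = fit$n.risk, n_event = ev, surv = s,
         median = if (length(med_idx)) fit$time[min(med_idx)] else NA_real_,
         n = length(time)),
    class = "km_estimate"
  )
}

#' @export
print.km_estimate <- function(x, ...) {
  cat(sprintf("km_estimate: n = %d, events = %d, median = %s\n",
              x$n, sum(x$n_event),
              if (is.na(x$median)) "not reached" else format(x$median)))
  invisible(x)
}

#' Log-rank test
#'
#' Standard two-group log-rank chi-square (1 df) with upper-tail p-value.
#'
#' @param time,event survival records pooled over both groups.
#' @param group two-level group label per record.
#' @return list with `chi2`, `df`, `p` and per-group `medians`.
#' @export
logrank_test <- function(time, event, group) {
  group <- as.character(group)
  if (length(unique(group)) != 2L) {
    stop("exactly two non-empty groups required", call. = FALSE)
  }
  if (sum(event) == 0) {
    stop("log-rank statistic undefined with zero events", call. = FALSE)
  }
  sd <- survival::survdiff(survival::Surv(time, event) ~ group)
  chi2 <- unname(sd$chisq)
  medians <- vapply(split(seq_along(time), group), function(i) {
    km_estimate(time[i], event[i])$median
  }, 0)
  list(chi2 = chi2, df = 1L, p = stats::pchisq(chi2, 1, lower.tail = FALSE),
       medians = medians)
}

#' Dichotomize a continuous marker for survival comparison
#'
#' `"median"` splits at the sample median with ties going to the low group
#' (`value > median` is high). `"optimal_logrank"` scans every distinct cut
#' point that leaves at least `min_frac` of the samples in each arm and picks
#' the cut with the smallest log-rank p-value; that p-value is
#' selection-biased (minimum over candidate cuts) and is reported with a
#' warning attribute, not as an honest test.
#'
#' @param values numeric marker values, one per sample (>= 4 samples,
#'   non-constant).
#' @param method `"median"` or `"optimal_logrank"`.
#' @param time,event survival records, required for the optimal method.
#' @param min_frac minimum fraction of samples per arm for candidate cuts.
#' @return factor with levels `low`/`high`; attributes `cutpoint` and (for the
#'   optimal method) `p_selected` plus a `selection_bias` note.
#' @export
dichotomize <- function(values, method = c("median", "optimal_logrank"),
                        time = NULL, event = NULL, min_frac = 0.10) {
  method <- match.arg(method)
  if (length(values) < 4L) stop("at least 4 samples required", call. = FALSE)
  if (length(unique(values)) < 2L) {
    stop("constant marker cannot be dichotomized", call. = FALSE)
  }
  if (method == "median") {
    cut <- stats::median(values)
    lab <- factor(ifelse(values > cut, "high", "low"), levels = c("low", "high"))
    attr(lab, "cutpoint") <- cut
    return(lab)
  }
  if (is.null(time) || is.null(event)) {
    stop("'time' and 'event' are required for optimal_logrank", call. = FALSE)
  }
  n <- length(values)
  min_arm <- max(1L, ceiling(min_frac * n))
  cand <- sort(unique(values))
  cand <- cand[vapply(cand, function(c) {
    sum(values > c) >= min_arm && sum(values <= c) >= min_arm
  }, TRUE)]
  if (length(cand) == 0L) stop("no admissible cut points", call. = FALSE)
  ps <- vapply(cand, function(c) {
    logrank_test(time, event, ifelse(values > c, "high", "low"))$p
  }, 0)
  best <- cand[which.min(ps)]
  lab <- factor(ifelse(values > best, "high", "low"), levels = c("low", "high"))
  attr(lab, "cutpoint") <- best
  attr(lab, "p_selected") <- min(ps)
  attr(lab, "selection_bias") <-
    "p_selected is the minimum over scanned cuts and is not an honest p-value"
  lab
}

#' Write a KM curve table as TSV
#'
#' @param km a [km_estimate()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_km_table <- function(km, path) {
  write_tsv(data.frame(time = km$time, n_risk = km$n_risk,
                       n_event = km$n_event, surv = km$surv), path)
}
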
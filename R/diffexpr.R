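#' Welch two-sample t-test p-value
#'
#' Two-sided p-value from Welch's unequal-variance t-test with Satterthwaite
#' degrees of freedom (equivalent to a two-group one-way ANOVA up to variance
#' pooling; set `pooled = TRUE` for the pooled-variance/ANOVA-identical
#' variant).
#'
#' @param group_a,group_b numeric vectors, each with at least 2 finite values.
#' @param pooled use the pooled-variance (classic two-sample) statistic.
#' @return list with `statistic` (t, oriented `mean(b) - mean(a)`) and `p`.
#' @export
welch_t_pvalue <- function(group_a, group_b, pooled = FALSE) {
  group_a <- group_a[is.finite(group_a)]
  group_b <- group_b[is.finite(group_b)]
  if (length(group_a) < 2 || length(group_b) < 2) {
    stop("each group needs at least 2 finite values", call. = FALSE)
  }
  va <- stats::var(group_a)
  vb <- stats::var(group_b)
  if (va == 0 && vb == 0) {
    # degenerate: no within-group variability
    if (mean(group_a) == mean(group_b)) return(list(statistic = 0, p = 1))
    return(list(statistic = sign(mean(group_b) - mean(group_a)) * Inf, p = 0))
  }
  tt <- stats::t.test(group_b, group_a, var.equal = pooled)
  list(statistic = unname(tt$statistic), p = unname(tt$p.value))
}

#' Two-group differential expression with fold-change and p-value gates
#'
#' Tests every feature of an [expression_matrix()] for a difference between
#' non-responders and responders. A feature passes when both gates hold
#' strictly: `|linear_fc| > fc_threshold` and `p < p_threshold`. The sign
#' convention is NR minus R, so `log2fc > 0` means higher in non-responders.
#' `linear_fc` is the signed fold change
#' (`2^log2fc` if `log2fc >= 0`, else `-2^(-log2fc)`), so the fold-change
#' gate applies symmetrically to up- and down-regulation.
#'
#' Missing values are allowed: a feature is tested on its non-missing samples
#' and flagged untestable (never passing) if either group drops below 2
#' observations.
#'
#' @param matrix an [expression_matrix()].
#' @param fc_threshold linear fold-change gate (default 1.5).
#' @param p_threshold p-value gate (default 0.05).
#' @param pooled use the pooled-variance t statistic (see [welch_t_pvalue()]).
#' @param adjust `"none"` (raw p, the default) or `"BH"`; with `"BH"` the
#'   p gate is applied to Benjamini-Hochberg adjusted values and a note is
#'   emitted, since the raw-p rule is the conventional reporting default here.
#' @return data frame with one row per feature: `feature_id`, `mean_R`,
#'   `mean_NR`, `log2fc`, `linear_fc`, `p_value` (and `p_adjusted` when
#'   `adjust = "BH"`), `direction` (`up`/`down`/`none`), `passes`, `testable`.
#' @export
differential_expression <- function(matrix, fc_threshold = 1.5,
                                    p_threshold = 0.05, pooled = FALSE,
                                    adjust = c("none", "BH")) {
  stopifnot(inherits(matrix, "expression_matrix"))
  adjust <- match.arg(adjust)
  if (fc_threshold < 1) stop("'fc_threshold' must be >= 1", call. = FALSE)
  idx_r <- matrix$labels == "R"
  idx_nr <- matrix$labels == "NR"

  res <- lapply(seq_len(nrow(matrix$values)), function(i) {
    x <- matrix$values[i, ]
    xr <- x[idx_r][is.finite(x[idx_r])]
    xnr <- x[idx_nr][is.finite(x[idx_nr])]
    testable <- length(xr) >= 2 && length(xnr) >= 2
    mean_r <- if (length(xr)) mean(xr) else NA_real_
    mean_nr <- if (length(xnr)) mean(xnr) else NA_real_
    p <- if (testable) welch_t_pvalue(xr, xnr, pooled = pooled)$p else NA_real_
    c(mean_r = mean_r, mean_nr = mean_nr, p = p, testable = testable)
  })
  res <- do.call(rbind, res)

  log2fc <- res[, "mean_nr"] - res[, "mean_r"]
  linear_fc <- ifelse(log2fc >= 0, 2^log2fc, -2^(-log2fc))
  p_value <- res[, "p"]
  p_gate <- p_value
  out <- data.frame(
    feature_id = matrix$feature_ids,
    mean_R = res[, "mean_r"], mean_NR = res[, "mean_nr"],
    log2fc = log2fc, linear_fc = linear_fc, p_value = p_value,
    stringsAsFactors = FALSE
  )
  if (adjust == "BH") {
    message("applying Benjamini-Hochberg adjustment before the p gate")
    out$p_adjusted <- bh_correction(p_value[!is.na(p_value)])[
      match(seq_along(p_value), which(!is.na(p_value)))]
    p_gate <- out$p_adjusted
  }
  testable <- as.logical(res[, "testable"])
  passes <- testable & abs(linear_fc) > fc_threshold &
    !is.na(p_gate) & p_gate < p_threshold
  out$direction <- ifelse(passes & log2fc > 0, "up",
                          ifelse(passes & log2fc < 0, "down", "none"))
  out$passes <- passes
  out$testable <- testable
  out
}

#' Write a differential-expression table as TSV
#'
#' @param de a [differential_expression()] result.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_de_table <- function(de, path) write_tsv(de, path)
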
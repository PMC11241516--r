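#' Read a long-format Ct table
#'
#' Expects columns `sample`, `group` (`R`/`NR`), `target`, `replicate`, `ct`.
#'
#' @param path TSV path.
#' @return data frame.
#' @export
read_ct_table <- function(path) {
  df <- read_tsv(path)
  need <- c("sample", "group", "target", "replicate", "ct")
  if (!all(need %in% names(df))) {
    stop("Ct table must have columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  df
}

#' Collapse qPCR replicates with a reliability cut-off
#'
#' Replicates with Ct above `max_ct` cycles are removed as unreliable before
#' averaging; a sample x target whose replicates are all removed is flagged
#' missing (and excluded downstream, with a log message). With
#' `sample_level = TRUE` the stricter reading is applied: any failing
#' replicate discards the whole sample x target measurement.
#'
#' @param table long Ct data frame (see [read_ct_table()]).
#' @param max_ct reliability cut-off in cycles (default 35; the filter is
#'   strict, `ct > max_ct` is removed).
#' @param sample_level apply the cut-off at the sample x target level.
#' @return data frame `sample`, `group`, `target`, `mean_ct` (NA when
#'   missing), `n_replicates_used`.
#' @export
collapse_replicates <- function(table, max_ct = 35, sample_level = FALSE) {
  stopifnot(all(c("sample", "group", "target", "ct") %in% names(table)))
  if (any(!is.finite(table$ct) | table$ct <= 0)) {
    stop("Ct values must be finite and positive", call. = FALSE)
  }
  key <- interaction(table$sample, table$target, drop = TRUE)
  rows <- lapply(split(table, key), function(d) {
    ok <- d$ct <= max_ct
    if (sample_level && any(!ok)) ok[] <- FALSE
    data.frame(sample = d$sample[1], group = d$group[1], target = d$target[1],
               mean_ct = if (any(ok)) mean(d$ct[ok]) else NA_real_,
               n_replicates_used = sum(ok), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  n_missing <- sum(is.na(out$mean_ct))
  if (n_missing > 0) {
    message(n_missing, " sample x target measurement(s) dropped: no replicate",
            " with Ct <= ", max_ct)
  }
  out[order(out$sample, out$target), ]
}

#' Delta-delta-Ct relative quantification
#'
#' Per sample: `delta_ct = mean_ct(target) - mean_ct(reference)`; then
#' `delta_delta_ct = delta_ct - mean(delta_ct of the calibrator group)` per
#' target, and `fold = 2^(-delta_delta_ct)` (amplification efficiency fixed
#' at 2). The calibrator defaults to the responder group, so folds read as
#' NR-relative-to-R. Samples missing the reference gene are excluded with a
#' warning.
#'
#' @param mean_cts a [collapse_replicates()] result.
#' @param reference_gene reference assay id.
#' @param calibrator_group group whose mean delta-Ct anchors the comparison.
#' @return data frame `sample`, `group`, `target`, `mean_ct`, `delta_ct`,
#'   `delta_delta_ct`, `fold` (one row per retained sample x non-reference
#'   target).
#' @export
delta_delta_ct <- function(mean_cts, reference_gene,
                           calibrator_group = "R") {
  stopifnot(all(c("sample", "group", "target", "mean_ct") %in% names(mean_cts)))
  ref <- mean_cts[mean_cts$target == reference_gene & !is.na(mean_cts$mean_ct), ]
  if (nrow(ref) == 0L) stop("reference gene not found in Ct table", call. = FALSE)
  ref_ct <- stats::setNames(ref$mean_ct, ref$sample)

  d <- mean_cts[mean_cts$target != reference_gene, , drop = FALSE]
  no_ref <- !(d$sample %in% names(ref_ct))
  if (any(no_ref)) {
    warning(length(unique(d$sample[no_ref])),
            " sample(s) excluded: missing reference gene measurement")
    d <- d[!no_ref, , drop = FALSE]
  }
  d <- d[!is.na(d$mean_ct), , drop = FALSE]
  d$delta_ct <- d$mean_ct - ref_ct[d$sample]

  out <- lapply(split(d, d$target), function(t) {
    cal <- t$delta_ct[t$group == calibrator_group]
    if (length(cal) == 0L) {
      stop("no calibrator-group measurements for target ", t$target[1],
           call. = FALSE)
    }
    t$delta_delta_ct <- t$delta_ct - mean(cal)
    t$fold <- 2^(-t$delta_delta_ct)
    t
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out[order(out$target, out$sample),
      c("sample", "group", "target", "mean_ct", "delta_ct", "delta_delta_ct",
        "fold")]
}

#' Full Ct-to-fold relative quantification
#'
#' Convenience chain: [collapse_replicates()] then [delta_delta_ct()].
#'
#' @inheritParams collapse_replicates
#' @inheritParams delta_delta_ct
#' @return see [delta_delta_ct()].
#' @export
relative_quantification <- function(table, reference_gene,
                                    calibrator_group = "R", max_ct = 35,
                                    sample_level = FALSE) {
  delta_delta_ct(collapse_replicates(table, max_ct, sample_level),
                 reference_gene, calibrator_group)
}

#' Mann-Whitney U test
#'
#' Two-sided rank-sum comparison. The exact null distribution is used when
#' the smaller group has at most 8 observations and there are no ties;
#' otherwise the normal approximation with tie and continuity correction is
#' used. `U` is the number of (a, b) pairs with `a > b` (ties counted 1/2).
#'
#' @param a,b numeric vectors, both non-empty.
#' @return list with `U`, `p` and `exact` (logical).
#' @export
mann_whitney_u <- function(a, b) {
  if (length(a) == 0L || length(b) == 0L) {
    stop("both groups must be non-empty", call. = FALSE)
  }
  ties <- anyDuplicated(c(a, b)) > 0L
  exact <- !ties && min(length(a), length(b)) <= 8
  wt <- suppressWarnings(
    stats::wilcox.test(a, b, exact = exact, correct = TRUE)
  )
  list(U = unname(wt$statistic), p = unname(wt$p.value), exact = exact)
}

#' Per-target group comparison of relative expression
#'
#' Median fold per group and the Mann-Whitney comparison of the per-sample
#' fold values between non-responders and responders, per target.
#'
#' @param relexp a [delta_delta_ct()] result.
#' @return data frame `target`, `median_fold_R`, `median_fold_NR`, `U`, `p`.
#' @export
qpcr_group_report <- function(relexp) {
  rows <- lapply(split(relexp, relexp$target), function(t) {
    fr <- t$fold[t$group == "R"]
    fnr <- t$fold[t$group == "NR"]
    mw <- mann_whitney_u(fnr, fr)
    data.frame(target = t$target[1],
               median_fold_R = stats::median(fr),
               median_fold_NR = stats::median(fnr),
               U = mw$U, p = mw$p, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
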
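#' Logistic marker-panel fit
#'
#' Maximum-likelihood logistic regression of the binary response (NR = 1,
#' R = 0) on a subset of markers, via `stats::glm`. When complete or
#' quasi-complete separation (or non-convergence) is detected — likely in
#' small cohorts — the model is refit with a small ridge penalty on the
#' non-intercept coefficients, escalating tenfold until the penalized IRLS
#' converges; the `converged` flag reports whether the plain ML fit succeeded.
#'
#' @param markers data frame of marker values, one row per sample (columns are
#'   marker ids). By convention expression markers are supplied as -delta-Ct
#'   (higher = more expressed).
#' @param labels `"R"`/`"NR"` per sample.
#' @param marker_subset columns to use (default all).
#' @param ridge_start initial ridge penalty used on the fallback path.
#' @return a `panel_model`: list with `markers` (ids), `coefficients`
#'   (intercept first; `NA` for aliased columns), `scores` (per-sample linear
#'   predictor), `fitted` (probabilities), `converged`, `ridge_penalty`,
#'   `labels`.
#' @export
fit_logistic <- function(markers, labels, marker_subset = colnames(markers),
                         ridge_start = 1e-4) {
  stopifnot(is.data.frame(markers))
  labels <- as.character(labels)
  if (!all(labels %in% c("R", "NR")) || length(unique(labels)) < 2L) {
    stop("labels must contain both R and NR", call. = FALSE)
  }
  if (sum(labels == "R") < 2L || sum(labels == "NR") < 2L) {
    stop("at least 2 samples per class required", call. = FALSE)
  }
  missing_m <- setdiff(marker_subset, colnames(markers))
  if (length(missing_m)) {
    stop("unknown marker id(s): ", paste(missing_m, collapse = ", "),
         call. = FALSE)
  }
  y <- as.integer(labels == "NR")
  X <- as.matrix(markers[, marker_subset, drop = FALSE])

  sep_warn <- FALSE
  fit <- withCallingHandlers(
    stats::glm.fit(cbind(`(Intercept)` = 1, X), y,
                   family = stats::binomial()),
    warning = function(w) {
      if (grepl("0 or 1|did not converge", conditionMessage(w))) {
        sep_warn <<- TRUE
        invokeRestart("muffleWarning")
      }
    }
  )
  plain_ok <- fit$converged && !sep_warn &&
    all(is.na(fit$coefficients) | abs(fit$coefficients) < 1e3)

  ridge <- 0
  coefs <- fit$coefficients
  if (!plain_ok) {
    ridge <- ridge_start
    repeat {
      r <- ridge_logistic_irls(X, y, ridge)
      if (r$converged || ridge >= 1e2) {
        coefs <- r$beta
        break
      }
      ridge <- ridge * 10
    }
  }
  beta <- ifelse(is.na(coefs), 0, coefs)
  scores <- drop(cbind(1, X) %*% beta)
  structure(
    list(markers = marker_subset, coefficients = coefs, scores = scores,
         fitted = stats::plogis(scores), converged = plain_ok,
         ridge_penalty = ridge, labels = labels),
    class = "panel_model"
  )
}

# IRLS with an L2 penalty on non-intercept coefficients
ridge_logistic_irls <- function(X, y, lambda, max_iter = 100, tol = 1e-9) {
  Xd <- cbind(1, X)
  p <- ncol(Xd)
  D <- diag(c(0, rep(lambda, p - 1)), p)
  beta <- rep(0, p)
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    eta <- drop(Xd %*% beta)
    mu <- stats::plogis(eta)
    w <- pmax(mu * (1 - mu), 1e-10)
    z <- eta + (y - mu) / w
    new_beta <- tryCatch(
      solve(crossprod(Xd, w * Xd) + D, crossprod(Xd, w * z)),
      error = function(e) NULL
    )
    if (is.null(new_beta)) break
    new_beta <- drop(new_beta)
    if (max(abs(new_beta - beta)) < tol) {
      beta <- new_beta
      converged <- TRUE
      break
    }
    beta <- new_beta
  }
  names(beta) <- c("(Intercept)", colnames(X))
  list(beta = beta, converged = converged)
}

#' @export
print.panel_model <- function(x, ...) {
  cat(sprintf("panel_model: %s | ML converged: %s%s\n",
              paste(x$markers, collapse = " + "), x$converged,
              if (x$ridge_penalty > 0) {
                sprintf(" (ridge %.0e)", x$ridge_penalty)
              } else ""))
  invisible(x)
}

#' ROC curve and AUC by the midrank (Mann-Whitney) formula
#'
#' `AUC = U / (n1 * n0)`: the probability that a random positive (NR) sample
#' scores above a random negative (R) sample, ties counted 1/2 — computed
#' from midranks, hence invariant to strictly monotone score transforms. The
#' curve is evaluated at every distinct threshold (predict NR when
#' `score >= threshold`).
#'
#' @param scores numeric per-sample scores, oriented NR-positive.
#' @param labels `"R"`/`"NR"` per sample (or a logical/0-1 vector with
#'   `TRUE`/1 = positive).
#' @param positive label treated as positive when `labels` is character.
#' @return a `roc_curve`: list with `thresholds`, `sensitivity`,
#'   `specificity`, `auc`, `n_positive`, `n_negative`.
#' @export
roc_auc <- function(scores, labels, positive = "NR") {
  pos <- if (is.character(labels) || is.factor(labels)) {
    as.character(labels) == positive
  } else {
    as.logical(labels)
  }
  n1 <- sum(pos)
  n0 <- sum(!pos)
  if (n1 == 0L || n0 == 0L) stop("both classes required", call. = FALSE)
  if (length(scores) != length(pos)) stop("length mismatch", call. = FALSE)
  r <- rank(scores) # midranks
  auc <- (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)

  th <- c(-Inf, sort(unique(scores)), Inf)
  sens <- vapply(th, function(t) sum(pos & scores >= t) / n1, 0)
  spec <- vapply(th, function(t) sum(!pos & scores < t) / n0, 0)
  structure(list(thresholds = th, sensitivity = sens, specificity = spec,
                 auc = auc, n_positive = n1, n_negative = n0),
            class = "roc_curve")
}

#' @export
print.roc_curve <- function(x, ...) {
  cat(sprintf("roc_curve: AUC = %.3f (%d positive vs %d negative)\n",
              x$auc, x$n_positive, x$n_negative))
  invisible(x)
}

#' Evaluate marker panels by in-sample AUC
#'
#' Single-marker panels are scored by the raw marker value (AUC is invariant
#' to the monotone logistic transform); multi-marker panels by the linear
#' score of a [fit_logistic()] fit. AUCs are in-sample, matching the
#' conventional reporting of small-cohort panel analyses; use
#' `loocv = TRUE` for leave-one-out cross-validated scores.
#'
#' @param markers data frame of marker values (samples x markers).
#' @param labels `"R"`/`"NR"` per sample.
#' @param panels list of character vectors of marker ids.
#' @param loocv score each sample from a model fit without it.
#' @return data frame sorted by decreasing AUC: `panel`, `n_markers`, `auc`,
#'   `converged`, `ridge_penalty`; fitted models in `attr(, "models")`.
#' @export
evaluate_panels <- function(markers, labels, panels, loocv = FALSE) {
  if (length(panels) == 0L) stop("no panels supplied", call. = FALSE)
  unknown <- setdiff(unlist(panels), colnames(markers))
  if (length(unknown)) {
    stop("unknown marker id(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  models <- vector("list", length(panels))
  rows <- lapply(seq_along(panels), function(i) {
    p <- panels[[i]]
    if (length(p) == 1L && !loocv) {
      scores <- markers[[p]]
      conv <- NA
      ridge <- NA_real_
    } else if (!loocv) {
      m <- fit_logistic(markers, labels, p)
      models[[i]] <<- m
      scores <- m$scores
      conv <- m$converged
      ridge <- m$ridge_penalty
    } else {
      scores <- vapply(seq_along(labels), function(j) {
        m <- fit_logistic(markers[-j, , drop = FALSE], labels[-j], p)
        beta <- ifelse(is.na(m$coefficients), 0, m$coefficients)
        drop(c(1, as.numeric(markers[j, p])) %*% beta)
      }, 0)
      conv <- NA
      ridge <- NA_real_
    }
    data.frame(panel = paste(p, collapse = " + "),
               n_markers = length(p),
               auc = roc_auc(scores, labels)$auc,
               converged = conv, ridge_penalty = ridge,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  ord <- order(-out$auc, out$n_markers, out$panel)
  out <- out[ord, ]
  rownames(out) <- NULL
  attr(out, "models") <- models[ord]
  out
}

#' Build a marker matrix from relative expression
#'
#' Converts a [delta_delta_ct()] table into a samples x markers data frame of
#' -delta-Ct values (higher = more expressed) with an aligned label vector,
#' ready for [fit_logistic()] / [evaluate_panels()].
#'
#' @param relexp a [delta_delta_ct()] result.
#' @return list with `markers` (data frame) and `labels`.
#' @export
marker_matrix_from_relexp <- function(relexp) {
  samples <- sort(unique(relexp$sample))
  targets <- sort(unique(relexp$target))
  m <- matrix(NA_real_, length(samples), length(targets),
              dimnames = list(samples, targets))
  m[cbind(match(relexp$sample, samples), match(relexp$target, targets))] <-
    -relexp$delta_ct
  labels <- relexp$group[match(samples, relexp$sample)]
  list(markers = as.data.frame(m), labels = labels)
}
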
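#' Round half away from zero
#'
#' Decimal rounding with ties going away from zero, the convention used by
#' most clinical statistics packages. Base [round()] rounds half to even,
#' which does not reproduce conventionally printed percentages
#' (e.g. 55.5 -> 56, not 55.4... -> 55).
#'
#' @param x numeric vector.
#' @param digits number of decimal places.
#' @return rounded numeric vector.
#' @keywords internal
round_half_up <- function(x, digits = 0) {
  f <- 10^digits
  # small absolute nudge guards against values sitting a ulp below .5
  sign(x) * floor(abs(x) * f + 0.5 + sqrt(.Machine$double.eps)) / f
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_if_not_count <- function(x, name, min = 0) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < min || x != floor(x)) {
    stop(sprintf("'%s' must be a single integer >= %d", name, min), call. = FALSE)
  }
  invisible(as.integer(x))
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

read_tsv <- function(path, ...) {
  utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE, ...)
}
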
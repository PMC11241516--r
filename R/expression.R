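#' Expression matrix with response labels
#'
#' A light container for a log2 feature-by-sample expression table together
#' with a two-class response label per sample: `"R"` (responder) or `"NR"`
#' (non-responder). This is the substrate of the differential-expression
#' stage.
#'
#' @param values numeric matrix, features in rows, samples in columns.
#'   Row names are feature ids, column names are sample ids.
#' @param labels character or factor of `"R"`/`"NR"`, one per column of
#'   `values` (named vectors are matched to column names).
#' @return an object of class `expression_matrix`: a list with elements
#'   `values`, `labels`, `feature_ids`, `sample_ids`.
#' @examples
#' m <- matrix(rnorm(20), nrow = 4,
#'             dimnames = list(paste0("g", 1:4), paste0("s", 1:5)))
#' em <- expression_matrix(m, c("R", "R", "NR", "NR", "NR"))
#' @export
expression_matrix <- function(values, labels) {
  if (!is.matrix(values) || !is.numeric(values)) {
    stop("'values' must be a numeric matrix", call. = FALSE)
  }
  if (is.null(rownames(values)) || is.null(colnames(values))) {
    stop("'values' must have feature row names and sample column names",
         call. = FALSE)
  }
  if (anyDuplicated(rownames(values))) {
    stop("duplicate feature ids", call. = FALSE)
  }
  if (!is.null(names(labels))) labels <- labels[colnames(values)]
  labels <- as.character(labels)
  if (length(labels) != ncol(values)) {
    stop("one label per sample required", call. = FALSE)
  }
  if (!all(labels %in% c("R", "NR"))) {
    stop("labels must be 'R' or 'NR'", call. = FALSE)
  }
  if (length(unique(labels)) < 2L) {
    stop("both classes (R and NR) must be present", call. = FALSE)
  }
  structure(
    list(values = values, labels = labels,
         feature_ids = rownames(values), sample_ids = colnames(values)),
    class = "expression_matrix"
  )
}

#' @export
print.expression_matrix <- function(x, ...) {
  cat(sprintf("expression_matrix: %d features x %d samples (R = %d, NR = %d)\n",
              nrow(x$values), ncol(x$values),
              sum(x$labels == "R"), sum(x$labels == "NR")))
  invisible(x)
}

#' @export
dim.expression_matrix <- function(x) dim(x$values)

#' Write / read an expression matrix as TSV
#'
#' The matrix is written features-in-rows with a `feature_id` first column and
#' sample ids as the remaining header fields. Labels travel in a separate
#' two-column sample table (`sample`, `group`) so the matrix file stays a
#' plain numeric table.
#'
#' @param em an [expression_matrix()].
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_expression_tsv <- function(em, path) {
  df <- data.frame(feature_id = em$feature_ids, em$values,
                   check.names = FALSE, stringsAsFactors = FALSE)
  write_tsv(df, path)
}

#' @rdname write_expression_tsv
#' @param labels named `"R"`/`"NR"` vector (names = sample ids), or a path to
#'   a two-column TSV with columns `sample` and `group`.
#' @export
read_expression_tsv <- function(path, labels) {
  df <- read_tsv(path)
  if (colnames(df)[1] != "feature_id") {
    stop("expression TSV must have a 'feature_id' first column", call. = FALSE)
  }
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df$feature_id
  if (is.character(labels) && length(labels) == 1L && file.exists(labels)) {
    s <- read_tsv(labels)
    labels <- stats::setNames(s$group, s$sample)
  }
  expression_matrix(m, labels)
}
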
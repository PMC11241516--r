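#' Normalize miRNA identifiers
#'
#' Trims whitespace and emphasis characters and lowercases, keeping the
#' canonical `hsa-` prefix as written (e.g. `*hsa-miR-223-3p*` ->
#' `hsa-mir-223-3p`).
#'
#' @param x character vector of miRNA names.
#' @return normalized character vector.
#' @export
normalize_mirna <- function(x) {
  tolower(gsub("^[\\s*]+|[\\s*]+$", "", x, perl = TRUE))
}

#' Normalize gene symbols
#'
#' Uppercases, trims, and applies an optional alias map of symbol corrections
#' (old symbol -> corrected symbol).
#'
#' @param x character vector of gene symbols.
#' @param alias_map named character vector, `names()` are symbols as printed
#'   and values the corrected symbols; `NULL` disables aliasing.
#' @return normalized character vector.
#' @export
normalize_symbol <- function(x, alias_map = NULL) {
  x <- toupper(gsub("^[\\s*\\[]+|[\\s*\\]]+$", "", x, perl = TRUE))
  if (!is.null(alias_map) && length(alias_map)) {
    hit <- match(x, toupper(names(alias_map)))
    x[!is.na(hit)] <- toupper(alias_map[hit[!is.na(hit)]])
  }
  x
}

#' Packaged gene-symbol alias map
#'
#' Corrections for typographical symbol variants appearing in the packaged
#' curated interaction fixture (e.g. `CHUCK` -> `CHUK`). Applied by default by
#' [read_interaction_table()]; pass `alias_map = NULL` there to keep symbols
#' exactly as printed.
#'
#' @return named character vector (printed symbol -> corrected symbol).
#' @export
default_alias_map <- function() {
  path <- system.file("extdata", "symbol_aliases.tsv", package = "mirtarnet")
  df <- read_tsv(path)
  stats::setNames(df$corrected, df$printed)
}

#' Construct an interaction set
#'
#' @param records data frame with columns `mirna`, `gene` and optionally
#'   `evidence`; pairs are normalized and deduplicated.
#' @param alias_map symbol alias map applied to `gene` (see
#'   [normalize_symbol()]).
#' @return an `interaction_set`: list with `records` (deduplicated, normalized
#'   data frame) and `alias_map`.
#' @export
interaction_set <- function(records, alias_map = NULL) {
  stopifnot(is.data.frame(records), all(c("mirna", "gene") %in% names(records)))
  records$mirna <- normalize_mirna(records$mirna)
  records$gene <- normalize_symbol(records$gene, alias_map)
  if (any(!nzchar(records$mirna)) || any(!nzchar(records$gene))) {
    stop("empty miRNA or gene identifiers in interaction records", call. = FALSE)
  }
  if (!"evidence" %in% names(records)) {
    records$evidence <- rep(NA_character_, nrow(records))
  }
  records <- records[!duplicated(records[, c("mirna", "gene")]),
                     c("mirna", "gene", "evidence"), drop = FALSE]
  rownames(records) <- NULL
  structure(list(records = records, alias_map = alias_map),
            class = "interaction_set")
}

#' @export
print.interaction_set <- function(x, ...) {
  cat(sprintf("interaction_set: %d validated miRNA-target pairs (%d miRNAs, %d genes)\n",
              nrow(x$records), length(unique(x$records$mirna)),
              length(unique(x$records$gene))))
  invisible(x)
}

#' Read a miRNA-target interaction table
#'
#' Accepts the miRTarBase-like tab-separated dialect (columns `miRNA` and
#' `Target Gene`, any further columns kept as evidence) or a minimal
#' two-column table whose first two columns are miRNA and gene. miRNA names
#' are lowercased, gene symbols uppercased and passed through the alias map,
#' and duplicate pairs dropped.
#'
#' @param source a file path or a character vector of raw TSV lines.
#' @param alias_map symbol corrections applied to target genes; defaults to
#'   the packaged map ([default_alias_map()]). Use `NULL` to keep symbols as
#'   printed.
#' @param evidence_filter optional regular expression; only records whose
#'   evidence tag matches are kept.
#' @return an `interaction_set`.
#' @export
read_interaction_table <- function(source,
                                   alias_map = default_alias_map(),
                                   evidence_filter = NULL) {
  df <- if (length(source) == 1L && file.exists(source)) {
    read_tsv(source)
  } else {
    read_tsv(textConnection(paste(source, collapse = "\n")))
  }
  if (nrow(df) == 0L) {
    warning("empty interaction table")
    return(interaction_set(data.frame(mirna = character(), gene = character(),
                                      stringsAsFactors = FALSE), alias_map))
  }
  nm <- tolower(gsub("[ ._]", "", names(df)))
  mi_names <- c("mirna", "mirnaid", "mir", "mirbaseid")
  ge_names <- c("targetgene", "gene", "genesymbol", "target")
  mi_col <- match(TRUE, nm %in% mi_names)
  ge_col <- match(TRUE, nm %in% ge_names)
  if (is.na(mi_col) || is.na(ge_col)) {
    if (ncol(df) >= 2L && !any(nm %in% c(mi_names, ge_names))) {
      # minimal dialect: first two columns are miRNA and gene
      mi_col <- 1L
      ge_col <- 2L
    } else {
      stop("interaction table must provide miRNA and target-gene columns",
           call. = FALSE)
    }
  }
  ev_col <- match(TRUE, nm %in% c("evidence", "supporttype", "experiments"))
  rec <- data.frame(mirna = as.character(df[[mi_col]]),
                    gene = as.character(df[[ge_col]]),
                    evidence = if (!is.na(ev_col)) as.character(df[[ev_col]])
                               else NA_character_,
                    stringsAsFactors = FALSE)
  if (!is.null(evidence_filter)) {
    rec <- rec[grepl(evidence_filter, rec$evidence %||% ""), , drop = FALSE]
  }
  interaction_set(rec, alias_map)
}

#' Write an interaction set in the miRTarBase-like dialect
#'
#' @param interactions an `interaction_set`.
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_interaction_table <- function(interactions, path) {
  stopifnot(inherits(interactions, "interaction_set"))
  df <- interactions$records
  names(df) <- c("miRNA", "Target Gene", "Evidence")
  write_tsv(df, path)
}
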
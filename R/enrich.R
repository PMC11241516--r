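#' Read a GMT gene-set file
#'
#' Standard tab-separated GMT: term id, description, then member symbols.
#' Lines starting with `#` are skipped.
#'
#' @param path GMT file path.
#' @param background optional gene universe; defaults to the union of all set
#'   members.
#' @return a `gene_set_collection`: list with `sets` (named list of character
#'   vectors), `descriptions` and `background`.
#' @export
read_gmt <- function(path, background = NULL) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- vapply(parts, length, 0L) < 3L
  if (any(bad)) stop("malformed GMT line(s): need term, description, members",
                     call. = FALSE)
  sets <- lapply(parts, function(p) unique(p[-(1:2)]))
  names(sets) <- vapply(parts, `[`, "", 1L)
  desc <- stats::setNames(vapply(parts, `[`, "", 2L), names(sets))
  gene_set_collection(sets, descriptions = desc, background = background)
}

#' @rdname read_gmt
#' @param sets named list of character vectors (term -> member symbols).
#' @param descriptions optional named descriptions.
#' @export
gene_set_collection <- function(sets, descriptions = NULL, background = NULL) {
  if (length(sets) == 0L) stop("empty gene-set collection", call. = FALSE)
  if (any(vapply(sets, length, 0L) == 0L)) {
    stop("gene sets must be non-empty", call. = FALSE)
  }
  if (is.null(names(sets)) || anyDuplicated(names(sets))) {
    stop("sets must have unique names", call. = FALSE)
  }
  background <- unique(background %||% unlist(sets, use.names = FALSE))
  outside <- setdiff(unlist(sets, use.names = FALSE), background)
  if (length(outside)) {
    stop("set members outside the supplied background: ",
         paste(utils::head(outside, 5), collapse = ", "), call. = FALSE)
  }
  structure(list(sets = sets,
                 descriptions = descriptions %||%
                   stats::setNames(rep("", length(sets)), names(sets)),
                 background = background),
            class = "gene_set_collection")
}

#' Hypergeometric gene-set over-representation
#'
#' For each term, the upper-tail hypergeometric probability
#' `P(X >= k)` of drawing at least `k` term members in a query of size `n`
#' from a universe of size `N` containing `K` term members. Query genes
#' outside the background are dropped with a warning. Results are sorted by
#' corrected p-value.
#'
#' @param query character vector of gene symbols.
#' @param collection a [gene_set_collection()].
#' @param adjust multiple-testing correction: Benjamini-Hochberg (default) or
#'   Bonferroni.
#' @return data frame with one row per term: `term`, `description`, `k`
#'   (overlap), `K` (term size), `n` (effective query size), `N` (background
#'   size), `p_hyper`, `p_corrected`, `percent_genes` (100 k/K), plus
#'   list-columns `overlap_genes` and `members`.
#' @export
hypergeometric_enrichment <- function(query, collection,
                                      adjust = c("BH", "bonferroni")) {
  stopifnot(inherits(collection, "gene_set_collection"))
  adjust <- match.arg(adjust)
  query <- unique(query)
  if (length(query) == 0L) stop("empty query", call. = FALSE)
  dropped <- setdiff(query, collection$background)
  if (length(dropped)) {
    warning(length(dropped), " query gene(s) outside the background dropped")
    query <- intersect(query, collection$background)
  }
  if (length(query) == 0L) stop("no query genes in the background", call. = FALSE)

  N <- length(collection$background)
  n <- length(query)
  rows <- lapply(names(collection$sets), function(term) {
    members <- collection$sets[[term]]
    overlap <- sort(intersect(query, members))
    k <- length(overlap)
    K <- length(members)
    p <- if (k == 0L) 1 else stats::phyper(k - 1, K, N - K, n,
                                           lower.tail = FALSE)
    list(term = term, description = unname(collection$descriptions[term]),
         k = k, K = K, n = n, N = N, p_hyper = p,
         percent_genes = percent_genes(k, K),
         overlap_genes = overlap, members = members)
  })
  out <- data.frame(
    term = vapply(rows, `[[`, "", "term"),
    description = vapply(rows, `[[`, "", "description"),
    k = vapply(rows, `[[`, 0L, "k"),
    K = vapply(rows, function(r) length(r$members), 0L),
    n = n, N = N,
    p_hyper = vapply(rows, `[[`, 0, "p_hyper"),
    percent_genes = vapply(rows, `[[`, 0, "percent_genes"),
    stringsAsFactors = FALSE
  )
  out$p_corrected <- if (adjust == "BH") {
    bh_correction(out$p_hyper)
  } else {
    pmin(1, out$p_hyper * nrow(out))
  }
  out$overlap_genes <- lapply(rows, `[[`, "overlap_genes")
  out$members <- lapply(rows, `[[`, "members")
  out <- out[order(out$p_corrected, out$p_hyper, out$term), ]
  rownames(out) <- NULL
  out
}

#' Percentage of a term's genes present in the query
#'
#' `100 * k / K`, rounded half-up to 2 decimals for reporting.
#'
#' @param k overlap count.
#' @param K term size (>= 1).
#' @return percentage in \[0, 100\].
#' @export
percent_genes <- function(k, K) {
  if (any(K < 1)) stop("term size K must be >= 1", call. = FALSE)
  if (any(k < 0 | k > K)) stop("k must lie in [0, K]", call. = FALSE)
  round_half_up(100 * k / K, 2)
}

#' Cohen's kappa between two gene sets over a universe
#'
#' Chance-corrected agreement of the two membership indicators across the
#' universe: `kappa = (p_o - p_e) / (1 - p_e)` on the 2x2 table of
#' (in A) x (in B) counts. When both sets equal the universe (`p_e = 1`),
#' kappa is defined as 1.
#'
#' @param set_a,set_b character vectors, subsets of `universe`.
#' @param universe finite, non-empty gene universe.
#' @return kappa in \[-1, 1\].
#' @export
kappa_score <- function(set_a, set_b, universe) {
  universe <- unique(universe)
  if (length(universe) == 0L) stop("empty universe", call. = FALSE)
  set_a <- unique(set_a)
  set_b <- unique(set_b)
  if (length(setdiff(set_a, universe)) || length(setdiff(set_b, universe))) {
    stop("sets must be subsets of the universe", call. = FALSE)
  }
  n <- length(universe)
  in_a <- universe %in% set_a
  in_b <- universe %in% set_b
  n11 <- sum(in_a & in_b)
  n10 <- sum(in_a & !in_b)
  n01 <- sum(!in_a & in_b)
  n00 <- n - n11 - n10 - n01
  p_o <- (n11 + n00) / n
  p_e <- ((n11 + n10) * (n11 + n01) + (n01 + n00) * (n10 + n00)) / n^2
  if (abs(1 - p_e) < .Machine$double.eps) return(1)
  (p_o - p_e) / (1 - p_e)
}

#' Group enriched terms by kappa score
#'
#' Builds the pairwise kappa matrix of the enriched terms' member sets over
#' the union of all members, connects terms with kappa at or above the
#' threshold, and reports the connected components as functional groups, each
#' labelled by its most significant term.
#'
#' @param results a [hypergeometric_enrichment()] table (needs the `members`
#'   list-column).
#' @param kappa_threshold minimum kappa for an edge (default 0.4).
#' @return a `term_group_set`: list with `kappa_matrix`, `groups` (data frame
#'   `term`, `group`, `group_label`) and `threshold`.
#' @export
group_terms <- function(results, kappa_threshold = 0.4) {
  stopifnot(is.data.frame(results), "members" %in% names(results),
            nrow(results) >= 1L)
  terms <- results$term
  members <- results$members
  universe <- unique(unlist(members))
  k <- length(terms)
  km <- matrix(1, k, k, dimnames = list(terms, terms))
  if (k > 1) {
    for (i in seq_len(k - 1)) {
      for (j in seq(i + 1, k)) {
        km[i, j] <- km[j, i] <- kappa_score(members[[i]], members[[j]],
                                            universe)
      }
    }
  }
  adj <- km >= kappa_threshold
  diag(adj) <- FALSE
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
  comp <- igraph::components(g)$membership
  # stable group ids: order of first appearance in the input
  ids <- match(comp, unique(comp))
  label <- vapply(sort(unique(ids)), function(gr) {
    in_gr <- which(ids == gr)
    in_gr[which.min(results$p_corrected[in_gr])]
  }, 0L)
  groups <- data.frame(term = terms, group = ids,
                       group_label = terms[label][ids],
                       stringsAsFactors = FALSE)
  structure(list(kappa_matrix = km, groups = groups,
                 threshold = kappa_threshold),
            class = "term_group_set")
}

#' Benjamini-Hochberg correction
#'
#' Step-up false-discovery-rate adjustment; values are validated to lie in
#' \[0, 1\].
#'
#' @param p_values numeric vector of raw p-values.
#' @return adjusted p-values, each `>=` its raw value and capped at 1.
#' @export
bh_correction <- function(p_values) {
  if (any(!is.finite(p_values) | p_values < 0 | p_values > 1)) {
    stop("p-values must lie in [0, 1]", call. = FALSE)
  }
  stats::p.adjust(p_values, method = "BH")
}

#' Write an enrichment report TSV
#'
#' Columns mirror the conventional pathway-report layout: term, corrected p,
#' percent of term genes, overlap count, and the comma-separated overlapping
#' genes.
#'
#' @param results a [hypergeometric_enrichment()] table.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_enrichment_report <- function(results, path) {
  df <- data.frame(
    term = results$term,
    p_corrected = results$p_corrected,
    percent_genes = results$percent_genes,
    n_genes = results$k,
    associated_genes = vapply(results$overlap_genes, paste, "",
                              collapse = ","),
    stringsAsFactors = FALSE
  )
  write_tsv(df, path)
}
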
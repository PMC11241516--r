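#' Reciprocal-direction miRNA-target network
#'
#' The core integration step: an edge (miRNA m, gene g) is kept if and only if
#' the pair is a validated interaction, both features pass differential
#' expression, and their directions are opposite (miRNA up with target down,
#' or vice versa) — the reciprocal-expression predicate. Nodes without edges
#' are excluded.
#'
#' @param de_mirnas,de_genes [differential_expression()] result tables; only
#'   `feature_id`, `direction` and `passes` are used.
#' @param interactions an `interaction_set` (see [read_interaction_table()]).
#' @param arm_agnostic when `TRUE`, interaction miRNAs with no exact match in
#'   the DE list are retried with the `-5p`/`-3p` arm suffix stripped on both
#'   sides (logged); default is strict exact matching after normalization.
#' @return a `reciprocal_network`: list with `edges` (data frame `mirna`,
#'   `gene`, `mirna_direction`, `gene_direction`), `mirna_nodes`, `gene_nodes`,
#'   `mirna_direction`, `gene_direction` (named vectors over nodes).
#' @export
reciprocal_filter <- function(de_mirnas, de_genes, interactions,
                              arm_agnostic = FALSE) {
  stopifnot(inherits(interactions, "interaction_set"))
  mi <- de_mirnas[de_mirnas$passes %in% TRUE &
                    de_mirnas$direction %in% c("up", "down"), , drop = FALSE]
  ge <- de_genes[de_genes$passes %in% TRUE &
                   de_genes$direction %in% c("up", "down"), , drop = FALSE]
  mi_dir <- stats::setNames(mi$direction, normalize_mirna(mi$feature_id))
  ge_dir <- stats::setNames(ge$direction,
                            normalize_symbol(ge$feature_id,
                                             interactions$alias_map))

  rec <- interactions$records
  m_dir <- mi_dir[rec$mirna]
  if (arm_agnostic && anyNA(m_dir)) {
    strip_arm <- function(x) sub("-[35]p$", "", x)
    fb <- stats::setNames(mi_dir, strip_arm(names(mi_dir)))
    miss <- is.na(m_dir)
    m_dir[miss] <- fb[strip_arm(rec$mirna[miss])]
    if (any(miss & !is.na(m_dir))) {
      message(sum(miss & !is.na(m_dir)),
              " interaction miRNA(s) matched via arm-agnostic fallback")
    }
  }
  g_dir <- ge_dir[rec$gene]
  keep <- !is.na(m_dir) & !is.na(g_dir) & m_dir != g_dir
  edges <- data.frame(mirna = rec$mirna[keep], gene = rec$gene[keep],
                      mirna_direction = unname(m_dir[keep]),
                      gene_direction = unname(g_dir[keep]),
                      stringsAsFactors = FALSE)
  rownames(edges) <- NULL
  mn <- sort(unique(edges$mirna))
  gn <- sort(unique(edges$gene))
  structure(
    list(edges = edges, mirna_nodes = mn, gene_nodes = gn,
         mirna_direction = stats::setNames(
           edges$mirna_direction[match(mn, edges$mirna)], mn),
         gene_direction = stats::setNames(
           edges$gene_direction[match(gn, edges$gene)], gn)),
    class = "reciprocal_network"
  )
}

#' @export
print.reciprocal_network <- function(x, ...) {
  cat(sprintf("reciprocal_network: %d miRNAs, %d genes, %d edges\n",
              length(x$mirna_nodes), length(x$gene_nodes), nrow(x$edges)))
  invisible(x)
}

#' Summarize a reciprocal network
#'
#' @param network a [reciprocal_filter()] result.
#' @return list with `n_mirnas`, `n_genes`, `n_edges` and `targets`, a named
#'   list mapping each miRNA to its sorted target symbols.
#' @export
network_summary <- function(network) {
  stopifnot(inherits(network, "reciprocal_network"))
  targets <- lapply(split(network$edges$gene, network$edges$mirna),
                    function(g) sort(unique(g)))
  list(n_mirnas = length(network$mirna_nodes),
       n_genes = length(network$gene_nodes),
       n_edges = nrow(network$edges),
       targets = targets[order(names(targets))])
}

as_igraph <- function(network) {
  nodes <- data.frame(
    name = c(network$mirna_nodes, network$gene_nodes),
    type = rep(c("miRNA", "gene"),
               c(length(network$mirna_nodes), length(network$gene_nodes))),
    direction = c(unname(network$mirna_direction),
                  unname(network$gene_direction)),
    stringsAsFactors = FALSE
  )
  igraph::graph_from_data_frame(network$edges[, c("mirna", "gene")],
                                directed = TRUE, vertices = nodes)
}

network_from_edges <- function(edges, mirna_direction, gene_direction) {
  edges$mirna_direction <- unname(mirna_direction[edges$mirna])
  edges$gene_direction <- unname(gene_direction[edges$gene])
  mn <- sort(unique(edges$mirna))
  gn <- sort(unique(edges$gene))
  structure(
    list(edges = edges, mirna_nodes = mn, gene_nodes = gn,
         mirna_direction = mirna_direction[mn],
         gene_direction = gene_direction[gn]),
    class = "reciprocal_network"
  )
}

#' Export / import a reciprocal network
#'
#' `export_network()` serializes the bipartite network either as SIF lines
#' (`mirna<TAB>targets<TAB>gene`) or as GraphML with `type`
#' (`miRNA`/`gene`) and `direction` node attributes.
#' `read_network_sif()` / `read_network_graphml()` read the formats back;
#' SIF does not carry directions, so they default to the up-miRNA/down-gene
#' orientation unless supplied.
#'
#' @param network a `reciprocal_network`.
#' @param format `"sif"` or `"graphml"`.
#' @param path optional output file; when `NULL` the text is returned.
#' @return `export_network()`: the serialized text (single string), invisibly
#'   when written to `path`. Readers return a `reciprocal_network`.
#' @export
export_network <- function(network, format = c("sif", "graphml"), path = NULL) {
  stopifnot(inherits(network, "reciprocal_network"))
  format <- tolower(format[1])
  if (!format %in% c("sif", "graphml")) {
    stop("unknown network format: ", format, call. = FALSE)
  }
  if (format == "sif") {
    txt <- paste(sprintf("%s\ttargets\t%s", network$edges$mirna,
                         network$edges$gene), collapse = "\n")
    if (nzchar(txt)) txt <- paste0(txt, "\n")
  } else {
    g <- as_igraph(network)
    tmp <- path %||% tempfile(fileext = ".graphml")
    igraph::write_graph(g, tmp, format = "graphml")
    txt <- paste(readLines(tmp), collapse = "\n")
    if (is.null(path)) unlink(tmp)
  }
  if (!is.null(path)) {
    if (format == "sif") writeLines(sub("\n$", "", txt), path)
    return(invisible(txt))
  }
  txt
}

#' @rdname export_network
#' @param source file path or character vector of SIF lines.
#' @param mirna_direction,gene_direction optional named direction vectors for
#'   SIF input (defaults: miRNAs `"up"`, genes `"down"`).
#' @export
read_network_sif <- function(source, mirna_direction = NULL,
                             gene_direction = NULL) {
  lines <- if (length(source) == 1L && file.exists(source)) {
    readLines(source)
  } else {
    unlist(strsplit(source, "\n", fixed = TRUE))
  }
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  edges <- data.frame(mirna = vapply(parts, `[`, "", 1L),
                      gene = vapply(parts, `[`, "", 3L),
                      stringsAsFactors = FALSE)
  mn <- sort(unique(edges$mirna))
  gn <- sort(unique(edges$gene))
  md <- mirna_direction %||% stats::setNames(rep("up", length(mn)), mn)
  gd <- gene_direction %||% stats::setNames(rep("down", length(gn)), gn)
  network_from_edges(edges, md, gd)
}

#' @rdname export_network
#' @export
read_network_graphml <- function(source) {
  path <- source
  if (!(length(source) == 1L && file.exists(source))) {
    path <- tempfile(fileext = ".graphml")
    writeLines(source, path)
    on.exit(unlink(path))
  }
  g <- igraph::read_graph(path, format = "graphml")
  el <- igraph::as_edgelist(g)
  v <- data.frame(name = igraph::V(g)$name, type = igraph::V(g)$type,
                  direction = igraph::V(g)$direction, stringsAsFactors = FALSE)
  edges <- data.frame(mirna = el[, 1], gene = el[, 2], stringsAsFactors = FALSE)
  md <- stats::setNames(v$direction[v$type == "miRNA"],
                        v$name[v$type == "miRNA"])
  gd <- stats::setNames(v$direction[v$type == "gene"],
                        v$name[v$type == "gene"])
  network_from_edges(edges, md, gd)
}

#' Write a per-miRNA target summary TSV
#'
#' @param network a `reciprocal_network`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_network_summary <- function(network, path) {
  s <- network_summary(network)
  df <- data.frame(
    mirna = names(s$targets),
    n_targets = vapply(s$targets, length, 0L),
    targets = vapply(s$targets, paste, "", collapse = ","),
    stringsAsFactors = FALSE
  )
  write_tsv(df, path)
}
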
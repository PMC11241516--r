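# shared helpers: fixture paths and hand-rolled DE tables / random instances

fixture_interactions <- function(...) {
  read_interaction_table(
    system.file("extdata", "table2_interactions.tsv", package = "mirtarnet"),
    ...)
}

fixture_collection <- function() {
  read_gmt(system.file("extdata", "table3_pathways.gmt", package = "mirtarnet"))
}

# minimal passing DE table with a fixed direction per feature
mk_de <- function(ids, direction, passes = TRUE) {
  n <- length(ids)
  direction <- rep_len(direction, n)
  passes <- rep_len(passes, n)
  data.frame(
    feature_id = as.character(ids),
    mean_R = rep(0, n), mean_NR = rep(0, n),
    log2fc = ifelse(direction == "up", 1, -1),
    linear_fc = ifelse(direction == "up", 2, -2),
    p_value = rep(0.01, n),
    direction = ifelse(passes, direction, "none"),
    passes = passes, testable = rep(TRUE, n),
    stringsAsFactors = FALSE
  )
}

# random DE table: random pass flags and directions
random_de <- function(ids) {
  passes <- sample(c(TRUE, FALSE), length(ids), replace = TRUE)
  dir <- ifelse(passes, sample(c("up", "down"), length(ids), replace = TRUE),
                "none")
  mk_de(ids, dir, passes)
}

# brute-force reciprocal filter: row-by-row lookup with the bare predicate
brute_reciprocal_edges <- function(de_mi, de_ge, interactions) {
  rec <- interactions$records
  keep <- logical(nrow(rec))
  for (i in seq_len(nrow(rec))) {
    mi <- which(normalize_mirna(de_mi$feature_id) == rec$mirna[i])
    ge <- which(normalize_symbol(de_ge$feature_id,
                                 interactions$alias_map) == rec$gene[i])
    if (length(mi) == 1 && length(ge) == 1 &&
        isTRUE(de_mi$passes[mi]) && isTRUE(de_ge$passes[ge]) &&
        de_mi$direction[mi] %in% c("up", "down") &&
        de_ge$direction[ge] %in% c("up", "down") &&
        de_mi$direction[mi] != de_ge$direction[ge]) {
      keep[i] <- TRUE
    }
  }
  e <- rec[keep, c("mirna", "gene")]
  e[order(e$mirna, e$gene), ]
}

sorted_edges <- function(network) {
  e <- network$edges[, c("mirna", "gene")]
  e <- e[order(e$mirna, e$gene), ]
  rownames(e) <- NULL
  e
}
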
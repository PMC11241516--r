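test_that("interaction reader normalizes, deduplicates and validates", {
  txt <- c("miRNA\tTarget Gene",
           "hsa-miR-223-3p\tPRDM1",
           "hsa-miR-223-3p\tPRDM1",
           "HSA-miR-130b-3p\tPrdm1")
  it <- read_interaction_table(txt)
  expect_equal(nrow(it$records), 2L)
  expect_true(all(c("hsa-mir-223-3p", "hsa-mir-130b-3p") %in% it$records$mirna))
  expect_true(all(it$records$gene == "PRDM1"))

  # minimal two-column dialect
  it2 <- read_interaction_table(c("mir\tgene", "hsa-miR-21-5p\tPTEN"))
  expect_equal(it2$records$gene, "PTEN")

  # alias corrections applied by default, not when disabled
  it3 <- read_interaction_table(c("miRNA\tTarget Gene",
                                  "hsa-miR-223-3p\tCHUCK"))
  expect_equal(it3$records$gene, "CHUK")
  it4 <- read_interaction_table(c("miRNA\tTarget Gene",
                                  "hsa-miR-223-3p\tCHUCK"), alias_map = NULL)
  expect_equal(it4$records$gene, "CHUCK")

  expect_error(read_interaction_table(c("foo\tbar\tmiRNA", "a\tb\tc")),
               "column")
  expect_warning(read_interaction_table("miRNA\tTarget Gene"), "empty")
})

test_that("curated fixture yields the 37-miRNA / 60-gene bipartite network", {
  it <- fixture_interactions()
  de_mi <- mk_de(unique(it$records$mirna), "up")
  de_ge <- mk_de(unique(it$records$gene), "down")
  net <- reciprocal_filter(de_mi, de_ge, it)
  s <- network_summary(net)
  expect_equal(s$n_mirnas, 37L)
  expect_equal(s$n_genes, 60L)
  expect_equal(s$targets[["hsa-mir-200c-3p"]],
               sort(c("ZEB1", "FLT1", "RNF2", "CFL2", "DUSP1", "KLF9",
                      "CRKL", "ROCK2")))
  # printed-string counts are alias-independent
  it_raw <- fixture_interactions(alias_map = NULL)
  s_raw <- network_summary(reciprocal_filter(
    mk_de(unique(it_raw$records$mirna), "up"),
    mk_de(unique(it_raw$records$gene), "down"), it_raw))
  expect_equal(c(s_raw$n_mirnas, s_raw$n_genes), c(37L, 60L))
})

test_that("same-direction and non-passing features are excluded", {
  it <- interaction_set(data.frame(mirna = c("m1", "m2", "m3"),
                                   gene = c("G1", "G2", "G3")))
  de_mi <- mk_de(c("m1", "m2", "m3"), c("up", "up", "up"))
  de_ge <- mk_de(c("G1", "G2", "G3"), c("down", "up", "down"),
                 passes = c(TRUE, TRUE, FALSE))
  net <- reciprocal_filter(de_mi, de_ge, it)
  expect_equal(sorted_edges(net),
               data.frame(mirna = "m1", gene = "G1"))
  # empty inputs give an empty network, not an error
  empty <- reciprocal_filter(mk_de(character(), character()),
                             mk_de(character(), character()), it)
  s <- network_summary(empty)
  expect_equal(c(s$n_mirnas, s$n_genes, s$n_edges), c(0L, 0L, 0L))
  expect_length(s$targets, 0L)
})

test_that("filter matches the brute-force oracle on random instances", {
  for (seed in 1:5) {
    set.seed(seed)
    mirnas <- sprintf("hsa-mir-%d-5p", 1:30)
    genes <- sprintf("G%02d", 1:40)
    pairs <- expand.grid(mirna = mirnas, gene = genes,
                         stringsAsFactors = FALSE)
    pairs <- pairs[sample(nrow(pairs), 300), ]
    it <- interaction_set(pairs)
    de_mi <- random_de(mirnas)
    de_ge <- random_de(genes)
    net <- reciprocal_filter(de_mi, de_ge, it)
    oracle <- brute_reciprocal_edges(de_mi, de_ge, it)
    rownames(oracle) <- NULL
    expect_equal(sorted_edges(net), oracle)
  }
})

test_that("tightening DE thresholds never adds edges; flipping labels keeps them", {
  set.seed(9)
  co <- generate_cohort(cohort_config(seed = 9))
  de_mi <- differential_expression(co$mirna_matrix)
  de_ge <- differential_expression(co$gene_matrix)
  loose <- reciprocal_filter(de_mi, de_ge, co$interactions)
  de_mi2 <- differential_expression(co$mirna_matrix, fc_threshold = 3,
                                    p_threshold = 0.01)
  de_ge2 <- differential_expression(co$gene_matrix, fc_threshold = 3,
                                    p_threshold = 0.01)
  tight <- reciprocal_filter(de_mi2, de_ge2, co$interactions)
  key <- function(n) paste(n$edges$mirna, n$edges$gene)
  expect_true(all(key(tight) %in% key(loose)))

  # flipping every direction leaves the inequality predicate invariant
  flip <- function(de) {
    de$direction <- c(up = "down", down = "up", none = "none")[de$direction]
    de
  }
  flipped <- reciprocal_filter(flip(de_mi), flip(de_ge), co$interactions)
  expect_setequal(key(flipped), key(loose))
})

test_that("arm-agnostic fallback matches bare names only when enabled", {
  it <- interaction_set(data.frame(mirna = "hsa-mir-421", gene = "ATM"))
  de_mi <- mk_de("hsa-mir-421-3p", "up")
  de_ge <- mk_de("ATM", "down")
  strict <- reciprocal_filter(de_mi, de_ge, it)
  expect_equal(nrow(strict$edges), 0L)
  relaxed <- suppressMessages(
    reciprocal_filter(de_mi, de_ge, it, arm_agnostic = TRUE))
  expect_equal(nrow(relaxed$edges), 1L)
})

test_that("network export round-trips through SIF and GraphML", {
  it <- fixture_interactions()
  net <- reciprocal_filter(mk_de(unique(it$records$mirna), "up"),
                           mk_de(unique(it$records$gene), "down"), it)
  # single-edge SIF
  one <- reciprocal_filter(mk_de("hsa-mir-146-5p", "up"),
                           mk_de("TRAF6", "down"), it)
  expect_equal(export_network(one, "sif"), "hsa-mir-146-5p\ttargets\tTRAF6\n")

  sif <- export_network(net, "sif")
  back <- read_network_sif(strsplit(sif, "\n")[[1]])
  expect_equal(sorted_edges(back), sorted_edges(net))

  gml_path <- withr::local_tempfile(fileext = ".graphml")
  export_network(net, "graphml", gml_path)
  back2 <- read_network_graphml(gml_path)
  expect_equal(sorted_edges(back2), sorted_edges(net))
  expect_equal(length(back2$mirna_nodes) + length(back2$gene_nodes), 97L)
  expect_equal(back2$mirna_direction[net$mirna_nodes],
               net$mirna_direction)

  expect_error(export_network(net, "gexf"), "unknown")
})
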
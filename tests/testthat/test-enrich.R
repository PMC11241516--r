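test_that("GMT reader and collection validation work", {
  col <- fixture_collection()
  expect_length(col$sets, 15L)
  expect_equal(length(col$sets[["NF-kappa B signalling pathway"]]), 104L)
  expect_true(all(unlist(col$sets) %in% col$background))
  expect_error(gene_set_collection(list(a = character())), "non-empty")
  expect_error(gene_set_collection(list(a = "G1"), background = "G2"),
               "outside")
})

test_that("hypergeometric p matches combinatorial oracle and is monotone in k", {
  # independent oracle: direct combinatorial tail sum
  tail_oracle <- function(k, K, N, n) {
    if (k == 0) return(1)
    j <- k:min(K, n)
    sum(choose(K, j) * choose(N - K, n - j)) / choose(N, n)
  }
  col <- gene_set_collection(list(term = paste0("g", 1:5)),
                             background = paste0("g", 1:20))
  res <- suppressWarnings(
    hypergeometric_enrichment(paste0("g", c(1:3, 10, 11)), col))
  expect_equal(res$k, 3L)
  expect_equal(res$p_hyper, tail_oracle(3, 5, 20, 5), tolerance = 1e-14)

  # literal enumeration over all C(10, 4) draws for a tiny universe
  N <- 10; K <- 4; n <- 4
  draws <- utils::combn(N, n)
  ks <- apply(draws, 2, function(d) sum(d <= K))
  for (k in 0:4) {
    expect_equal(tail_oracle(k, K, N, n), mean(ks >= k), tolerance = 1e-12)
  }

  # monotone decreasing in k for fixed (N, K, n)
  ps <- vapply(0:5, tail_oracle, 0, K = 5, N = 20, n = 5)
  expect_true(all(diff(ps) < 0))

  # disjoint query
  res0 <- suppressWarnings(hypergeometric_enrichment(paste0("g", 15:18), col))
  expect_equal(res0$k, 0L)
  expect_equal(res0$p_hyper, 1)
})

test_that("query genes outside the background are dropped with a warning", {
  col <- gene_set_collection(list(term = paste0("g", 1:5)),
                             background = paste0("g", 1:20))
  expect_warning(res <- hypergeometric_enrichment(c("g1", "g2", "NOPE"), col),
                 "dropped")
  expect_equal(res$n, 2L)
  expect_error(suppressWarnings(hypergeometric_enrichment("NOPE", col)),
               "no query genes")
})

test_that("percent_genes reports half-up percentages of the term", {
  expect_equal(percent_genes(6, 104), 5.77)
  expect_equal(percent_genes(8, 294), 2.72)
  expect_equal(percent_genes(0, 10), 0)
  expect_equal(percent_genes(10, 10), 100)
  expect_error(percent_genes(1, 0), "K")
  expect_error(percent_genes(5, 4), "k")
})

test_that("kappa score agrees with the 2x2 hand computation", {
  u <- paste0("x", 1:4)
  expect_equal(kappa_score(c("x1", "x2"), c("x1", "x2"), u), 1)
  # disjoint sets covering the universe: p_o = 0, p_e = 0.5 -> kappa = -1
  expect_equal(kappa_score(c("x1", "x2"), c("x3", "x4"), u), -1)
  # hand-worked asymmetric case: A={x1,x2}, B={x2,x3}
  # n11=1 n10=1 n01=1 n00=1, p_o=.5, p_e=.5 -> kappa = 0
  expect_equal(kappa_score(c("x1", "x2"), c("x2", "x3"), u), 0)
  # symmetry on random sets
  set.seed(4)
  u2 <- paste0("g", 1:30)
  for (i in 1:10) {
    a <- sample(u2, sample(5:15, 1))
    b <- sample(u2, sample(5:15, 1))
    expect_equal(kappa_score(a, b, u2), kappa_score(b, a, u2))
  }
  expect_error(kappa_score("a", "a", character()), "universe")
  expect_error(kappa_score("zz", "x1", u), "subsets")
})

test_that("term grouping finds kappa components, order-invariantly", {
  mk_res <- function(terms, members, p) {
    data.frame(term = terms, p_corrected = p,
               stringsAsFactors = FALSE) |>
      (\(d) {d$members <- members; d})()
  }
  # identical member sets group together; a disjoint one stays alone
  res <- mk_res(c("A", "B", "C"),
                list(paste0("g", 1:5), paste0("g", 1:5), paste0("h", 1:5)),
                c(0.01, 0.02, 0.03))
  tg <- group_terms(res)
  expect_equal(tg$groups$group[1], tg$groups$group[2])
  expect_false(tg$groups$group[3] == tg$groups$group[1])
  expect_equal(unique(tg$groups$group_label[1:2]), "A")

  # all-disjoint terms give singletons
  res2 <- mk_res(c("A", "B", "C"),
                 list(paste0("a", 1:4), paste0("b", 1:4), paste0("c", 1:4)),
                 c(0.01, 0.02, 0.03))
  expect_equal(length(unique(group_terms(res2)$groups$group)), 3L)

  # union-find oracle on random terms + input-order invariance
  set.seed(6)
  u <- paste0("g", 1:40)
  members <- lapply(1:10, function(i) sample(u, sample(5:12, 1)))
  res3 <- mk_res(paste0("T", 1:10), members, runif(10))
  tg3 <- group_terms(res3, kappa_threshold = 0.3)
  # oracle: union-find over thresholded kappa matrix
  parent <- 1:10
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  for (i in 1:9) for (j in (i + 1):10) {
    if (kappa_score(members[[i]], members[[j]], unique(unlist(members))) >= 0.3) {
      parent[find(i)] <- find(j)
    }
  }
  roots <- vapply(1:10, find, 0L)
  same <- outer(roots, roots, "==")
  got <- outer(tg3$groups$group, tg3$groups$group, "==")
  expect_equal(got, same, ignore_attr = TRUE)

  perm <- sample(10)
  tg_perm <- group_terms(res3[perm, ], kappa_threshold = 0.3)
  m <- match(res3$term, tg_perm$groups$term)
  got_perm <- outer(tg_perm$groups$group[m], tg_perm$groups$group[m], "==")
  expect_equal(got_perm, same, ignore_attr = TRUE)
})

test_that("BH correction matches the hand computation and bounds", {
  expect_equal(bh_correction(0.02), 0.02)
  expect_equal(bh_correction(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(bh_correction(rep(1, 4)), rep(1, 4))
  p <- c(0.001, 0.04, 0.2, 0.9)
  q <- bh_correction(p)
  expect_true(all(q >= p))
  expect_true(all(q <= 1))
  expect_error(bh_correction(c(0.5, 1.2)), "0, 1")
})

test_that("Bonferroni option is at least as conservative as BH", {
  col <- fixture_collection()
  q <- col$sets[["NF-kappa B signalling pathway"]][1:6]
  bh <- suppressWarnings(hypergeometric_enrichment(q, col, adjust = "BH"))
  bf <- suppressWarnings(hypergeometric_enrichment(q, col,
                                                   adjust = "bonferroni"))
  m <- match(bh$term, bf$term)
  expect_true(all(bf$p_corrected[m] >= bh$p_corrected - 1e-15))
})
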
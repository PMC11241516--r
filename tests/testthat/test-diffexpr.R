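test_that("Welch t-test handles identity, oracle and degenerate cases", {
  # identical multisets with positive variance
  r <- welch_t_pvalue(c(1, 2, 3), c(3, 1, 2))
  expect_equal(r$statistic, 0)
  expect_equal(r$p, 1)

  # frozen high-precision oracle (independent arbitrary-precision t CDF)
  r <- welch_t_pvalue(c(1, 2, 3), c(4, 5, 6))
  expect_equal(abs(r$statistic), 3.6742346141747673, tolerance = 1e-12)
  expect_equal(r$p, 0.021311641128756713, tolerance = 1e-12)

  # zero variance in both groups
  expect_equal(welch_t_pvalue(c(2, 2), c(2, 2))$p, 1)
  expect_equal(welch_t_pvalue(c(2, 2), c(3, 3))$p, 0)
  expect_error(welch_t_pvalue(1, c(1, 2)), "at least 2")
})

test_that("parametric and brute-force permutation p-values shrink together", {
  a <- c(0.0, 0.5, 1.0)
  perm_p <- function(a, b) {
    pool <- c(a, b)
    obs <- abs(mean(b) - mean(a))
    idx <- utils::combn(6, 3)
    ds <- apply(idx, 2, function(i) abs(mean(pool[-i]) - mean(pool[i])))
    mean(ds >= obs - 1e-12)
  }
  effects <- c(0.5, 2, 5)
  par_p <- vapply(effects, function(e) welch_t_pvalue(a, a + e)$p, 0)
  prm_p <- vapply(effects, function(e) perm_p(a, a + e), 0)
  expect_true(all(diff(par_p) < 0))
  expect_true(all(diff(prm_p) <= 0))
  # permutation p cannot undercut its own resolution
  expect_true(all(prm_p >= 1 / choose(6, 3) - 1e-12))
})

test_that("fold-change and p gates apply strictly and symmetrically", {
  set.seed(1)
  base <- rnorm(6, sd = 0.01)
  m <- rbind(
    small_fc = c(base, base + 0.30),      # log2fc 0.30, tiny p: FC gate fails
    clear_up = c(base, base + 1.00),      # log2fc 1.0: passes up
    clear_dn = c(base, base - 1.00),      # passes down
    flat = c(base, base + 0.001)
  )
  colnames(m) <- paste0("s", 1:12)
  em <- expression_matrix(m, rep(c("R", "NR"), each = 6))
  de <- differential_expression(em)
  expect_lt(de[de$feature_id == "small_fc", "p_value"], 0.05)
  expect_false(de[de$feature_id == "small_fc", "passes"])
  expect_true(de[de$feature_id == "clear_up", "passes"])
  expect_equal(de[de$feature_id == "clear_up", "direction"], "up")
  expect_true(de[de$feature_id == "clear_dn", "passes"])
  expect_equal(de[de$feature_id == "clear_dn", "direction"], "down")
  expect_false(de[de$feature_id == "flat", "passes"])
  # signed linear fold change has magnitude >= 1 always
  expect_true(all(abs(de$linear_fc) >= 1))
})

test_that("swapping class labels negates log2fc and keeps p", {
  set.seed(2)
  m <- matrix(rnorm(8 * 10), nrow = 8,
              dimnames = list(paste0("f", 1:8), paste0("s", 1:10)))
  lab <- rep(c("R", "NR"), each = 5)
  de1 <- differential_expression(expression_matrix(m, lab))
  de2 <- differential_expression(expression_matrix(m, rev(lab)))
  expect_equal(de1$log2fc, -de2$log2fc)
  expect_equal(de1$p_value, de2$p_value, tolerance = 1e-12)
})

test_that("features with too few complete observations are untestable", {
  m <- matrix(rnorm(2 * 8), nrow = 2,
              dimnames = list(c("ok", "gappy"), paste0("s", 1:8)))
  m["gappy", 1:3] <- NA # leaves 1 responder value
  em <- expression_matrix(m, rep(c("R", "NR"), each = 4))
  de <- differential_expression(em)
  expect_false(de[de$feature_id == "gappy", "testable"])
  expect_false(de[de$feature_id == "gappy", "passes"])
  expect_true(de[de$feature_id == "ok", "testable"])
})

test_that("strong planted effects are fully recovered with correct direction", {
  co <- generate_cohort(cohort_config(n_responders = 10, n_nonresponders = 10,
                                      effect_log2 = 2, noise_sd = 0.25,
                                      seed = 21))
  de_mi <- differential_expression(co$mirna_matrix)
  de_ge <- differential_expression(co$gene_matrix)
  mi <- de_mi[match(co$truth_pairs$mirna, de_mi$feature_id), ]
  ge <- de_ge[match(co$truth_pairs$gene, de_ge$feature_id), ]
  expect_true(all(mi$passes) && all(mi$direction == "up"))
  expect_true(all(ge$passes) && all(ge$direction == "down"))
})

test_that("BH-adjusted gate is exposed and more conservative", {
  set.seed(3)
  m <- matrix(rnorm(50 * 10), nrow = 50,
              dimnames = list(paste0("f", 1:50), paste0("s", 1:10)))
  m[1, 6:10] <- m[1, 6:10] + 8
  em <- expression_matrix(m, rep(c("R", "NR"), each = 5))
  raw <- differential_expression(em)
  adj <- suppressMessages(differential_expression(em, adjust = "BH"))
  expect_true(all(adj$p_adjusted >= adj$p_value - 1e-15, na.rm = TRUE))
  expect_true(sum(adj$passes) <= sum(raw$passes))
  expect_true(adj$passes[1])
})
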
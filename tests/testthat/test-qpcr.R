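mk_ct <- function(sample, group, target, cts) {
  data.frame(sample = sample, group = group, target = target,
             replicate = seq_along(cts), ct = cts, stringsAsFactors = FALSE)
}

test_that("replicate collapse applies the reliability cut-off", {
  ct <- rbind(mk_ct("s1", "R", "mA", c(30.0, 30.2, 30.4)),
              mk_ct("s2", "R", "mA", c(30.0, 36.0, 30.4)),
              mk_ct("s3", "R", "mA", c(36, 37, 38)))
  out <- suppressMessages(collapse_replicates(ct))
  expect_equal(out$mean_ct[out$sample == "s1"], 30.2)
  expect_equal(out$mean_ct[out$sample == "s2"], 30.2)  # 36 dropped
  expect_true(is.na(out$mean_ct[out$sample == "s3"]))
  # boundary: Ct = 35 is kept (rule is strictly greater)
  ct35 <- mk_ct("s4", "R", "mA", c(35, 35, 35))
  expect_equal(collapse_replicates(ct35)$mean_ct, 35)
  # strict sample-level interpretation drops the whole measurement
  strict <- suppressMessages(collapse_replicates(ct, sample_level = TRUE))
  expect_true(is.na(strict$mean_ct[strict$sample == "s2"]))
  expect_error(collapse_replicates(mk_ct("s", "R", "m", c(-1, 30, 30))),
               "positive")
})

test_that("delta-delta-Ct fold changes follow the closed form", {
  # target == reference everywhere -> fold 1
  ct <- rbind(mk_ct("r1", "R", "mA", rep(25, 3)),
              mk_ct("r1", "R", "REF", rep(25, 3)),
              mk_ct("n1", "NR", "mA", rep(27, 3)),
              mk_ct("n1", "NR", "REF", rep(27, 3)),
              mk_ct("r2", "R", "mA", rep(24, 3)),
              mk_ct("r2", "R", "REF", rep(24, 3)))
  rel <- relative_quantification(ct, "REF")
  expect_true(all(rel$fold == 1))

  # NR sample one cycle below the calibrator mean delta-Ct -> fold 2
  ct2 <- rbind(mk_ct("r1", "R", "mA", rep(28, 3)),
               mk_ct("r1", "R", "REF", rep(22, 3)),
               mk_ct("r2", "R", "mA", rep(28, 3)),
               mk_ct("r2", "R", "REF", rep(22, 3)),
               mk_ct("n1", "NR", "mA", rep(27, 3)),
               mk_ct("n1", "NR", "REF", rep(22, 3)))
  rel2 <- relative_quantification(ct2, "REF")
  expect_equal(rel2$fold[rel2$sample == "n1"], 2)
  # calibrator group is centred: mean delta-delta-Ct of R is 0
  expect_equal(mean(rel2$delta_delta_ct[rel2$group == "R"]), 0)
})

test_that("folds are invariant to per-sample Ct shifts", {
  set.seed(8)
  ct <- generate_ct_table(6, targets = c("mA", "mB"), group_shift_ct = 1,
                          seed = 8)
  rel <- relative_quantification(ct, "RNU48")
  shifted <- ct
  offs <- stats::setNames(runif(length(unique(ct$sample)), -2, 2),
                          unique(ct$sample))
  shifted$ct <- shifted$ct + offs[shifted$sample]
  rel_s <- relative_quantification(shifted, "RNU48")
  expect_equal(rel_s$fold, rel$fold, tolerance = 1e-12)
})

test_that("samples without a reference measurement are excluded with warning", {
  ct <- rbind(mk_ct("r1", "R", "mA", rep(28, 3)),
              mk_ct("r1", "R", "REF", rep(22, 3)),
              mk_ct("n1", "NR", "mA", rep(27, 3)))
  collapsed <- collapse_replicates(ct)
  expect_warning(rel <- delta_delta_ct(collapsed, "REF"), "reference")
  expect_false("n1" %in% rel$sample)
})

test_that("Mann-Whitney U matches enumeration and identities", {
  r <- mann_whitney_u(c(1, 2, 3), c(4, 5, 6))
  expect_equal(r$U, 0)
  expect_equal(r$p, 0.1)
  expect_true(r$exact)

  # identity U(a,b) + U(b,a) = n_a * n_b, with and without ties
  a <- c(1.2, 3.5, 2.2, 9)
  b <- c(0.5, 3.5, 7)
  expect_equal(mann_whitney_u(a, b)$U + mann_whitney_u(b, a)$U,
               length(a) * length(b))

  # identical groups: p = 1 up to the approximation
  expect_gt(mann_whitney_u(c(1, 2, 3), c(1, 2, 3))$p, 0.99)

  # exact path vs brute-force enumeration over all rank assignments
  enum_p <- function(a, b) {
    na <- length(a); nb <- length(b)
    u_obs <- sum(outer(a, b, ">"))
    pool <- c(a, b)
    idx <- utils::combn(na + nb, na)
    us <- apply(idx, 2, function(i) sum(outer(pool[i], pool[-i], ">")))
    if (u_obs > na * nb / 2) min(1, 2 * mean(us >= u_obs))
    else min(1, 2 * mean(us <= u_obs))
  }
  set.seed(10)
  for (i in 1:8) {
    na <- sample(2:6, 1); nb <- sample(2:6, 1)
    x <- sample(seq(0.1, 20, by = 0.1), na + nb) # distinct -> no ties
    a <- x[1:na]; b <- x[-(1:na)]
    got <- mann_whitney_u(a, b)
    expect_equal(got$p, enum_p(a, b), tolerance = 1e-12)
    expect_equal(got$U, sum(outer(a, b, ">")))
  }
  expect_error(mann_whitney_u(numeric(), 1:3), "non-empty")
})

test_that("planted NR up-regulation yields higher NR fold medians", {
  ct <- generate_ct_table(8, targets = c("mA", "mB"), group_shift_ct = 1.5,
                          seed = 12)
  rep <- qpcr_group_report(relative_quantification(ct, "RNU48"))
  expect_true(all(rep$median_fold_NR > rep$median_fold_R))
  expect_true(all(rep$p < 0.05))
})
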
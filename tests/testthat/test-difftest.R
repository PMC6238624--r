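test_that("size factors follow the median-of-ratios definition", {
  # identical libraries -> all 1
  m <- matrix(rep(c(4L, 7L, 12L), 2), ncol = 2)
  expect_equal(unname(estimate_size_factors(m)), c(1, 1))
  # hand-derived: geometric means (8, 2, 18); ratio medians (0.5, 2)
  m2 <- matrix(c(4L, 1L, 9L, 16L, 4L, 36L), ncol = 2)
  expect_equal(unname(estimate_size_factors(m2)), c(0.5, 2.0))
  # scale equivariance of size-factor ratios: scaling one library by c
  # multiplies its factor by c relative to every other library (the
  # geometric-mean reference itself absorbs c^(1/n), so only ratios are
  # exactly equivariant -- the same holds for DESeq2)
  set.seed(1)
  m3 <- matrix(rpois(300, 40), ncol = 3) + 1L
  sf <- estimate_size_factors(m3)
  m3b <- m3; m3b[, 2] <- m3b[, 2] * 5L
  sf2 <- estimate_size_factors(m3b)
  expect_equal(unname((sf2[2] / sf2[1]) / (sf[2] / sf[1])), 5,
               tolerance = 1e-12)
  expect_equal(unname(sf2[3] / sf2[1]), unname(sf[3] / sf[1]),
               tolerance = 1e-12)
  # degenerate reference set
  expect_error(estimate_size_factors(matrix(c(1L, 0L, 0L, 2L), 2)),
               "reference set")
})

test_that("size factors agree with the DESeq2 reference implementation", {
  set.seed(99)
  counts <- matrix(rnbinom(6 * 400, size = 5,
                           mu = rep(c(20, 50, 100), 800)), ncol = 6)
  counts <- counts + 1L   # all-positive so both reference sets coincide
  ours <- estimate_size_factors(counts)
  ref <- DESeq2::estimateSizeFactorsForMatrix(counts)
  expect_equal(unname(ours), unname(ref), tolerance = 1e-10)
})

test_that("dispersion estimation recovers known generative dispersions", {
  sf <- c(1, 1.2, 0.8, 1.1, 0.9, 1.05)
  cond <- rep(c("wild_type", "mutant"), each = 3)
  # Poisson data (true alpha 0): shrunk estimates nearly vanish
  set.seed(21)
  mu <- runif(2000, 50, 200)
  cp <- sapply(sf, function(s) rpois(2000, mu * s))
  dp <- estimate_dispersions(cp, estimate_size_factors(cp), cond)
  expect_lte(median(dp$alpha), 0.05)
  # NB alpha = 0.2 at mean 100: median within [0.1, 0.4]
  set.seed(22)
  cn <- sapply(sf, function(s) rnbinom(2000, size = 1 / 0.2, mu = 100 * s))
  dn <- estimate_dispersions(cn, estimate_size_factors(cn), cond)
  expect_gte(median(dn$alpha), 0.1)
  expect_lte(median(dn$alpha), 0.4)
  # all-zero position: raw alpha 0 and excluded from the trend fit
  cz <- rbind(cn[1:50, ], 0L)
  dz <- estimate_dispersions(cz, estimate_size_factors(cn)[1:6], cond)
  expect_equal(dz$alpha_raw[51], 0)
  expect_error(estimate_dispersions(cn[, 1:2],
                                    c(1, 1), c("wild_type", "mutant")),
               "replicates")
})

test_that("wald_test computes fold changes, p-values and pseudocounts", {
  cond <- rep(c("wild_type", "mutant"), each = 2)
  sf <- rep(1, 4)
  r <- wald_test(matrix(c(40, 40, 10, 10), 1), cond, sf, alpha = 0.05)
  expect_equal(r$log2fc, 2)
  expect_false(r$pseudocount_used)
  # identical counts in both conditions: symmetric null
  r0 <- wald_test(matrix(c(15, 20, 15, 20), 1), cond, sf, alpha = 0.1)
  expect_equal(r0$log2fc, 0)
  expect_equal(r0$p_value, 1)
  # pseudocount keeps single-strain positions finite
  r1 <- wald_test(matrix(c(30, 30, 0, 0), 1), cond, sf, alpha = 0.1)
  expect_true(is.finite(r1$log2fc) && r1$pseudocount_used)
  expect_error(wald_test(matrix(1:4, 1), cond, sf, alpha = -1), "finite")
})

test_that("null NB simulation yields calibrated Wald p-values", {
  set.seed(31)
  sf_true <- c(1, 1.2, 0.8, 1.1, 0.9, 1.05)
  cond <- rep(c("wild_type", "mutant"), each = 3)
  counts <- sapply(sf_true, function(s)
    rnbinom(10000, size = 1 / 0.1, mu = 50 * s))
  sf <- estimate_size_factors(counts)
  disp <- estimate_dispersions(counts, sf, cond)
  res <- wald_test(counts, cond, sf, disp$alpha)
  expect_gte(mean(res$p_value < 0.05), 0.03)
  expect_lte(mean(res$p_value < 0.05), 0.07)
})

test_that("adjust_bh implements step-up BH", {
  expect_equal(adjust_bh(c(0.01, 0.02, 0.04, 0.05)),
               c(0.04, 0.04, 0.05, 0.05))
  expect_equal(adjust_bh(rep(1, 5)), rep(1, 5))
  expect_equal(adjust_bh(0.3), 0.3)
  expect_error(adjust_bh(c(0.1, 1.2)), "\\[0, 1\\]")
  set.seed(5)
  for (i in 1:50) {
    p <- runif(sample(1:200, 1))
    expect_equal(adjust_bh(p), bh_bruteforce(p))
    expect_equal(adjust_bh(p), p.adjust(p, "BH"))
    expect_true(all(adjust_bh(p) >= p - 1e-12))
  }
})

test_that("run_difftest is scale-invariant and label-symmetric", {
  set.seed(41)
  tab <- toy_table(matrix(rnbinom(120 * 6, size = 10, mu = 60), ncol = 6))
  res <- run_difftest(tab)
  # scale invariance: scaling one library moves its size factor by x4
  # relative to the others; fold changes are exactly unchanged and
  # p-values only through the weak scale dependence of the moment
  # dispersion estimates
  tab2 <- tab
  tab2$counts[, 3] <- tab2$counts[, 3] * 4L
  res2 <- run_difftest(tab2)
  sf_a <- attr(res, "size_factors"); sf_b <- attr(res2, "size_factors")
  expect_equal(unname((sf_b[3] / sf_b[1]) / (sf_a[3] / sf_a[1])), 4,
               tolerance = 1e-9)
  expect_equal(res2$log2fc, res$log2fc, tolerance = 1e-12)
  expect_equal(res2$p_value, res$p_value, tolerance = 0.02)
  # symmetry: swapping condition labels negates log2fc, keeps p
  tab3 <- tab
  tab3$libraries$condition <- ifelse(tab$libraries$condition == "mutant",
                                     "wild_type", "mutant")
  res3 <- run_difftest(tab3)
  expect_equal(res3$log2fc, -res$log2fc)
  expect_equal(res3$p_value, res$p_value)
})

test_that("ma_table reproduces the MA-plot significance classes", {
  df <- data.frame(base_mean = c(100, 80, 60, 50),
                   log2fc = c(1.5, -2, 3, 0.5),
                   padj = c(0.01, 0.001, 0.2, 0.01))
  cls <- ma_table(df)$class
  expect_equal(as.character(cls),
               c("wt_enriched", "mut_enriched", "ns", "ns"))
})
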
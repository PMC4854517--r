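test_that("coverage filter keeps SNPs inside the band in every pool", {
  snps <- data.frame(chrom = "s1", pos = c(10L, 20L, 30L),
                     ref = "A", alt = "C")
  ref <- matrix(c(25L, 25L, 40L, 30L, 4L, 40L, 30L, 25L, 40L), 3)
  alt <- matrix(c(6L, 20L, 11L, 8L, 25L, 10L, 8L, 20L, 15L), 3)
  cc <- pool_counts(snps, ref, alt)   # totals: (31,38,38)/(45,29,45)/(51,50,55)
  out <- suppressMessages(filter_by_coverage(cc, 30, 50))
  expect_equal(out$snps$pos, 10L)     # row2 has a 29x pool, row3 a 51x pool
  expect_warning(suppressMessages(filter_by_coverage(cc, 300, 500)),
                 "every SNP")
})

test_that("count normalisation matches the hand-derived examples", {
  expect_equal(normalize_counts(40, 20, 30), list(ref = 20, alt = 10))
  expect_equal(normalize_counts(20, 10, 30), list(ref = 20, alt = 10))
  expect_equal(normalize_counts(99, 1, 30), list(ref = 29, alt = 1))
})

test_that("normalisation shifts the frequency estimate by < 1/expected", {
  set.seed(31)
  for (i in 1:200) {
    ref <- rpois(1, 40); alt <- rpois(1, 15)
    if (ref + alt == 0) next
    nm <- normalize_counts(ref, alt, 30)
    f0 <- alt / (ref + alt)
    f1 <- nm$alt / (nm$ref + nm$alt)
    expect_lte(abs(f1 - f0), 1 / 30 + 1e-12)
  }
})

test_that("chi-square contrast reproduces hand-evaluated tables", {
  res <- chi2_contrast(90, 10, 50, 50)
  expect_equal(res$chi2, 200 * (90 * 50 - 10 * 50)^2 / (100 * 100 * 140 * 60))
  expect_equal(res$chi2, 38.095, tolerance = 1e-4)
  expect_equal(res$p, 6.7e-10, tolerance = 0.01)
  same <- chi2_contrast(60, 40, 60, 40)
  expect_equal(same$chi2, 0)
  expect_equal(same$p, 1)
  mono <- chi2_contrast(100, 0, 100, 0)
  expect_true(mono$monomorphic)
  expect_true(is.na(mono$chi2))
})

test_that("vectorised chi-square agrees with stats::chisq.test", {
  set.seed(32)
  for (i in 1:20) {
    m <- matrix(rpois(4, 50) + 1, 2)
    ours <- chi2_contrast(m[1, 1], m[2, 1], m[1, 2], m[2, 2])
    ref <- stats::chisq.test(m, correct = FALSE)
    expect_equal(ours$chi2, unname(ref$statistic), tolerance = 1e-12)
    expect_equal(ours$p, ref$p.value, tolerance = 1e-12)
  }
})

test_that("Nei F_ST matches direct formula evaluation and edge cases", {
  expect_equal(pool_fst(c(0.2, 0.8)), 0.36)
  expect_equal(pool_fst(c(0.3, 0.3, 0.3)), 0)
  expect_equal(pool_fst(c(0, 1)), 1)
  expect_equal(pool_fst(c(0, 0)), 0)  # H_T = 0 convention
})

test_that("F_ST equals the variance identity 2 Var(p) / H_T", {
  set.seed(33)
  for (i in 1:50) {
    p <- runif(8)
    pbar <- mean(p)
    ht <- 2 * pbar * (1 - pbar)
    vp <- mean((p - pbar)^2)
    expect_equal(pool_fst(p), 2 * vp / ht, tolerance = 1e-12)
  }
})

test_that("F_ST distribution summary behaves on degenerate inputs", {
  one <- fst_distribution(0.25)
  expect_equal(one$mean, 0.25)
  expect_equal(one$median, 0.25)
  expect_equal(fst_distribution(rep(0, 10))$mean, 0)
  expect_error(fst_distribution(numeric(0)), "no F_ST")
})

test_that("inflation factor is calibrated on null and elevated on mixtures", {
  set.seed(34)
  expect_equal(inflation_factor(runif(1e4)), 1, tolerance = 0.05)
  expect_equal(inflation_factor(rep(0.5, 200)), 1, tolerance = 1e-12)
  mix <- c(runif(9500), pchisq(rchisq(500, 1, ncp = 30), 1, lower.tail = FALSE))
  expect_gt(inflation_factor(mix), 1)
})

test_that("Bonferroni thresholds reproduce the worked examples", {
  expect_equal(signif(bonferroni_threshold(10195), 2), 4.9e-6)
  expect_equal(bonferroni_threshold(1), 0.05)
  expect_equal(bonferroni_threshold(1e6), 5e-8)
  expect_equal(unname(stringent_cutoffs["scan"]), 1e-10)
  expect_equal(unname(stringent_cutoffs["cluster"]), 1e-20)
})

test_that("the scan flags monomorphic SNPs and orients groups stably", {
  sim <- small_block_sim()
  sc <- suppressMessages(scan_contrast(sim$counts, sim$pops, "superpool"))
  expect_true(all(sc$p[!sc$monomorphic] > 0 & sc$p[!sc$monomorphic] <= 1))
  expect_true(all(sc$daf >= 0 & sc$daf <= 1, na.rm = TRUE))
  expect_true(all(sc$fst >= 0 & sc$fst <= 1, na.rm = TRUE))
  expect_equal(unname(attr(sc, "groups")), c("groupA", "groupB"))
})

test_that("default pool sizes leave residual overdispersion (lambda > 1)", {
  # chromosome sampling on top of read sampling inflates the chi-square
  # even without differentiation; with realistic 47-100 fish pools the
  # scan's inflation factor sits above 1
  sim <- neutral_sim()
  sc <- suppressMessages(scan_contrast(sim$counts, sim$pops, "superpool"))
  maf <- pmin((sc$p_A + sc$p_B) / 2, 1 - (sc$p_A + sc$p_B) / 2)
  lam <- inflation_factor(sc$p[!sc$monomorphic & maf >= 0.05])
  expect_gt(lam, 1)
})
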
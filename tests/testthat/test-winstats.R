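test_that("pooled heterozygosity matches the direct formula", {
  expect_equal(pooled_heterozygosity(30, 10), 2 * 30 * 10 / 40^2)
  expect_equal(pooled_heterozygosity(c(30, 20), c(10, 20)),
               2 * 50 * 30 / 80^2)
  expect_equal(pooled_heterozygosity(c(12, 40), c(0, 0)), 0)
  expect_true(is.na(pooled_heterozygosity(numeric(0), numeric(0))))
  # label-swap invariance
  set.seed(61)
  a <- rpois(5, 30); b <- rpois(5, 10)
  expect_equal(pooled_heterozygosity(a, b), pooled_heterozygosity(b, a))
  expect_lte(pooled_heterozygosity(a, b), 0.5)
})

test_that("windowed H_p drops in a region swept to near-fixation", {
  sim <- small_block_sim()
  hp <- hp_windows(sim$counts, window_size = 5000)
  expect_true(all(hp$end - hp$start == 4999))
  vals <- as.matrix(hp[, sim$counts$pools])
  expect_true(all(vals <= 0.5 + 1e-12, na.rm = TRUE))
})

test_that("Tajima's D is exactly zero when pi equals Watterson's estimator", {
  # n = 4: a1 = 11/6; 8 singletons + 3 doubletons give pi = S/a1 = 6
  counts <- c(rep(1, 8), rep(2, 3))
  expect_equal(tajimas_d(counts, 4), 0)
  expect_true(is.na(tajimas_d(integer(0), 10)))
})

test_that("pi from derived counts is an unbiased estimator of theta", {
  set.seed(62)
  theta <- 5
  wins <- simulate_coalescent_windows(20, 1000, theta = theta)
  pis <- vapply(wins, function(z)
    sum(2 * z * (20 - z)) / (20 * 19), numeric(1))
  expect_equal(mean(pis), theta, tolerance = 0.05)
})

test_that("region diversity separates fixed differences from identity", {
  snps <- data.frame(chrom = "s1", pos = seq(10, 1000, by = 10),
                     ref = "A", alt = "C")
  n_snp <- nrow(snps)
  # population A all reference, population B all alternate
  geno <- rbind(matrix(0L, 4, n_snp), matrix(2L, 4, n_snp))
  g <- genotype_matrix(geno, snps, pool = rep(c("pa", "pb"), each = 4))
  reg <- data.frame(chrom = "s1", start = 1, end = 1000, set = "x")
  div <- diversity_regions(g, "pa", "pb", reg)
  expect_equal(div$pi_A, 0)
  expect_equal(div$pi_B, 0)
  expect_equal(div$pi_between, n_snp / 1000)
  # identical haplotypes everywhere
  g0 <- genotype_matrix(matrix(0L, 8, n_snp), snps,
                        pool = rep(c("pa", "pb"), each = 4))
  div0 <- diversity_regions(g0, "pa", "pb", reg)
  expect_equal(div0$pi_between, 0)
  # empty region is missing, not zero
  reg2 <- data.frame(chrom = "s2", start = 1, end = 1000, set = "x")
  expect_true(is.na(diversity_regions(g, "pa", "pb", reg2)$pi_A))
})

test_that("haplotype blocks carry excess diversity within and between", {
  sim <- small_block_sim()
  truth <- sim$truth[1, ]
  reg <- data.frame(chrom = "scaffold1",
                    start = c(truth$start, 6e5), end = c(truth$end, 7e5),
                    set = c("differentiated", "control"))
  gp <- unique(sim$genotypes$pool)
  div <- diversity_regions(sim$genotypes, gp[1], gp[2], reg)
  expect_gt(div$pi_A[1], div$pi_A[2])
  expect_gt(div$pi_between[1], div$pi_between[2])
  expect_gte(div$pi_between[1], (div$pi_A[1] + div$pi_B[1]) / 2)
})

test_that("LD decays with distance and duplicated sites give r2 = 1", {
  snps <- data.frame(chrom = "s1", pos = c(100L, 100L, 5000L),
                     ref = "A", alt = "C")
  set.seed(63)
  col1 <- rbinom(20, 2, 0.5)
  geno <- cbind(col1, col1, rbinom(20, 2, 0.5))
  # duplicated column at distance zero
  snps_ok <- data.frame(chrom = "s1", pos = c(100L, 101L, 5000L),
                        ref = "A", alt = "C")
  g <- genotype_matrix(geno, snps_ok)
  ld <- ld_decay(g, max_dist = 1e4, bin_width = 1000)
  expect_equal(ld$mean_r2[1], 1, tolerance = 1e-9)
  # independent SNPs: E[r2] is about 1/n
  n_ind <- 40
  geno2 <- matrix(rbinom(n_ind * 200, 2, 0.4), n_ind)
  snps2 <- data.frame(chrom = "s1", pos = seq_len(200) * 50L,
                      ref = "A", alt = "C")
  ld2 <- ld_decay(genotype_matrix(geno2, snps2), max_dist = 1e4,
                  bin_width = 1e4)
  expect_equal(weighted.mean(ld2$mean_r2, ld2$n_pairs), 1 / n_ind,
               tolerance = 0.2)
})

test_that("LD inside a haplotype block dwarfs the background", {
  sim <- small_block_sim()
  g <- sim$genotypes
  inb <- in_intervals(g$snps, sim$truth)
  set.seed(64)
  idx_in <- sample(which(inb), 40)
  idx_out <- sample(which(!inb), 40)
  ld_in <- ld_decay(genotype_matrix(g$geno[, idx_in], g$snps[idx_in, ]),
                    max_dist = 2e5, bin_width = 2e5)
  ld_out <- ld_decay(genotype_matrix(g$geno[, idx_out], g$snps[idx_out, ]),
                     max_dist = 1e6, bin_width = 1e6)
  expect_gt(weighted.mean(ld_in$mean_r2, ld_in$n_pairs),
            5 * weighted.mean(ld_out$mean_r2, ld_out$n_pairs))
})

test_that("heterozygosity rate converts to percent diversity", {
  expect_equal(round(het_rate(1, 309)$percent, 2), 0.32)
  expect_equal(het_rate(0, 1e6)$percent, 0)
  expect_equal(het_rate(3236, 1e6)$percent, 0.3236)
  expect_error(het_rate(10, 0), "> 0")
})
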
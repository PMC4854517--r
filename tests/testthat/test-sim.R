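test_that("identical seeds reproduce identical datasets", {
  cfg <- sim_config(n_scaffolds = 1, scaffold_length = 2e5, n_pops = 4,
                    snp_spacing_bp = 300, n_geno_per_pool = 3, seed = 7)
  a <- simulate_metapopulation(cfg)
  b <- simulate_metapopulation(cfg)
  expect_identical(a$counts, b$counts)
  expect_identical(a$genotypes$geno, b$genotypes$geno)
  expect_identical(simulate_depth(cfg)$depth, simulate_depth(cfg)$depth)
})

test_that("no structure is injected at baseline F_ST zero", {
  cfg <- sim_config(n_scaffolds = 1, scaffold_length = 5e5, n_pops = 6,
                    baseline_fst = 0, snp_spacing_bp = 150,
                    n_geno_per_pool = 2, seed = 8)
  sim <- simulate_metapopulation(cfg)
  # true per-pool frequencies are exactly equal, so truth-level F_ST is 0
  expect_equal(max(pool_fst(sim$freqs)), 0)
  sc <- suppressMessages(scan_contrast(sim$counts, sim$pops, "superpool"))
  expect_lt(mean(sc$daf[!sc$monomorphic]), 0.1)
})

test_that("an injected block realises its target dAF within 0.05", {
  blocks <- data.frame(chrom = "scaffold1", start = 2e5, end = 3.5e5,
                       type = "salinity", target_daf = 0.8)
  cfg <- sim_config(n_scaffolds = 1, scaffold_length = 1e6, n_pops = 10,
                    blocks = blocks, snp_spacing_bp = 300,
                    n_geno_per_pool = 2, seed = 9)
  sim <- simulate_metapopulation(cfg)
  sc <- suppressMessages(scan_contrast(sim$counts, sim$pops, "superpool"))
  inb <- in_intervals(sc[, c("chrom", "pos")], sim$truth)
  expect_equal(mean(sc$daf[inb]), 0.8, tolerance = 0.05 / 0.8)
  expect_lt(mean(sc$daf[!inb & !sc$monomorphic]), 0.15)
})

test_that("constant-mode ancestral frequencies follow the folded 1/i law", {
  # high coverage so rare variants are ascertained with near certainty
  cfg <- sim_config(n_scaffolds = 2, scaffold_length = 1e6, n_pops = 4,
                    baseline_fst = 0, sfs_mode = "constant",
                    snp_spacing_bp = 50, n_chrom_sfs = 40,
                    mean_coverage = 200, n_geno_per_pool = 2, seed = 10)
  sim <- simulate_metapopulation(cfg)
  # truth frequencies (ascertainment-free): folded counts out of n_chrom
  i <- round(sim$freqs[, 1] * 40)
  folded <- tabulate(pmin(i, 40 - i), 20)
  gof <- stats::chisq.test(folded, p = expected_sfs(40, folded = TRUE))
  expect_gt(gof$p.value, 0.01)
})

test_that("neutral truth-level F_ST converges to the configured baseline", {
  sim <- neutral_sim()
  f <- pool_fst(sim$freqs)
  pbar <- rowMeans(sim$freqs)
  maf <- pmin(pbar, 1 - pbar)
  m <- mean(f[maf >= 0.01])
  expect_equal(m, 0.038, tolerance = 0.10)
})

test_that("truth table records every injected feature at its coordinates", {
  blocks <- make_blocks(4, 2, 1e6, 0.5, 0.7, seed = 21)
  cnvs <- data.frame(chrom = "scaffold1", start = 9e5, end = 9.05e5,
                     group = "groupB", fold = 2)
  cfg <- sim_config(n_scaffolds = 2, scaffold_length = 1e6, n_pops = 4,
                    blocks = blocks, cnvs = cnvs, snp_spacing_bp = 500,
                    n_geno_per_pool = 2, seed = 11)
  sim <- simulate_metapopulation(cfg)
  expect_equal(nrow(sim$truth), 5)
  expect_equal(sim$truth$start[1:4], blocks$start)
  expect_equal(sim$truth$effect[5], 2)
  expect_true(all(sim$truth$type[1:4] == "salinity"))
})

test_that("invalid configurations are rejected", {
  bad_blocks <- data.frame(chrom = "scaffold1", start = c(100, 500),
                           end = c(1000, 2000), type = "salinity",
                           target_daf = 0.5)
  expect_error(sim_config(blocks = bad_blocks), "overlapping")
  expect_error(sim_config(cnvs = data.frame(chrom = "scaffold1", start = 1,
                                            end = 10, group = "groupA",
                                            fold = -1)), "negative")
  expect_error(sim_config(category_props = c(intronic = 1.2)), "sum")
  cfg <- sim_config(seed = 1, n_geno_per_pool = 2)
  cfg$pools$n_fish[1] <- 0
  expect_error(simulate_metapopulation(cfg), "pool size")
})

test_that("unreachable target dAF is clamped with a warning", {
  blocks <- data.frame(chrom = "scaffold1", start = 1e5, end = 1.5e5,
                       type = "salinity", target_daf = 0.99)
  cfg <- sim_config(n_scaffolds = 1, scaffold_length = 5e5, n_pops = 4,
                    blocks = blocks, snp_spacing_bp = 400,
                    n_geno_per_pool = 2, seed = 12)
  expect_warning(simulate_metapopulation(cfg), "clamped")
})

test_that("depth simulation realises CNV fold changes on the right group", {
  cnvs <- data.frame(chrom = "scaffold1", start = 50001, end = 55000,
                     group = "groupB", fold = 2)
  cfg <- sim_config(n_scaffolds = 1, scaffold_length = 1e6, n_pops = 10,
                    cnvs = cnvs, n_geno_per_pool = 2, seed = 13)
  dm <- normalize_depth(simulate_depth(cfg))
  inw <- dm$windows$start >= 50001 & dm$windows$end <= 55000
  gB <- cfg$pools$superpool == "groupB"
  lr <- log2(mean(dm$depth[inw, gB]) / mean(dm$depth[inw, !gB]))
  expect_equal(lr, 1, tolerance = 0.1)
  lr0 <- log2(mean(dm$depth[!inw, gB]) / mean(dm$depth[!inw, !gB]))
  expect_lt(abs(lr0), 0.05)
})

test_that("simulated files round-trip through the readers without loss", {
  sim <- small_block_sim()
  dir <- withr::local_tempdir()
  sub <- sim$counts[1:300, ]
  write_sync(sub, file.path(dir, "counts.sync"))
  rt <- read_sync(file.path(dir, "counts.sync"), pools = sub$pools)
  expect_equal(rt$snps, sub$snps, ignore_attr = TRUE)
  expect_equal(rt$ref, sub$ref)
  expect_equal(rt$alt, sub$alt)
  write_metadata(sim$pops, file.path(dir, "meta.tsv"))
  expect_equal(read_metadata(file.path(dir, "meta.tsv")), sim$pops,
               ignore_attr = TRUE)
  dm <- simulate_depth(sim$config)
  write_depth_matrix(dm, file.path(dir, "depth.tsv"))
  dm2 <- read_depth_matrix(file.path(dir, "depth.tsv"))
  expect_equal(dm2$depth, dm$depth, tolerance = 1e-12)
  expect_equal(dm2$mappability, dm$mappability)
  write_bed(sim$truth, file.path(dir, "truth.bed"))
  tb <- read_bed_intervals(file.path(dir, "truth.bed"))
  expect_equal(tb$start, sim$truth$start)
  expect_equal(tb$end, sim$truth$end)
})
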
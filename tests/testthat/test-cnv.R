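make_depth <- function(n_win = 50, pools = 6, seed = 91) {
  set.seed(seed)
  win <- data.frame(chrom = "s1", start = (seq_len(n_win) - 1L) * 1000L + 1L,
                    end = seq_len(n_win) * 1000L)
  D <- matrix(rnorm(n_win * pools, mean = rep(c(40, 30, 20, 35, 25, 30),
                                              each = n_win)[seq_len(n_win * pools)],
                    sd = 2), n_win, pools,
              dimnames = list(NULL, sprintf("p%d", seq_len(pools))))
  depth_matrix(win, abs(D))
}

test_that("depth normalisation equalises pool means and is idempotent", {
  dm <- make_depth()
  nm <- normalize_depth(dm)
  expect_equal(attr(nm, "reference_pool"), "p1")  # highest mean
  means <- colMeans(nm$depth)
  expect_equal(unname(means), rep(means[["p1"]], 6), tolerance = 1e-12)
  expect_equal(nm$depth[, "p1"], dm$depth[, "p1"])  # reference unchanged
  nm2 <- normalize_depth(nm, "p1")
  expect_equal(nm2$depth, nm$depth, tolerance = 1e-12)
  # a pool at half the reference mean doubles
  dm2 <- dm; dm2$depth[, 2] <- dm$depth[, 1] / 2
  nm3 <- normalize_depth(dm2, "p1")
  expect_equal(nm3$depth[, 2], dm$depth[, 1], tolerance = 1e-12)
  dm3 <- dm; dm3$depth[, 3] <- 0
  expect_error(normalize_depth(dm3), "zero mean")
})

test_that("window ANOVA reproduces the hand example and the aov oracle", {
  win <- data.frame(chrom = "s1", start = 1L, end = 1000L)
  D <- matrix(c(1.0, 1.05, 0.95, 2.0, 2.1, 1.9), 1,
              dimnames = list(NULL, sprintf("p%d", 1:6)))
  dm <- depth_matrix(win, D)
  res <- suppressMessages(window_anova(dm, rep(c("A", "B"), each = 3),
                                       low_floor = 0))
  expect_equal(res$M, 1, tolerance = 0.01)
  expect_lt(res$p, 0.001)
  oracle <- summary(stats::aov(depth ~ grp,
                               data = data.frame(depth = D[1, ],
                                                 grp = rep(c("A", "B"),
                                                           each = 3))))[[1]]
  expect_equal(res$F, oracle[["F value"]][1], tolerance = 1e-10)
  expect_equal(res$p, oracle[["Pr(>F)"]][1], tolerance = 1e-10)
  # identical depths: F = 0, p = 1
  D0 <- matrix(rep(2, 6), 1, dimnames = list(NULL, sprintf("p%d", 1:6)))
  res0 <- suppressMessages(window_anova(depth_matrix(win, D0),
                                        rep(c("A", "B"), each = 3),
                                        low_floor = 0))
  expect_equal(res0$F, 0)
  expect_equal(res0$p, 1)
})

test_that("low-depth windows are excluded before testing", {
  dm <- make_depth(n_win = 20)
  dm$depth[3, ] <- 0.1
  expect_message(res <- window_anova(dm, rep(c("A", "B"), each = 3)),
                 "1 window")
  expect_equal(nrow(res), 19)
})

test_that("significant windows merge across gaps of at most one window", {
  ws <- data.frame(chrom = "s1", start = (0:9) * 1000L + 1L,
                   end = (1:10) * 1000L, mean_A = 1, mean_B = 2,
                   M = 1, F = 50, p = 1, mappability = 1)
  ws$p <- 1
  ws$p[c(3, 4)] <- 1e-5          # adjacent -> one 2-kb region
  out <- call_cnv_regions(ws)
  expect_equal(nrow(out), 1)
  expect_equal(out$end - out$start + 1, 2000)
  ws$p <- 1; ws$p[c(2, 4)] <- 1e-5   # one intervening window -> still one
  expect_equal(nrow(call_cnv_regions(ws)), 1)
  ws$p <- 1; ws$p[c(2, 6)] <- 1e-5   # three intervening -> two regions
  expect_equal(nrow(call_cnv_regions(ws)), 2)
})

test_that("low-mappability regions are flagged, not deleted", {
  ws <- data.frame(chrom = "s1", start = c(1L, 1001L), end = c(1000L, 2000L),
                   mean_A = 1, mean_B = 2, M = 1, F = 50, p = 1e-5,
                   mappability = c(0.2, 0.3))
  out <- call_cnv_regions(ws)
  expect_equal(nrow(out), 1)
  expect_true(out$low_mappability)
})

test_that("call counts shrink monotonically with stricter cutoffs", {
  dm <- make_depth(n_win = 400, seed = 92)
  nm <- normalize_depth(dm)
  nm$depth[101:110, 4:6] <- nm$depth[101:110, 4:6] * 1.9
  ws <- suppressMessages(window_anova(nm, rep(c("A", "B"), each = 3)))
  n1 <- nrow(call_cnv_regions(ws, p_cut = 0.01, m_cut = 0.3))
  n2 <- nrow(call_cnv_regions(ws, p_cut = 0.001, m_cut = 0.3))
  n3 <- nrow(call_cnv_regions(ws, p_cut = 0.001, m_cut = 0.6))
  expect_lte(n2, n1)
  expect_lte(n3, n2)
})

test_that("an injected 5-kb CNV is recovered with reciprocal overlap >= 80%", {
  cnvs <- data.frame(chrom = "scaffold1", start = 120001, end = 125000,
                     group = "groupB", fold = 2)
  cfg <- sim_config(n_scaffolds = 1, scaffold_length = 1e6, n_pops = 10,
                    cnvs = cnvs, n_geno_per_pool = 2, seed = 93)
  dm <- normalize_depth(simulate_depth(cfg))
  ws <- suppressMessages(window_anova(dm, cfg$pools$superpool))
  calls <- call_cnv_regions(ws)
  expect_equal(nrow(calls), 1)
  ov <- min(calls$end[1], 125000) - max(calls$start[1], 120001) + 1
  expect_gte(ov / 5000, 0.8)
  expect_gte(ov / (calls$end[1] - calls$start[1] + 1), 0.8)
  expect_equal(calls$M[1], 1, tolerance = 0.2)
})

test_that("the generator null yields the nominal false-positive window rate", {
  cfg <- sim_config(n_scaffolds = 2, scaffold_length = 5e6, n_pops = 20,
                    n_geno_per_pool = 2, seed = 94)
  dm <- normalize_depth(simulate_depth(cfg))
  ws <- suppressMessages(window_anova(dm, cfg$pools$superpool))
  p_cut <- 0.01
  fp <- sum(ws$p < p_cut)
  expected <- p_cut * nrow(ws)
  expect_lt(abs(fp - expected), 3 * sqrt(expected) + 1)
})
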
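#' Coverage filter for pooled counts
#'
#' Retains SNPs whose total read count lies inside `[low, high]` in every
#' pool.  Extreme coverage marks regions that are hard to sequence (low)
#' or oversampled, e.g. collapsed duplications (high), which inflate
#' differentiation statistics.
#'
#' @param counts a [pool_counts()] object.
#' @param low,high inclusive per-pool coverage bounds in reads.
#' @return the filtered [pool_counts()]; the number of removed SNPs is
#'   reported via `message()`, and an empty result triggers a warning.
#' @export
filter_by_coverage <- function(counts, low = 30, high = 50) {
  stopifnot(inherits(counts, "pool_counts"), low < high)
  tot <- counts$ref + counts$alt
  keep <- rowSums(tot < low | tot > high) == 0L
  message(sum(!keep), " SNP(s) removed by the ", low, "-", high,
          "x coverage filter")
  if (!any(keep)) warning("coverage filter removed every SNP")
  counts[keep, ]
}

round_half_away <- function(x) sign(x) * floor(abs(x) + 0.5)

#' Downscale read counts at over-covered positions
#'
#' Positions covered above the genome-wide expected coverage have their
#' counts scaled down to the expected total, which controls the
#' inflation of chi-square p-values at high-coverage positions.  The
#' minor allele count is scaled and rounded half away from zero (keeping
#' at least one read for any allele observed at least once) and the
#' major allele takes the remainder, so the site total equals the
#' expected coverage.  Counts are never scaled up.
#'
#' @param ref,alt numeric vectors (or matrices) of read counts.
#' @param expected_cov genome-wide expected coverage in reads.
#' @return list with components `ref` and `alt`, same shape as input.
#' @examples
#' normalize_counts(40, 20, 30)   # -> 20, 10
#' normalize_counts(99, 1, 30)    # -> 29, 1  (minor allele preserved)
#' @export
normalize_counts <- function(ref, alt, expected_cov) {
  stopifnot(expected_cov > 0)
  tot <- ref + alt
  scale <- tot > expected_cov
  f <- ifelse(scale, expected_cov / tot, 1)
  mnr <- pmin(ref, alt)
  m2 <- round_half_away(mnr * f)
  m2 <- ifelse(mnr >= 1, pmax(m2, 1), m2)
  M2 <- round_half_away(expected_cov) - m2
  minor_is_alt <- alt <= ref
  r <- ifelse(scale, ifelse(minor_is_alt, M2, m2), ref)
  a <- ifelse(scale, ifelse(minor_is_alt, m2, M2), alt)
  out_r <- ref; out_r[] <- r
  out_a <- alt; out_a[] <- a
  list(ref = out_r, alt = out_a)
}

#' Chi-square allele-frequency contrast between two superpools
#'
#' Pearson chi-square on the 2 x 2 table of reference/alternate read
#' counts by superpool, 1 degree of freedom, no continuity correction.
#' SNPs monomorphic across the union of the two superpools have no
#' defined statistic and are flagged (`NA` statistic and p-value).
#'
#' @param a_ref,a_alt,b_ref,b_alt read counts (vectors) for superpools A
#'   and B; per-pool counts should be normalised and summed first (see
#'   [scan_contrast()]).
#' @return data frame with `chi2`, `p` and logical `monomorphic`.
#' @examples
#' chi2_contrast(90, 10, 50, 50)  # chi2 ~ 38.1
#' @export
chi2_contrast <- function(a_ref, a_alt, b_ref, b_alt) {
  nA <- a_ref + a_alt; nB <- b_ref + b_alt
  stopifnot(all(nA > 0), all(nB > 0))
  N <- nA + nB
  alt_tot <- a_alt + b_alt
  mono <- alt_tot == 0 | alt_tot == N
  chi2 <- N * (a_ref * b_alt - a_alt * b_ref)^2 /
    (nA * nB * (a_ref + b_ref) * alt_tot)
  chi2[mono] <- NA_real_
  p <- stats::pchisq(chi2, df = 1, lower.tail = FALSE)
  data.frame(chi2 = chi2, p = p, monomorphic = mono)
}

#' Per-SNP F_ST from pool allele frequencies
#'
#' Nei's form F_ST = (H_T - H_S) / H_T with H_T = 2 p-bar q-bar and
#' H_S the average of per-pool 2 p q; non-negative per SNP, and 0 by
#' convention when H_T = 0.
#'
#' @param freqs numeric vector (one SNP) or matrix (SNPs x pools) of
#'   per-pool allele frequencies.
#' @param weights optional per-pool weights (default equal).
#' @return numeric vector of F_ST values in `[0, 1]`.
#' @examples
#' pool_fst(c(0.2, 0.8))  # 0.36
#' @export
pool_fst <- function(freqs, weights = NULL) {
  if (is.vector(freqs)) freqs <- matrix(freqs, nrow = 1)
  k <- ncol(freqs)
  stopifnot(k >= 2)
  if (is.null(weights)) weights <- rep(1 / k, k)
  weights <- weights / sum(weights)
  pbar <- drop(freqs %*% weights)
  ht <- 2 * pbar * (1 - pbar)
  hs <- drop((2 * freqs * (1 - freqs)) %*% weights)
  fst <- ifelse(ht > 0, (ht - hs) / ht, 0)
  pmin(pmax(fst, 0), 1)
}

#' Summary of the per-SNP F_ST distribution
#'
#' @param fst numeric vector of per-SNP F_ST values (coverage-filtered).
#' @param breaks histogram breaks passed to [hist()].
#' @return list with `mean`, `median`, `n` and `histogram`.
#' @export
fst_distribution <- function(fst, breaks = seq(0, 1, by = 0.01)) {
  fst <- fst[!is.na(fst)]
  if (length(fst) == 0) stop("no F_ST values")
  list(mean = mean(fst), median = stats::median(fst), n = length(fst),
       histogram = graphics::hist(fst, breaks = breaks, plot = FALSE))
}

#' Genomic-control inflation factor
#'
#' lambda = median of the chi-square(1) quantiles of the observed
#' p-values divided by the null median 0.4549.  Values slightly above 1
#' are expected when average differentiation among pools is not zero.
#'
#' @param pvals numeric vector of p-values (>= 100 of them).
#' @return the inflation factor lambda.
#' @export
inflation_factor <- function(pvals) {
  pvals <- pvals[!is.na(pvals)]
  stopifnot(length(pvals) >= 100)
  stats::median(stats::qchisq(pvals, df = 1, lower.tail = FALSE)) /
    stats::qchisq(0.5, df = 1)
}

#' Bonferroni-corrected significance threshold
#'
#' @param n_tests number of tests.
#' @param alpha family-wise error rate.
#' @return `alpha / n_tests`.
#' @examples
#' bonferroni_threshold(10195)  # 4.9e-6
#' @export
bonferroni_threshold <- function(n_tests, alpha = 0.05) {
  stopifnot(n_tests >= 1, alpha > 0, alpha < 1)
  alpha / n_tests
}

#' Stringent fixed significance cutoffs used alongside Bonferroni
#'
#' Named constants: `scan` (per-SNP differentiation scan) and `cluster`
#' (SNP inclusion when counting independent loci).
#' @export
stringent_cutoffs <- c(scan = 1e-10, cluster = 1e-20)

#' Per-SNP differentiation scan between two superpools
#'
#' The full scan stage: per-pool counts are normalised against the
#' expected coverage, summed within each superpool, and tested with the
#' 2 x 2 chi-square; pooled allele frequencies, |dAF| and Nei F_ST
#' across pools are reported per SNP.
#'
#' @param counts a [pool_counts()] object (coverage-filtered).
#' @param pops the pool metadata table (see [read_metadata()]).
#' @param contrast `"superpool"` (marine vs brackish labels in the
#'   `superpool` column) or `"season"` (spring vs autumn; summer and
#'   unknown pools are dropped).
#' @param expected_cov expected per-pool coverage used by
#'   [normalize_counts()]; `NULL` uses the genome-wide mean coverage.
#' @return a data frame of class `poolscan_scan`: `chrom`, `pos`,
#'   `p_A`, `p_B`, `daf`, `chi2`, `p`, `fst`, `monomorphic`.
#' @export
scan_contrast <- function(counts, pops, contrast = c("superpool", "season"),
                          expected_cov = NULL) {
  stopifnot(inherits(counts, "pool_counts"))
  contrast <- match.arg(contrast)
  validate_pop_table(pops)
  pops <- pops[match(counts$pools, pops$pool), ]
  if (anyNA(pops$pool)) stop("pool metadata missing for some count columns")
  grp <- if (contrast == "superpool") pops$superpool else pops$season
  if (contrast == "season") {
    keep_pool <- grp %in% c("spring", "autumn")
    counts <- counts[, keep_pool]
    grp <- grp[keep_pool]
  }
  lev <- sort(unique(grp))
  if (length(lev) != 2) stop("contrast needs exactly two groups, got: ",
                             paste(lev, collapse = ", "))
  if (is.null(expected_cov))
    expected_cov <- mean(counts$ref + counts$alt)
  nm <- normalize_counts(counts$ref, counts$alt, expected_cov)
  n_over <- sum(counts$ref + counts$alt > expected_cov)
  message(sprintf("%d of %d pool-site counts exceeded expected coverage %.1f and were normalised",
                  n_over, length(counts$ref), expected_cov))
  A <- grp == lev[1]
  a_ref <- rowSums(nm$ref[, A, drop = FALSE])
  a_alt <- rowSums(nm$alt[, A, drop = FALSE])
  b_ref <- rowSums(nm$ref[, !A, drop = FALSE])
  b_alt <- rowSums(nm$alt[, !A, drop = FALSE])
  chi <- chi2_contrast(a_ref, a_alt, b_ref, b_alt)
  p_A <- a_alt / (a_ref + a_alt)
  p_B <- b_alt / (b_ref + b_alt)
  tot <- counts$ref + counts$alt
  pf <- counts$alt / ifelse(tot > 0, tot, NA)
  fst <- pool_fst(pf)
  out <- data.frame(chrom = counts$snps$chrom, pos = counts$snps$pos,
                    p_A = p_A, p_B = p_B, daf = abs(p_A - p_B),
                    chi2 = chi$chi2, p = chi$p, fst = fst,
                    monomorphic = chi$monomorphic,
                    stringsAsFactors = FALSE)
  attr(out, "groups") <- stats::setNames(lev, c("A", "B"))
  attr(out, "contrast") <- contrast
  class(out) <- c("poolscan_scan", "data.frame")
  out
}

#' @export
print.poolscan_scan <- function(x, ...) {
  g <- attr(x, "groups")
  cat(sprintf("Superpool differentiation scan (%s): %s vs %s, %d SNPs\n",
              attr(x, "contrast"), g[1], g[2], nrow(x)))
  ok <- !x$monomorphic
  cat(sprintf("  tested: %d; median chi2 p %.3g; mean F_ST %.4f; mean |dAF| %.3f\n",
              sum(ok), stats::median(x$p[ok]), mean(x$fst, na.rm = TRUE),
              mean(x$daf[ok])))
  cat(sprintf("  p < 1e-10: %d SNPs; Bonferroni threshold %.3g\n",
              sum(x$p < 1e-10, na.rm = TRUE), 0.05 / sum(ok)))
  invisible(x)
}
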
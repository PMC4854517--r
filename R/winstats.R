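#' Pooled heterozygosity of one window
#'
#' H_p = 2 * (sum of major read counts) * (sum of minor read counts) /
#' (sum of all counts)^2, with the sums taken over the SNPs of the
#' window before the product.  Bounded by 0.5; invariant to swapping the
#' major/minor labels.
#'
#' @param major,minor per-SNP major and minor allele read counts of the
#'   window (orientation does not matter).
#' @return H_p, or `NA` for an empty window.
#' @examples
#' pooled_heterozygosity(30, 10)            # 0.375
#' pooled_heterozygosity(c(30, 20), c(10, 20))  # ~0.469
#' @export
pooled_heterozygosity <- function(major, minor) {
  if (length(major) == 0) return(NA_real_)
  smaj <- sum(major); smin <- sum(minor)
  2 * smaj * smin / (smaj + smin)^2
}

#' Pooled heterozygosity in fixed windows per pool
#'
#' @param counts a [pool_counts()] object.
#' @param window_size window width in bp (left-aligned, non-sliding;
#'   default 5 kb).
#' @return data frame `chrom`, `start`, `end` plus one H_p column per
#'   pool; windows with no SNPs are `NA`.
#' @export
hp_windows <- function(counts, window_size = 5000) {
  stopifnot(inherits(counts, "pool_counts"))
  snps <- counts$snps
  win_id <- paste(snps$chrom, (snps$pos - 1L) %/% window_size)
  keys <- unique(win_id)
  maj <- pmax(counts$ref, counts$alt)
  mnr <- pmin(counts$ref, counts$alt)
  hp <- matrix(NA_real_, length(keys), length(counts$pools),
               dimnames = list(NULL, counts$pools))
  idx <- split(seq_len(nrow(snps)), factor(win_id, levels = keys))
  for (k in seq_along(keys)) {
    i <- idx[[k]]
    for (j in seq_along(counts$pools))
      hp[k, j] <- pooled_heterozygosity(maj[i, j], mnr[i, j])
  }
  first <- vapply(idx, `[`, integer(1), 1L)
  wstart <- ((snps$pos[first] - 1L) %/% window_size) * window_size + 1L
  data.frame(chrom = snps$chrom[first], start = wstart,
             end = wstart + window_size - 1L, hp,
             check.names = FALSE, stringsAsFactors = FALSE)
}

#' Tajima's D from derived-allele counts
#'
#' Standard normalised difference between mean pairwise diversity and
#' Watterson's estimator, D = (pi - S/a1) / sqrt(e1 S + e2 S (S - 1)),
#' with the usual a1, a2, b1, b2, c1, c2, e1, e2 constants for a sample
#' of `n` chromosomes.  Undefined (NA) when there are no segregating
#' sites.
#'
#' @param counts derived (or minor) allele counts of the window's
#'   segregating sites, each in `1..n-1`.
#' @param n number of chromosomes sampled.
#' @return Tajima's D.
#' @export
tajimas_d <- function(counts, n) {
  stopifnot(n >= 4)
  counts <- counts[counts > 0 & counts < n]
  S <- length(counts)
  if (S == 0) return(NA_real_)
  ppi <- sum(2 * counts * (n - counts)) / (n * (n - 1))
  i <- seq_len(n - 1)
  a1 <- sum(1 / i); a2 <- sum(1 / i^2)
  b1 <- (n + 1) / (3 * (n - 1))
  b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1
  c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
  e1 <- c1 / a1
  e2 <- c2 / (a1^2 + a2)
  (ppi - S / a1) / sqrt(e1 * S + e2 * S * (S - 1))
}

#' Tajima's D in fixed windows from a genotype matrix
#'
#' Allele counts are taken over the 2N chromosomes of the genotyped
#' individuals (sites with missing calls are dropped).
#'
#' @param g a [genotype_matrix()].
#' @param window_size window width in bp (default 10 kb).
#' @return data frame `chrom`, `start`, `end`, `S`, `D`.
#' @export
tajd_windows <- function(g, window_size = 10000) {
  stopifnot(inherits(g, "genotype_matrix"))
  n <- 2L * nrow(g$geno)
  ac <- colSums(g$geno)
  ok <- !is.na(ac)
  snps <- g$snps[ok, ]; ac <- ac[ok]
  win_id <- paste(snps$chrom, (snps$pos - 1L) %/% window_size)
  keys <- unique(win_id)
  idx <- split(seq_len(nrow(snps)), factor(win_id, levels = keys))
  D <- vapply(idx, function(i) tajimas_d(ac[i], n), numeric(1))
  S <- vapply(idx, function(i) sum(ac[i] > 0 & ac[i] < n), integer(1))
  first <- vapply(idx, `[`, integer(1), 1L)
  wstart <- ((snps$pos[first] - 1L) %/% window_size) * window_size + 1L
  data.frame(chrom = snps$chrom[first], start = wstart,
             end = wstart + window_size - 1L, S = S, D = unname(D),
             stringsAsFactors = FALSE)
}

pi_within <- function(ac, n, len) {
  # mean pairwise difference per site among n chromosomes
  sum(2 * ac * (n - ac) / (n * (n - 1))) / len
}

pi_between <- function(acA, nA, acB, nB, len) {
  pA <- acA / nA; pB <- acB / nB
  sum(pA * (1 - pB) + pB * (1 - pA)) / len
}

#' Nucleotide diversity within and between populations per region
#'
#' For each region, mean pairwise difference per site among chromosomes
#' within each population and across the two populations.  Used to
#' contrast strongly differentiated regions against non-differentiated
#' control regions: haplotype blocks maintained by selection show
#' diversity as high as or higher than neutral regions even within
#' populations, whereas a recent hard sweep would deplete it.
#'
#' @param g a [genotype_matrix()] with a `pool` assignment.
#' @param popA,popB pool ids of the two populations.
#' @param regions data frame `chrom`, `start`, `end` and a `set` column
#'   (e.g. `differentiated` / `control`).
#' @return data frame: one row per region with `pi_A`, `pi_B`,
#'   `pi_between` (per bp) and `n_snps`; regions without genotyped SNPs
#'   get `NA`.
#' @export
diversity_regions <- function(g, popA, popB, regions) {
  stopifnot(inherits(g, "genotype_matrix"), !is.null(g$pool))
  ia <- g$pool %in% popA; ib <- g$pool %in% popB
  stopifnot(sum(ia) >= 2, sum(ib) >= 2)
  nA <- 2L * sum(ia); nB <- 2L * sum(ib)
  acA_all <- colSums(g$geno[ia, , drop = FALSE])
  acB_all <- colSums(g$geno[ib, , drop = FALSE])
  out <- regions
  out$pi_A <- out$pi_B <- out$pi_between <- NA_real_
  out$n_snps <- 0L
  for (r in seq_len(nrow(regions))) {
    i <- which(g$snps$chrom == regions$chrom[r] &
                 g$snps$pos >= regions$start[r] &
                 g$snps$pos <= regions$end[r])
    i <- i[!is.na(acA_all[i]) & !is.na(acB_all[i])]
    if (length(i) == 0) next
    len <- regions$end[r] - regions$start[r] + 1
    out$n_snps[r] <- length(i)
    out$pi_A[r] <- pi_within(acA_all[i], nA, len)
    out$pi_B[r] <- pi_within(acB_all[i], nB, len)
    out$pi_between[r] <- pi_between(acA_all[i], nA, acB_all[i], nB, len)
  }
  out
}

#' Compare diversity of differentiated vs control region sets
#'
#' One-sided Mann-Whitney (Wilcoxon rank-sum) tests that diversity in
#' the differentiated set exceeds the control set, for each of the three
#' diversity columns.
#'
#' @param div a [diversity_regions()] result with a `set` column with
#'   values `differentiated` and `control`.
#' @return named vector of one-sided p-values for `pi_A`, `pi_B`,
#'   `pi_between`.
#' @export
compare_region_diversity <- function(div) {
  stopifnot("set" %in% names(div))
  vapply(c("pi_A", "pi_B", "pi_between"), function(col) {
    stats::wilcox.test(div[[col]][div$set == "differentiated"],
                       div[[col]][div$set == "control"],
                       alternative = "greater", exact = FALSE)$p.value
  }, numeric(1))
}

#' Decay of linkage disequilibrium with distance
#'
#' Composite (unphased genotype-correlation) r-squared for all SNP pairs
#' up to `max_dist` apart on the same scaffold, averaged in distance
#' bins.
#'
#' @param g a [genotype_matrix()] (>= 10 individuals).
#' @param max_dist maximum pair distance in bp.
#' @param bin_width distance bin width in bp.
#' @return data frame `dist` (bin midpoint), `mean_r2`, `n_pairs`.
#' @export
ld_decay <- function(g, max_dist = 5e4, bin_width = 100) {
  stopifnot(inherits(g, "genotype_matrix"), nrow(g$geno) >= 10)
  geno <- g$geno
  v <- apply(geno, 2, stats::var)
  poly <- which(!is.na(v) & v > 0)
  d_all <- r2_all <- numeric(0)
  for (sc in unique(g$snps$chrom)) {
    i <- poly[g$snps$chrom[poly] == sc]
    if (length(i) < 2) next
    pos <- g$snps$pos[i]
    G <- scale(geno[, i, drop = FALSE])
    R <- stats::cor(G, use = "pairwise.complete.obs")
    pr <- which(upper.tri(R), arr.ind = TRUE)
    dd <- abs(pos[pr[, 1]] - pos[pr[, 2]])
    keep <- dd <= max_dist
    d_all <- c(d_all, dd[keep])
    r2_all <- c(r2_all, R[pr][keep]^2)
  }
  if (length(d_all) == 0)
    return(data.frame(dist = numeric(0), mean_r2 = numeric(0),
                      n_pairs = integer(0)))
  bin <- pmin(d_all %/% bin_width, max_dist %/% bin_width - 1)
  agg <- tapply(r2_all, bin, mean)
  cnt <- tapply(r2_all, bin, length)
  data.frame(dist = (as.numeric(names(agg)) + 0.5) * bin_width,
             mean_r2 = as.numeric(agg), n_pairs = as.integer(cnt))
}

#' Individual heterozygosity rate and percent nucleotide diversity
#'
#' Number of heterozygous sites per callable bp, restricted by
#' convention to scaffolds of at least `min_scaffold_bp` to avoid edge
#' effects.  One heterozygous site per 309 bp corresponds to 0.32%
#' diversity.
#'
#' @param geno one individual's genotype vector (0/1/2, `NA` allowed),
#'   or a precomputed heterozygous-site count.
#' @param callable_bp callable genome length in bp (> 0).
#' @param snps optional SNP table (for scaffold-length filtering).
#' @param scaffold_lengths optional named scaffold lengths in bp.
#' @param min_scaffold_bp minimum scaffold length retained.
#' @return list with `n_het`, `rate` (per bp) and `percent`.
#' @examples
#' het_rate(3236, 1e6)$percent  # 0.3236
#' @export
het_rate <- function(geno, callable_bp, snps = NULL,
                     scaffold_lengths = NULL, min_scaffold_bp = 1e6) {
  if (callable_bp <= 0) stop("callable length must be > 0")
  if (length(geno) == 1 && is.null(snps)) {
    n_het <- geno
  } else {
    keep <- rep(TRUE, length(geno))
    if (!is.null(snps) && !is.null(scaffold_lengths))
      keep <- scaffold_lengths[snps$chrom] >= min_scaffold_bp
    n_het <- sum(geno[keep] == 1, na.rm = TRUE)
  }
  rate <- n_het / callable_bp
  list(n_het = n_het, rate = rate, percent = 100 * rate)
}
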
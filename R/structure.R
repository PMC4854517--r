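#' F_IT statistic from individual genotypes of one sample
#'
#' Per SNP, F_IT = 1 - H_obs / H_exp with H_exp = 2 p q from the sample
#' allele frequency.  Positive values indicate heterozygote deficiency,
#' as produced by a Wahlund effect when two differentiated populations
#' are mixed in one sample; negative values indicate heterozygote
#' excess.  Monomorphic SNPs have no defined value and are excluded from
#' the summary; the mean and its standard error are reported over the
#' polymorphic loci.
#'
#' @param geno genotype matrix individuals x SNPs (0/1/2, `NA` allowed).
#' @param min_call_rate minimum per-SNP call rate retained.
#' @return list of class `fit_result`: per-SNP `fit`, `h_obs`, `h_exp`,
#'   and the summary `mean`, `se`, `n_poly`.
#' @export
fit_statistic <- function(geno, min_call_rate = 0.9) {
  if (is.vector(geno)) geno <- matrix(geno, ncol = 1)
  stopifnot(nrow(geno) >= 10)
  cr <- colMeans(!is.na(geno))
  geno <- geno[, cr >= min_call_rate, drop = FALSE]
  p <- colMeans(geno, na.rm = TRUE) / 2
  h_obs <- colMeans(geno == 1, na.rm = TRUE)
  h_exp <- 2 * p * (1 - p)
  fit <- ifelse(h_exp > 0, 1 - h_obs / h_exp, NA_real_)
  poly <- !is.na(fit)
  structure(list(fit = fit, h_obs = h_obs, h_exp = h_exp,
                 mean = mean(fit[poly]),
                 se = stats::sd(fit[poly]) / sqrt(sum(poly)),
                 n_poly = sum(poly)),
            class = "fit_result")
}

#' @export
print.fit_result <- function(x, ...) {
  cat(sprintf("F_IT over %d polymorphic loci: mean %.3f +/- %.3f (s.e.)\n",
              x$n_poly, x$mean, x$se))
  invisible(x)
}

#' Expected F_IT of a mixture of two populations (Wahlund effect)
#'
#' If a sample is a mix of two populations with allele frequencies `p1`
#' and `p2`, the expected heterozygosity of the mixture is the weighted
#' average of the within-population values, while the expected
#' Hardy-Weinberg heterozygosity uses the pooled frequency; the
#' resulting F = 1 - H_mix / (2 p-bar q-bar) is the heterozygote
#' deficiency expected under admixture, non-negative and zero only when
#' p1 = p2.
#'
#' @param p1,p2 allele frequencies of the two source populations.
#' @param mixing proportion of the first population in the mix.
#' @return expected F_IT; `NA` if the pooled frequency is 0 or 1.
#' @examples
#' expected_mixture_fit(0.1, 0.9)  # 0.64
#' @export
expected_mixture_fit <- function(p1, p2, mixing = 0.5) {
  stopifnot(all(p1 >= 0 & p1 <= 1), all(p2 >= 0 & p2 <= 1),
            mixing >= 0, mixing <= 1)
  h_mix <- mixing * 2 * p1 * (1 - p1) + (1 - mixing) * 2 * p2 * (1 - p2)
  pbar <- mixing * p1 + (1 - mixing) * p2
  ht <- 2 * pbar * (1 - pbar)
  ifelse(ht > 0, 1 - h_mix / ht, NA_real_)
}

#' Allele-frequency distance matrix between pools
#'
#' Default metric: mean over SNPs of the absolute per-pool frequency
#' difference, d(i, j) = mean |p_i - p_j|.  A different per-SNP metric
#' can be plugged in.
#'
#' @param freqs matrix pools x SNPs of allele frequencies.
#' @param method `"mean_abs"` (default) or a function
#'   `(p_i, p_j) -> distance`.
#' @return a `dist`-compatible symmetric matrix with zero diagonal.
#' @export
allele_freq_distance <- function(freqs, method = "mean_abs") {
  stopifnot(nrow(freqs) >= 2)
  fun <- if (is.function(method)) method else
    switch(method,
           mean_abs = function(a, b) mean(abs(a - b), na.rm = TRUE),
           stop("unknown method"))
  n <- nrow(freqs)
  d <- matrix(0, n, n, dimnames = list(rownames(freqs), rownames(freqs)))
  for (i in seq_len(n - 1)) for (j in (i + 1):n)
    d[i, j] <- d[j, i] <- fun(freqs[i, ], freqs[j, ])
  if (anyNA(d)) stop("NaN distance")
  d
}

#' Neighbor-joining tree from a distance matrix
#'
#' Canonical neighbor-joining (Saitou & Nei) on a symmetric distance
#' matrix; additive distances are recovered exactly.  Negative branch
#' lengths, which NJ can produce on noisy distances, are clamped to zero
#' with a warning.
#'
#' @param d symmetric distance matrix (>= 3 taxa, zero diagonal).
#' @return an unrooted [ape::phylo] tree.
#' @export
neighbor_joining <- function(d) {
  d <- as.matrix(d)
  stopifnot(nrow(d) >= 3, isTRUE(all.equal(d, t(d))),
            all(diag(d) == 0))
  if (anyNA(d)) stop("NaN distance")
  tr <- ape::nj(stats::as.dist(d))
  if (any(tr$edge.length < 0)) {
    warning("negative NJ branch length(s) clamped to zero")
    tr$edge.length[tr$edge.length < 0] <- 0
  }
  tr
}

#' Neighbor-joining tree of phased haplotypes at a locus
#'
#' Pairwise Hamming distance per site between phased haplotypes, then
#' neighbor-joining.  Two well-differentiated haplogroups segregating at
#' a locus appear as two clades.
#'
#' @param g a phased [genotype_matrix()] (or a 0/1 haplotype matrix,
#'   haplotypes in rows).
#' @param snps_idx optional column indices restricting to the locus.
#' @return an [ape::phylo] tree with one leaf per haplotype.
#' @export
haplotype_tree <- function(g, snps_idx = NULL) {
  if (inherits(g, "genotype_matrix")) {
    if (!isTRUE(g$phased) || is.null(g$haplotypes))
      stop("haplotype_tree needs phased haplotypes; phase externally first")
    H <- g$haplotypes
  } else {
    H <- g
  }
  if (!is.null(snps_idx)) H <- H[, snps_idx, drop = FALSE]
  stopifnot(nrow(H) >= 3, ncol(H) >= 1)
  D <- as.matrix(stats::dist(H, method = "manhattan")) / ncol(H)
  if (is.null(rownames(D)))
    dimnames(D) <- list(sprintf("h%d", seq_len(nrow(D))),
                        sprintf("h%d", seq_len(nrow(D))))
  neighbor_joining(D)
}

#' Molecular-clock dating of a population split
#'
#' time = divergence / rate, with the rate expressed per lineage pair
#' (i.e. the rate of divergence accumulation between the two lineages),
#' which avoids the factor-of-two ambiguity of per-lineage rates.
#'
#' @param divergence sequence divergence in substitutions per site.
#' @param rate divergence rate in substitutions per site per Myr
#'   (between the pair).
#' @return split time in Myr.
#' @examples
#' date_split(0.044, 0.02)  # 2.2 Myr
#' @export
date_split <- function(divergence, rate) {
  stopifnot(rate > 0, divergence >= 0)
  divergence / rate
}
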
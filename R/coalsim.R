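#' Single-site coalescent simulation of the allele-frequency spectrum
#'
#' Draws independent Kingman coalescent genealogies for a sample of `n`
#' chromosomes under either a constant population size or a single
#' instantaneous size change at scaled time `t` (the ancestral population
#' has `x` times the current size), places mutations uniformly on total
#' branch length, and returns the number of derived-allele carriers per
#' locus.  This reproduces the classic fixed-S "one segregating site per
#' locus" experiment used to compare an observed minor-allele-frequency
#' spectrum against the neutral equilibrium expectation, for which the
#' derived-allele count i has probability proportional to 1/i.
#'
#' @param n sample size in chromosomes.
#' @param n_loci number of independent loci to simulate.
#' @param model `"constant"` or `"size_change"`.
#' @param t time of the size change, in units of 4N0 generations
#'   (coalescent scaled time), looking backwards from the present.
#' @param x ratio of ancestral to current population size; `x < 1` means
#'   the population expanded towards the present (excess of rare alleles).
#' @return integer vector of length `n_loci`; each entry is the number of
#'   chromosomes (out of `n`) carrying the derived allele, in `1..n-1`.
#' @examples
#' set.seed(1)
#' cnt <- simulate_site_frequencies(n = 16, n_loci = 200)
#' mean(cnt == 1)  # singleton proportion, about 1/H_15
#' @export
simulate_site_frequencies <- function(n, n_loci, model = c("constant", "size_change"),
                                      t = 0.1, x = 0.35) {
  model <- match.arg(model)
  stopifnot(n >= 2, n_loci >= 1, t >= 0, x > 0)
  out <- integer(n_loci)
  if (model == "constant") {
    # E[k * w_k] = 2/(k-1), with k = n - j + 1 for epoch index j
    wbar <- 2 / (n - seq_len(n - 1L))
  } else {
    wbar <- rowMeans(coal_level_lengths(n, max(min(n_loci, 50000L), 2000L),
                                        model, t, x))
  }
  # chunk loci so the per-level matrices stay modest for large n
  chunk <- max(1L, min(n_loci, as.integer(2e7 / n)))
  done <- 0L
  while (done < n_loci) {
    m <- min(chunk, n_loci - done)
    out[done + seq_len(m)] <- coal_chunk_s1(n, m, wbar)
    done <- done + m
  }
  out
}

# Waiting times by level for one chunk of loci.
# Returns (n-1) x m matrix of per-level total branch length k * w_k;
# row j corresponds to the epoch with k = n - j + 1 active lineages.
coal_level_lengths <- function(n, m, model, t, x) {
  W <- matrix(0, nrow = n - 1L, ncol = m)
  tau <- numeric(m)
  for (j in seq_len(n - 1L)) {
    k <- n - j + 1L
    E <- stats::rexp(m, rate = k * (k - 1) / 2)
    if (model == "size_change") {
      # piecewise-constant size: residual waiting time past t stretches by x
      w <- ifelse(tau >= t, x * E,
                  ifelse(tau + E <= t, E, (t - tau) + x * (E - (t - tau))))
    } else {
      w <- E
    }
    tau <- tau + w
    W[j, ] <- k * w
  }
  W
}

# One chunk of fixed-S = 1 loci: returns derived carrier counts.
#
# Conditioning on exactly one segregating site is taken in the theta -> 0
# limit: the probability that the site falls in the epoch with k active
# lineages is proportional to the EXPECTED total branch length of that
# epoch (length-biased per-tree placement would distort the spectrum away
# from the analytic 1/i law).  Topology is independent of coalescence
# times, so the epoch is drawn from the expected profile and the carrier
# count is the leaf count of a uniformly chosen lineage at that level.
coal_chunk_s1 <- function(n, m, wbar) {
  epoch <- sample.int(n - 1L, m, replace = TRUE, prob = wbar)
  res <- integer(m)
  C <- matrix(1L, nrow = m, ncol = n)  # leaf counts of active lineages
  r <- seq_len(m)
  for (j in seq_len(n - 1L)) {
    k <- n - j + 1L
    hit <- which(epoch == j)
    if (length(hit)) {
      slot <- sample.int(k, length(hit), replace = TRUE)
      res[hit] <- C[cbind(hit, slot)]
    }
    # merge a random pair of active lineages; compact slot k into the hole
    a <- sample.int(k, m, replace = TRUE)
    b <- sample.int(k - 1L, m, replace = TRUE)
    b <- b + (b >= a)
    lo <- pmin(a, b); hi <- pmax(a, b)
    C[cbind(r, lo)] <- C[cbind(r, lo)] + C[cbind(r, hi)]
    sel <- hi != k
    if (any(sel)) C[cbind(r[sel], hi[sel])] <- C[r[sel] + (k - 1L) * m]
  }
  res
}

#' Coalescent windows with Poisson-distributed segregating sites
#'
#' Simulates `n_windows` independent non-recombining windows: one
#' genealogy each, with the number of mutations Poisson(theta/2 * total
#' branch length) and each mutation placed uniformly on the branches.
#' Used to study window statistics (e.g. Tajima's D) under neutrality
#' with and without a historical size change.
#'
#' @inheritParams simulate_site_frequencies
#' @param n_windows number of windows.
#' @param theta population-scaled mutation rate (4 N0 mu) per window.
#' @return list of integer vectors; element w holds the derived-allele
#'   counts of the segregating sites in window w (possibly empty).
#' @export
simulate_coalescent_windows <- function(n, n_windows, theta,
                                        model = c("constant", "size_change"),
                                        t = 0.1, x = 0.35) {
  model <- match.arg(model)
  stopifnot(n >= 2, n_windows >= 1, theta > 0)
  W <- coal_level_lengths(n, n_windows, model, t, x)
  L <- colSums(W)
  S <- stats::rpois(n_windows, theta / 2 * L)
  # per-window mutation epochs
  epochs <- vector("list", n_windows)
  for (w in seq_len(n_windows)) {
    if (S[w] > 0L)
      epochs[[w]] <- sample.int(n - 1L, S[w], replace = TRUE, prob = W[, w])
  }
  out <- lapply(S, integer)
  C <- matrix(1L, nrow = n_windows, ncol = n)
  r <- seq_len(n_windows)
  for (j in seq_len(n - 1L)) {
    k <- n - j + 1L
    for (w in which(S > 0L)) {
      at <- which(epochs[[w]] == j)
      if (length(at)) {
        slot <- sample.int(k, length(at), replace = TRUE)
        out[[w]][at] <- C[w, slot]
      }
    }
    a <- sample.int(k, n_windows, replace = TRUE)
    b <- sample.int(k - 1L, n_windows, replace = TRUE)
    b <- b + (b >= a)
    lo <- pmin(a, b); hi <- pmax(a, b)
    C[cbind(r, lo)] <- C[cbind(r, lo)] + C[cbind(r, hi)]
    sel <- hi != k
    if (any(sel)) C[cbind(r[sel], hi[sel])] <- C[r[sel] + (k - 1L) * n_windows]
  }
  out
}

#' Expected neutral site-frequency spectrum
#'
#' Probability of a derived-allele count i (unfolded, i in 1..n-1) or a
#' minor-allele count (folded) for a constant-size neutral population:
#' P(i) proportional to 1/i, normalised by the harmonic number H_{n-1}.
#'
#' @param n sample size in chromosomes.
#' @param folded fold the spectrum to minor-allele counts?
#' @return named numeric vector of probabilities.
#' @export
expected_sfs <- function(n, folded = FALSE) {
  stopifnot(n >= 2)
  i <- seq_len(n - 1L)
  p <- (1 / i) / sum(1 / i)
  if (!folded) return(stats::setNames(p, i))
  nf <- floor(n / 2)
  pf <- vapply(seq_len(nf), function(j) {
    if (j == n - j) p[j] else p[j] + p[n - j]
  }, numeric(1))
  stats::setNames(pf, seq_len(nf))
}

#' Hypergeometric subsampling of derived-allele counts
#'
#' Subsamples each locus from `n` to `m` chromosomes without replacement
#' (hypergeometric draw of derived alleles), drops loci that become
#' monomorphic, folds to the minor-allele count, and tabulates the folded
#' spectrum.  The procedure is repeated `n_resamples` times and the mean
#' and standard deviation of each bin's proportion across resamples are
#' reported, mirroring the resampling used to compare a large simulated
#' panel with a smaller empirical sample.
#'
#' @param counts derived-allele counts out of `n` (from
#'   [simulate_site_frequencies()]).
#' @param n original sample size.
#' @param m subsample size (`2 <= m <= n`).
#' @param n_resamples number of independent resampling rounds.
#' @return list with `mean` and `sd` (named vectors over minor-allele
#'   counts `1..floor(m/2)`), and `spectra`, the per-resample matrix.
#' @export
subsample_spectrum <- function(counts, n, m, n_resamples = 10) {
  stopifnot(m >= 2, m <= n, all(counts >= 0), all(counts <= n))
  nf <- floor(m / 2)
  spectra <- matrix(0, nrow = n_resamples, ncol = nf,
                    dimnames = list(NULL, seq_len(nf)))
  for (r in seq_len(n_resamples)) {
    sub <- stats::rhyper(length(counts), counts, n - counts, m)
    sub <- sub[sub > 0L & sub < m]
    minor <- pmin(sub, m - sub)
    tab <- tabulate(minor, nbins = nf)
    spectra[r, ] <- tab / sum(tab)
  }
  list(mean = colMeans(spectra), sd = apply(spectra, 2L, stats::sd),
       spectra = spectra)
}

#' Kolmogorov-Smirnov comparison of two allele-frequency spectra
#'
#' Two-sample KS test on per-locus minor-allele frequencies, the check
#' used to ask whether an observed spectrum is compatible with the
#' spectrum simulated under neutral equilibrium.
#'
#' @param observed,simulated numeric vectors of per-locus minor-allele
#'   frequencies (values in \[0, 0.5\]).
#' @return list with the KS statistic `D` and `p`.
#' @export
ks_compare <- function(observed, simulated) {
  stopifnot(length(observed) > 0, length(simulated) > 0)
  kt <- suppressWarnings(stats::ks.test(observed, simulated))
  list(D = unname(kt$statistic), p = kt$p.value)
}
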
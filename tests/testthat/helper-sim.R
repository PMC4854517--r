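# shared fixtures, built in code and memoised across test files

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache))
    assign(key, expr, envir = .fixture_cache)
  get(key, envir = .fixture_cache)
}

# evenly spaced, non-overlapping haplotype blocks on a multi-scaffold genome
make_blocks <- function(n_blocks, n_scaffolds, scaffold_length,
                        daf_lo, daf_hi, type = "salinity",
                        size_lo = 1e4, size_hi = 2e5, seed = 99) {
  set.seed(seed)
  per <- ceiling(n_blocks / n_scaffolds)
  out <- list(); b <- 0
  for (s in seq_len(n_scaffolds)) {
    slots <- seq(5e4, scaffold_length - size_hi - 5e4, length.out = per + 1)
    for (k in seq_len(per)) {
      if (b >= n_blocks) break
      b <- b + 1
      sz <- round(stats::runif(1, size_lo, size_hi))
      st <- round(slots[k])
      out[[b]] <- data.frame(chrom = sprintf("scaffold%d", s), start = st,
                             end = st + sz - 1, type = type,
                             target_daf = stats::runif(1, daf_lo, daf_hi),
                             stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}

# small metapopulation with one strong salinity block, used by several files
small_block_sim <- function() {
  cached("small_block_sim", {
    blocks <- data.frame(chrom = "scaffold1", start = 4e5, end = 5e5,
                         type = "salinity", target_daf = 0.5,
                         stringsAsFactors = FALSE)
    cfg <- sim_config(n_scaffolds = 1, scaffold_length = 1e6, n_pops = 4,
                      blocks = blocks, snp_spacing_bp = 300,
                      n_geno_per_pool = 10, seed = 5)
    simulate_metapopulation(cfg)
  })
}

# neutral sim at default baseline F_ST, moderate size
neutral_sim <- function() {
  cached("neutral_sim", {
    cfg <- sim_config(n_scaffolds = 4, scaffold_length = 1.5e6, n_pops = 20,
                      snp_spacing_bp = 120, n_geno_per_pool = 5, seed = 43)
    simulate_metapopulation(cfg)
  })
}

# trapezoid integration of the binomial-GLMM marginal log-likelihood on the
# deviance scale (relative to the saturated model), independent of lme4
glmm_marginal_loglik <- function(alt, tot, group, pop, b0, b1, s2,
                                 ngrid = 4001, halfwidth = 10) {
  lev <- levels(factor(group))
  sd <- sqrt(s2)
  kernel <- function(i, uu) {
    pr <- stats::plogis(b0 + b1 * (group[i] == lev[2]) + uu)
    sum(alt[i] * log(pr) + (tot[i] - alt[i]) * log1p(-pr))
  }
  ll <- 0
  for (pp in unique(pop)) {
    i <- which(pop == pp)
    if (sd < 1e-4) {
      # the Gaussian collapses to a point mass at zero
      ll <- ll + kernel(i, 0)
      next
    }
    g <- seq(-halfwidth * sd, halfwidth * sd, length.out = ngrid)
    vals <- vapply(g, function(uu)
      exp(kernel(i, uu)) * stats::dnorm(uu, 0, sd), numeric(1))
    ll <- ll + log(sum((vals[-1] + vals[-ngrid]) / 2) * diff(g)[1])
  }
  ph <- alt / tot
  sat <- sum(ifelse(alt > 0, alt * log(ph), 0) +
               ifelse(alt < tot, (tot - alt) * log1p(-ph), 0))
  ll - sat
}

# fraction of SNPs (by index) falling inside a set of truth intervals
in_intervals <- function(snps, intervals) {
  hit <- rep(FALSE, nrow(snps))
  for (r in seq_len(nrow(intervals)))
    hit <- hit | (snps$chrom == intervals$chrom[r] &
                    snps$pos >= intervals$start[r] &
                    snps$pos <= intervals$end[r])
  hit
}
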
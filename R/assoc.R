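#' Pearson correlation between allele frequency and salinity
#'
#' The environmental-association arm of the scan: per SNP, the standard
#' Pearson correlation of per-pool allele frequency against the salinity
#' at the sampling locality.  SNPs reaching `|r| >= r_cut` are flagged.
#' Note this arm alone does not correct for population structure and is
#' anti-conservative under it; pair it with an empirical null.
#'
#' @param freqs numeric matrix SNPs x pools of allele frequencies (or a
#'   vector for one SNP).
#' @param salinity per-pool salinity in permil (not constant).
#' @param r_cut flagging threshold on `|r|`.
#' @return data frame with `r` and logical `flagged` (`NA` r for
#'   frequency-constant SNPs, which are flagged).
#' @export
salinity_correlation <- function(freqs, salinity, r_cut = 0.8) {
  if (is.vector(freqs)) freqs <- matrix(freqs, nrow = 1)
  stopifnot(ncol(freqs) == length(salinity), ncol(freqs) >= 3,
            stats::sd(salinity) > 0)
  s <- salinity - mean(salinity)
  f <- freqs - rowMeans(freqs)
  sdf <- sqrt(rowSums(f^2))
  r <- drop(f %*% s) / (sdf * sqrt(sum(s^2)))
  r[sdf == 0] <- NA_real_
  data.frame(r = r, flagged = is.na(r) | abs(r) >= r_cut)
}

#' Binomial mixed-model contrast of spawning groups at one SNP
#'
#' Fits alternate-allele counts per pool with a logit-link binomial
#' GLMM: a fixed spawning-group effect and a Gaussian random intercept
#' per population, the model that accounts for variability between
#' populations within groups.  The marginal likelihood is maximised with
#' adaptive Gauss-Hermite quadrature (`nAGQ` nodes; the 1-node Laplace
#' default is deliberately not used) via [lme4::glmer()].  The p-value
#' is a 1-df likelihood-ratio test against the model without the group
#' effect.
#'
#' @param alt,total alternate and total allele counts per pool.
#' @param group factor with two levels (e.g. spring/autumn) per pool.
#' @param population population id per pool (the random-effect grouping).
#' @param nAGQ number of adaptive Gauss-Hermite quadrature nodes.
#' @return list of class `glmm_fit`: `beta` (group log-odds), `beta0`
#'   (intercept), `sigma2`
#'   (random-intercept variance), `loglik`, `loglik_null`, `lrt`, `p`,
#'   `boundary` (variance at zero) and `separated`.
#' @export
glmm_spawning <- function(alt, total, group, population, nAGQ = 10) {
  stopifnot(length(alt) == length(total), all(total > 0),
            all(alt >= 0), all(alt <= total))
  group <- factor(group)
  if (nlevels(group) != 2) stop("group must have exactly two levels")
  if (any(tapply(population, group, function(z) length(unique(z))) < 2))
    stop("need >= 2 populations per group")
  df <- data.frame(alt = alt, ref = total - alt, group = group,
                   population = factor(population))
  if (stats::sd(alt / total) == 0) {
    # constant observed frequency: both models fit the data perfectly
    return(structure(list(beta = 0, beta0 = stats::qlogis(alt[1] / total[1]),
                          sigma2 = 0, loglik = 0, loglik_null = 0, lrt = 0,
                          p = 1, boundary = TRUE, separated = FALSE,
                          groups = levels(group)),
                     class = "glmm_fit"))
  }
  sep <- all(alt[group == levels(group)[1]] == 0) &&
    all(alt[group == levels(group)[2]] == total[group == levels(group)[2]])
  sep <- sep || (all(alt[group == levels(group)[2]] == 0) &&
                   all(alt[group == levels(group)[1]] ==
                         total[group == levels(group)[1]]))
  ctrl <- lme4::glmerControl(check.conv.singular = "ignore",
                             check.conv.grad = "ignore",
                             check.conv.hess = "ignore",
                             check.response.not.const = "ignore")
  fit1 <- suppressWarnings(suppressMessages(
    lme4::glmer(cbind(alt, ref) ~ group + (1 | population), data = df,
                family = stats::binomial(), nAGQ = nAGQ, control = ctrl)))
  fit0 <- suppressWarnings(suppressMessages(
    lme4::glmer(cbind(alt, ref) ~ 1 + (1 | population), data = df,
                family = stats::binomial(), nAGQ = nAGQ, control = ctrl)))
  ll1 <- as.numeric(stats::logLik(fit1))
  ll0 <- as.numeric(stats::logLik(fit0))
  lrt <- max(0, 2 * (ll1 - ll0))
  vc <- as.data.frame(lme4::VarCorr(fit1))$vcov[1]
  structure(list(beta = unname(lme4::fixef(fit1)[2]),
                 beta0 = unname(lme4::fixef(fit1)[1]), sigma2 = vc,
                 loglik = ll1, loglik_null = ll0, lrt = lrt,
                 p = stats::pchisq(lrt, df = 1, lower.tail = FALSE),
                 boundary = vc < 1e-8, separated = sep,
                 groups = levels(group)),
            class = "glmm_fit")
}

#' @export
print.glmm_fit <- function(x, ...) {
  cat(sprintf("Binomial GLMM %s vs %s: beta = %.3f, sigma2 = %.4f, LRT p = %.3g%s\n",
              x$groups[1], x$groups[2], x$beta, x$sigma2, x$p,
              if (x$separated) " [complete separation]" else ""))
  invisible(x)
}

#' Mixed-model spawning scan over many SNPs
#'
#' Applies [glmm_spawning()] to every SNP of a pooled count set.  The
#' effective binomial denominator per pool is the smaller of the number
#' of chromosomes (2 x fish) and the normalised read depth, since read
#' counts cannot carry more information than the chromosomes sampled.
#'
#' @param counts a [pool_counts()] object.
#' @param pops pool metadata; pools with season `spring` or `autumn` are
#'   contrasted, others dropped.
#' @param expected_cov expected coverage for count normalisation
#'   (`NULL`: genome-wide mean).
#' @param nAGQ quadrature nodes.
#' @return data frame: `chrom`, `pos`, `beta`, `sigma2`, `lrt`, `p`,
#'   `separated`.
#' @export
glmm_scan <- function(counts, pops, expected_cov = NULL, nAGQ = 10) {
  stopifnot(inherits(counts, "pool_counts"))
  validate_pop_table(pops)
  pops <- pops[match(counts$pools, pops$pool), ]
  keep <- pops$season %in% c("spring", "autumn")
  counts <- counts[, keep]
  pops <- pops[keep, ]
  if (is.null(expected_cov)) expected_cov <- mean(counts$ref + counts$alt)
  nm <- normalize_counts(counts$ref, counts$alt, expected_cov)
  tot <- nm$ref + nm$alt
  denom <- pmin(tot, matrix(rep(2 * pops$n_fish, each = nrow(tot)),
                            nrow = nrow(tot)))
  alt_eff <- round_half_away(nm$alt / ifelse(tot > 0, tot, 1) * denom)
  n <- nrow(counts$snps)
  out <- data.frame(chrom = counts$snps$chrom, pos = counts$snps$pos,
                    beta = NA_real_, sigma2 = NA_real_, lrt = NA_real_,
                    p = NA_real_, separated = NA)
  for (i in seq_len(n)) {
    fit <- try(glmm_spawning(alt_eff[i, ], denom[i, ], pops$season,
                             pops$pool, nAGQ = nAGQ), silent = TRUE)
    if (!inherits(fit, "try-error")) {
      out$beta[i] <- fit$beta; out$sigma2[i] <- fit$sigma2
      out$lrt[i] <- fit$lrt; out$p[i] <- fit$p
      out$separated[i] <- fit$separated
    }
  }
  out
}
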
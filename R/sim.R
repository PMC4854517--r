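#' Configuration for the synthetic metapopulation generator
#'
#' Bundles and validates everything [simulate_metapopulation()] and
#' [simulate_depth()] need: genome layout, pool metadata, the neutral
#' differentiation level, the shape of the allele-frequency spectrum,
#' injected haplotype blocks with a target allele-frequency difference
#' (dAF) between contrast groups, copy-number variants, and functional
#' category proportions.  Defaults emulate the study system the package
#' targets: pools of 47-100 diploids sequenced to ~30x, neutral
#' between-population F_ST near 0.038, an expansion-shaped spectrum with
#' an excess of rare alleles, differentiated haplotype blocks of
#' 10-200 kb and CNVs of 1-26 kb.
#'
#' @param n_scaffolds number of scaffolds.
#' @param scaffold_length scaffold length in bp.
#' @param pools data frame with columns `pool`, `n_fish`, `salinity`
#'   (permil), `season` (`spring`/`summer`/`autumn`/`unknown`) and
#'   `superpool` (`groupA`/`groupB`, the marine-vs-brackish contrast).
#'   If `NULL`, 20 pools in two balanced superpools are created with
#'   salinities 20-35 (groupA) and 3-12 (groupB) and sizes drawn in
#'   47-100 fish.
#' @param n_pops number of pools when `pools` is auto-generated.
#' @param mean_coverage expected reads per site per pool.
#' @param baseline_fst neutral differentiation among pools, in `[0, 1)`.
#' @param sfs_mode `"constant"` (spectrum proportional to 1/i) or
#'   `"expansion"` (size-change coalescent, excess rare alleles).
#' @param snp_spacing_bp mean spacing between segregating sites in bp;
#'   the default 40 yields ~0.3% nucleotide diversity under the default
#'   expansion spectrum.
#' @param blocks data frame of injected haplotype blocks with columns
#'   `chrom`, `start`, `end`, `type` (`salinity` or `spawning`) and
#'   `target_daf`; `NULL` for none.
#' @param cnvs data frame of copy-number variants with columns `chrom`,
#'   `start`, `end`, `group` (which superpool carries the change) and
#'   `fold` (depth fold change, > 0); `NULL` for none.
#' @param category_props named proportions of functional SNP categories
#'   (must be non-negative, summing to <= 1; remainder is intergenic).
#' @param nonsyn_block_bias fold enrichment of the `non-synonymous`
#'   category inside injected blocks relative to the genome proportion.
#' @param pool_size_range range the per-pool number of diploids is drawn
#'   from when `pools` is auto-generated.
#' @param n_chrom_sfs nominal chromosome count used to discretise
#'   ancestral allele frequencies from the spectrum.
#' @param hap_divergence_eps haplogroup allele frequencies at
#'   block-diagnostic SNPs are `1 - eps` vs `eps`.
#' @param mixture_sd per-pool standard deviation of the haplogroup
#'   mixture proportion around its group mean.
#' @param coverage_overdispersion negative-binomial overdispersion of
#'   per-site depth; 0 gives pure Poisson.
#' @param geno_pools pool ids for which individual genotypes are drawn;
#'   default: the first pool of each superpool (individual sequencing of
#'   every pool is rarely available in practice).
#' @param n_geno_per_pool diploid individuals genotyped per such pool.
#' @param window_size depth-window width in bp for [simulate_depth()].
#' @param depth_sd_frac coefficient of variation of per-window depth.
#' @param low_map_frac fraction of windows flagged with low mappability.
#' @param seed integer seed stored with the configuration.
#' @return an object of class `sim_config`.
#' @export
sim_config <- function(n_scaffolds = 4, scaffold_length = 1e6, pools = NULL,
                       n_pops = 20, mean_coverage = 30, baseline_fst = 0.038,
                       sfs_mode = c("expansion", "constant"),
                       snp_spacing_bp = 40, blocks = NULL, cnvs = NULL,
                       category_props = c("non-synonymous" = 0.01,
                                          "synonymous" = 0.01,
                                          "5'UTR" = 0.005, "3'UTR" = 0.01,
                                          "5kb-upstream" = 0.05,
                                          "5kb-downstream" = 0.05,
                                          "intronic" = 0.35),
                       nonsyn_block_bias = 1,
                       pool_size_range = c(47, 100), n_chrom_sfs = 200,
                       hap_divergence_eps = 0.025, mixture_sd = 0.05,
                       coverage_overdispersion = 0,
                       geno_pools = NULL, n_geno_per_pool = 30,
                       window_size = 1000, depth_sd_frac = 0.1,
                       low_map_frac = 0.05, seed = 1L) {
  sfs_mode <- match.arg(sfs_mode)
  stopifnot(n_scaffolds >= 1, scaffold_length >= 1000,
            mean_coverage > 0, baseline_fst >= 0, baseline_fst < 1,
            snp_spacing_bp >= 1, pool_size_range[1] >= 1,
            hap_divergence_eps > 0, hap_divergence_eps < 0.5,
            coverage_overdispersion >= 0)
  if (is.null(pools)) {
    stopifnot(n_pops >= 2, n_pops %% 2 == 0)
    half <- n_pops / 2
    set.seed(seed)  # pool metadata is part of the configuration
    pools <- data.frame(
      pool = sprintf("P%02d", seq_len(n_pops)),
      n_fish = sample(seq(pool_size_range[1], pool_size_range[2]), n_pops,
                      replace = TRUE),
      salinity = c(stats::runif(half, 20, 35), stats::runif(half, 3, 12)),
      season = rep(c("spring", "autumn"), length.out = n_pops),
      superpool = rep(c("groupA", "groupB"), each = half),
      stringsAsFactors = FALSE)
  }
  validate_pop_table(pools)
  if (any(category_props < 0) || sum(category_props) > 1)
    stop("category_props must be non-negative and sum to <= 1")
  if (!is.null(blocks)) {
    stopifnot(all(c("chrom", "start", "end", "type", "target_daf") %in%
                    names(blocks)))
    check_disjoint_intervals(blocks, scaffold_length, "blocks")
    stopifnot(all(blocks$target_daf > 0), all(blocks$target_daf <= 1))
  }
  if (!is.null(cnvs)) {
    stopifnot(all(c("chrom", "start", "end", "group", "fold") %in% names(cnvs)))
    if (any(cnvs$fold < 0)) stop("negative CNV fold change")
    check_disjoint_intervals(cnvs, scaffold_length, "cnvs")
  }
  if (is.null(geno_pools)) geno_pools <- pools$pool[!duplicated(pools$superpool)]
  structure(list(
    n_scaffolds = n_scaffolds, scaffold_length = scaffold_length,
    pools = pools, mean_coverage = mean_coverage,
    baseline_fst = baseline_fst, sfs_mode = sfs_mode,
    snp_spacing_bp = snp_spacing_bp, blocks = blocks, cnvs = cnvs,
    category_props = category_props, nonsyn_block_bias = nonsyn_block_bias,
    n_chrom_sfs = n_chrom_sfs, hap_divergence_eps = hap_divergence_eps,
    mixture_sd = mixture_sd,
    coverage_overdispersion = coverage_overdispersion,
    geno_pools = geno_pools, n_geno_per_pool = n_geno_per_pool,
    window_size = window_size, depth_sd_frac = depth_sd_frac,
    low_map_frac = low_map_frac, seed = as.integer(seed)),
    class = "sim_config")
}

check_disjoint_intervals <- function(df, scaffold_length, what) {
  if (any(df$start < 1) || any(df$end > scaffold_length) ||
      any(df$end < df$start))
    stop(what, ": intervals must lie within their scaffold")
  for (sc in unique(df$chrom)) {
    d <- df[df$chrom == sc, , drop = FALSE]
    d <- d[order(d$start), , drop = FALSE]
    if (nrow(d) > 1 && any(d$start[-1] <= d$end[-nrow(d)]))
      stop(what, ": overlapping intervals on ", sc)
  }
  invisible(TRUE)
}

#' Simulate a pooled and individually genotyped metapopulation
#'
#' Generates per-SNP, per-pool read counts, individual genotypes with
#' phased haplotypes, pool metadata, per-SNP functional annotations and
#' a truth table of injected features.  Neutral SNPs get ancestral
#' frequencies from the configured allele-frequency spectrum and
#' per-pool frequencies from a Balding-Nichols beta draw at
#' `baseline_fst`; SNPs inside injected blocks follow a two-haplogroup
#' system whose per-pool mixture proportion tracks the contrast group so
#' the realised superpool |dAF| matches `target_daf`.  Read counts use a
#' double-binomial pool-seq error model: chromosomes sampled from
#' 2 x pool size, then reads at Poisson(mean coverage).
#'
#' @param config a [sim_config()] object.
#' @return a list of class `pool_sim` with elements `counts`
#'   ([pool_counts()]), `genotypes` ([genotype_matrix()]), `pops`
#'   (pool metadata), `freqs` (true per-pool frequency matrix),
#'   `annotations` (per-SNP category), `truth` (truth table data frame)
#'   and `config`.
#' @examples
#' cfg <- sim_config(n_scaffolds = 1, scaffold_length = 2e5, n_pops = 4,
#'                   n_geno_per_pool = 5, seed = 7)
#' sim <- simulate_metapopulation(cfg)
#' dim(sim$counts$ref)
#' @export
simulate_metapopulation <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  if (any(config$pools$n_fish < 1)) stop("zero pool size")
  set.seed(config$seed)
  pools <- config$pools
  n_pool <- nrow(pools)

  snps <- draw_snp_positions(config)
  n_snp <- nrow(snps)
  p0 <- draw_ancestral_freqs(config, n_snp)

  # Balding-Nichols neutral per-pool frequencies
  fst <- config$baseline_fst
  P <- matrix(0, n_snp, n_pool, dimnames = list(NULL, pools$pool))
  if (fst > 0) {
    lam <- (1 - fst) / fst
    for (j in seq_len(n_pool))
      P[, j] <- stats::rbeta(n_snp, p0 * lam, (1 - p0) * lam)
  } else {
    P[] <- p0
  }

  # haplogroup mixture per pool for each block; overwrite block SNP freqs
  blocks <- config$blocks
  block_of_snp <- rep(NA_integer_, n_snp)
  hap_freq <- NULL   # n_snp x 2 haplogroup allele frequencies (blocks only)
  M <- NULL          # n_block x n_pool mixture proportions
  if (!is.null(blocks) && nrow(blocks) > 0) {
    eps <- config$hap_divergence_eps
    delta <- 1 - 2 * eps
    hap_freq <- matrix(NA_real_, n_snp, 2)
    M <- matrix(NA_real_, nrow(blocks), n_pool)
    for (b in seq_len(nrow(blocks))) {
      in_b <- which(snps$chrom == blocks$chrom[b] &
                      snps$pos >= blocks$start[b] & snps$pos <= blocks$end[b])
      block_of_snp[in_b] <- b
      target <- blocks$target_daf[b]
      if (target > delta) {
        warning("block ", b, ": target_daf ", target,
                " unreachable at haplogroup divergence ", delta, "; clamped")
        target <- delta
      }
      grp <- if (blocks$type[b] == "spawning") {
        ifelse(pools$season == "spring", "groupA", "groupB")
      } else pools$superpool
      m_mean <- ifelse(grp == "groupA", 0.5 + target / (2 * delta),
                       0.5 - target / (2 * delta))
      m <- stats::rnorm(n_pool, m_mean, config$mixture_sd)
      M[b, ] <- pmin(pmax(m, 0), 1)
      # diagnostic SNPs: haplogroup 1 carries the alt allele at high freq,
      # random orientation per SNP
      flip <- stats::runif(length(in_b)) < 0.5
      hap_freq[in_b, 1] <- ifelse(flip, eps, 1 - eps)
      hap_freq[in_b, 2] <- ifelse(flip, 1 - eps, eps)
      for (j in seq_len(n_pool))
        P[in_b, j] <- M[b, j] * hap_freq[in_b, 1] +
          (1 - M[b, j]) * hap_freq[in_b, 2]
    }
  }

  reads <- sample_pool_reads(P, pools, config, block_of_snp, hap_freq, M)
  # a variant never seen in any pool's reads would not be in a call set
  observed <- rowSums(reads$alt) > 0L
  snps <- snps[observed, , drop = FALSE]
  P <- P[observed, , drop = FALSE]
  block_of_snp <- block_of_snp[observed]
  if (!is.null(hap_freq)) hap_freq <- hap_freq[observed, , drop = FALSE]
  counts <- pool_counts(snps = snps,
                        ref = reads$ref[observed, , drop = FALSE],
                        alt = reads$alt[observed, , drop = FALSE])

  genotypes <- draw_individual_genotypes(P, snps, pools, config,
                                         block_of_snp, hap_freq, M)
  annotations <- draw_annotations(config, nrow(snps), block_of_snp)

  truth <- data.frame(chrom = character(0), start = integer(0),
                      end = integer(0), type = character(0),
                      effect = numeric(0), stringsAsFactors = FALSE)
  if (!is.null(blocks) && nrow(blocks) > 0)
    truth <- rbind(truth, data.frame(chrom = blocks$chrom,
                                     start = blocks$start, end = blocks$end,
                                     type = as.character(blocks$type),
                                     effect = blocks$target_daf,
                                     stringsAsFactors = FALSE))
  if (!is.null(config$cnvs) && nrow(config$cnvs) > 0)
    truth <- rbind(truth, data.frame(chrom = config$cnvs$chrom,
                                     start = config$cnvs$start,
                                     end = config$cnvs$end,
                                     type = paste0("cnv_", config$cnvs$group),
                                     effect = config$cnvs$fold,
                                     stringsAsFactors = FALSE))

  structure(list(counts = counts, genotypes = genotypes, pops = pools,
                 freqs = P, annotations = annotations, truth = truth,
                 config = config),
            class = "pool_sim")
}

draw_snp_positions <- function(config) {
  out <- vector("list", config$n_scaffolds)
  for (s in seq_len(config$n_scaffolds)) {
    gaps <- stats::rgeom(ceiling(config$scaffold_length /
                                   config$snp_spacing_bp * 1.3),
                         1 / config$snp_spacing_bp) + 1L
    pos <- cumsum(gaps)
    pos <- pos[pos <= config$scaffold_length]
    out[[s]] <- data.frame(chrom = sprintf("scaffold%d", s), pos = pos,
                           stringsAsFactors = FALSE)
  }
  snps <- do.call(rbind, out)
  n <- nrow(snps)
  ref <- sample(c("A", "C", "G", "T"), n, replace = TRUE)
  alt <- vapply(ref, function(b) sample(setdiff(c("A", "C", "G", "T"), b), 1),
                character(1), USE.NAMES = FALSE)
  cbind(snps, data.frame(ref = ref, alt = alt, stringsAsFactors = FALSE))
}

draw_ancestral_freqs <- function(config, n_snp) {
  n_chrom <- config$n_chrom_sfs
  if (config$sfs_mode == "constant") {
    i <- sample(seq_len(n_chrom - 1L), n_snp, replace = TRUE,
                prob = 1 / seq_len(n_chrom - 1L))
  } else {
    i <- simulate_site_frequencies(n_chrom, n_snp, model = "size_change")
  }
  # keep frequencies off the boundary so pools stay polymorphic-capable
  pmin(pmax(i / n_chrom, 1 / n_chrom), 1 - 1 / n_chrom)
}

# double-binomial read sampling; block SNPs share the per-pool haplogroup
# chromosome draw so within-pool LD across a block is preserved
sample_pool_reads <- function(P, pools, config, block_of_snp, hap_freq, M) {
  n_snp <- nrow(P); n_pool <- ncol(P)
  ref <- alt <- matrix(0L, n_snp, n_pool, dimnames = dimnames(P))
  od <- config$coverage_overdispersion
  for (j in seq_len(n_pool)) {
    nc <- 2L * pools$n_fish[j]
    phat <- numeric(n_snp)
    neutral <- is.na(block_of_snp)
    phat[neutral] <- stats::rbinom(sum(neutral), nc, P[neutral, j]) / nc
    if (!all(neutral)) {
      for (b in unique(block_of_snp[!neutral])) {
        in_b <- which(block_of_snp == b)
        k1 <- stats::rbinom(1L, nc, M[b, j])
        phat[in_b] <- (stats::rbinom(length(in_b), k1, hap_freq[in_b, 1]) +
                         stats::rbinom(length(in_b), nc - k1,
                                       hap_freq[in_b, 2])) / nc
      }
    }
    depth <- if (od > 0) {
      stats::rnbinom(n_snp, size = 1 / od, mu = config$mean_coverage)
    } else {
      stats::rpois(n_snp, config$mean_coverage)
    }
    a <- stats::rbinom(n_snp, depth, phat)
    alt[, j] <- a
    ref[, j] <- depth - a
  }
  list(ref = ref, alt = alt)
}

draw_individual_genotypes <- function(P, snps, pools, config,
                                      block_of_snp, hap_freq, M) {
  gp <- intersect(config$geno_pools, pools$pool)
  if (length(gp) == 0) return(NULL)
  n_ind <- length(gp) * config$n_geno_per_pool
  n_snp <- nrow(P)
  H <- matrix(0L, 2L * n_ind, n_snp)  # rows: haplotypes
  ind_pool <- rep(gp, each = config$n_geno_per_pool)
  hap_pool <- rep(ind_pool, each = 2L)
  hap_group <- rep(NA_integer_, 2L * n_ind)  # truth haplogroup (block system)
  neutral <- is.na(block_of_snp)
  for (j in seq_along(gp)) {
    pj <- match(gp[j], pools$pool)
    rows <- which(hap_pool == gp[j])
    nn <- sum(neutral)
    H[rows, neutral] <- matrix(
      stats::rbinom(length(rows) * nn, 1L,
                    rep(P[neutral, pj], each = length(rows))),
      nrow = length(rows))
    if (!all(neutral)) {
      for (b in unique(block_of_snp[!neutral])) {
        in_b <- which(block_of_snp == b)
        g <- stats::rbinom(length(rows), 1L, M[b, pj])  # 1 = haplogroup 1
        hap_group[rows] <- g
        for (k in seq_along(rows)) {
          pr <- if (g[k] == 1L) hap_freq[in_b, 1] else hap_freq[in_b, 2]
          H[rows[k], in_b] <- stats::rbinom(length(in_b), 1L, pr)
        }
      }
    }
  }
  geno <- H[seq(1, 2 * n_ind, by = 2), , drop = FALSE] +
    H[seq(2, 2 * n_ind, by = 2), , drop = FALSE]
  ids <- sprintf("%s_i%02d", ind_pool,
                 stats::ave(seq_len(n_ind), ind_pool, FUN = seq_along))
  rownames(geno) <- ids
  rownames(H) <- paste0(rep(ids, each = 2), c("_h1", "_h2"))
  genotype_matrix(geno = geno, snps = snps, haplotypes = H, phased = TRUE,
                  pool = ind_pool, hap_group = hap_group)
}

draw_annotations <- function(config, n_snp, block_of_snp) {
  props <- config$category_props
  cats <- c(names(props), "intergenic")
  base_p <- c(props, intergenic = 1 - sum(props))
  ann <- character(n_snp)
  in_block <- !is.na(block_of_snp)
  ann[!in_block] <- sample(cats, sum(!in_block), replace = TRUE, prob = base_p)
  if (any(in_block)) {
    pb <- base_p
    pb["non-synonymous"] <- pb["non-synonymous"] * config$nonsyn_block_bias
    pb <- pb / sum(pb)
    ann[in_block] <- sample(cats, sum(in_block), replace = TRUE, prob = pb)
  }
  ann
}

#' Simulate a per-pool read-depth matrix over fixed windows
#'
#' Per-pool, per-window mean depth is Normal around a pool-specific depth
#' scale, multiplied by the configured fold change inside CNV intervals
#' for the pools of the affected superpool.  A mappability value per
#' window is emitted, with a configurable fraction of low-mappability
#' windows.
#'
#' @param config a [sim_config()] object (fields `cnvs`, `window_size`,
#'   `depth_sd_frac`, `low_map_frac`).
#' @return a [depth_matrix()] object.
#' @export
simulate_depth <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  if (!is.null(config$cnvs) && any(config$cnvs$fold < 0))
    stop("negative CNV fold change")
  set.seed(config$seed + 1L)
  pools <- config$pools
  ws <- config$window_size
  n_win_per <- floor(config$scaffold_length / ws)
  win <- do.call(rbind, lapply(seq_len(config$n_scaffolds), function(s) {
    data.frame(chrom = sprintf("scaffold%d", s),
               start = (seq_len(n_win_per) - 1L) * ws + 1L,
               end = seq_len(n_win_per) * ws, stringsAsFactors = FALSE)
  }))
  n_win <- nrow(win); n_pool <- nrow(pools)
  # pool-specific depth scale: sequencing yield varies between libraries
  scale <- exp(stats::rnorm(n_pool, 0, 0.15))
  mu <- config$mean_coverage * scale
  D <- matrix(stats::rnorm(n_win * n_pool,
                           mean = rep(mu, each = n_win),
                           sd = rep(mu * config$depth_sd_frac, each = n_win)),
              n_win, n_pool, dimnames = list(NULL, pools$pool))
  D[D < 0] <- 0
  if (!is.null(config$cnvs)) {
    for (b in seq_len(nrow(config$cnvs))) {
      cv <- config$cnvs[b, ]
      hit <- which(win$chrom == cv$chrom & win$start <= cv$end &
                     win$end >= cv$start)
      cols <- which(pools$superpool == cv$group)
      D[hit, cols] <- D[hit, cols] * cv$fold
    }
  }
  mapp <- rep(1, n_win)
  low <- stats::runif(n_win) < config$low_map_frac
  mapp[low] <- stats::runif(sum(low), 0, 0.5)
  depth_matrix(windows = win, depth = D, mappability = mapp)
}

#' @export
print.pool_sim <- function(x, ...) {
  cat("Synthetic pool-seq metapopulation\n")
  cat(sprintf("  %d SNPs on %d scaffold(s), %d pools\n",
              nrow(x$counts$snps), x$config$n_scaffolds, nrow(x$pops)))
  nb <- sum(x$truth$type %in% c("salinity", "spawning"))
  nc <- sum(startsWith(x$truth$type, "cnv"))
  cat(sprintf("  truth: %d haplotype block(s), %d CNV(s)\n", nb, nc))
  if (!is.null(x$genotypes))
    cat(sprintf("  genotypes: %d individuals\n", nrow(x$genotypes$geno)))
  invisible(x)
}
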
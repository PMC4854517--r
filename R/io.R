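#' Pooled allele read counts
#'
#' Container for per-SNP, per-pool reference and alternate read counts,
#' the substrate of every scan in the package.  Sites are biallelic;
#' positions are 1-based and strictly increasing within a scaffold.
#'
#' @param snps data frame with columns `chrom`, `pos`, `ref`, `alt`.
#' @param ref,alt integer matrices (SNPs x pools) of read counts, with
#'   pool ids as column names.
#' @return an object of class `pool_counts` with elements `snps`, `ref`,
#'   `alt` and `pools` (the pool ids).
#' @export
pool_counts <- function(snps, ref, alt) {
  stopifnot(is.data.frame(snps),
            all(c("chrom", "pos", "ref", "alt") %in% names(snps)),
            nrow(ref) == nrow(snps), nrow(alt) == nrow(snps),
            ncol(ref) == ncol(alt))
  if (any(ref < 0) || any(alt < 0)) stop("negative read counts")
  for (sc in unique(snps$chrom)) {
    p <- snps$pos[snps$chrom == sc]
    if (is.unsorted(p, strictly = TRUE))
      stop("positions not strictly increasing on ", sc)
  }
  pools <- colnames(ref)
  if (is.null(pools)) pools <- sprintf("pool%d", seq_len(ncol(ref)))
  dimnames(ref) <- dimnames(alt) <- list(NULL, pools)
  structure(list(snps = snps, ref = ref, alt = alt, pools = pools),
            class = "pool_counts")
}

#' @export
print.pool_counts <- function(x, ...) {
  cat(sprintf("pool_counts: %d SNPs x %d pools on %d scaffold(s)\n",
              nrow(x$snps), length(x$pools), length(unique(x$snps$chrom))))
  invisible(x)
}

#' @export
`[.pool_counts` <- function(x, i, j) {
  if (missing(i)) i <- seq_len(nrow(x$snps))
  if (missing(j)) j <- seq_along(x$pools)
  pool_counts(snps = x$snps[i, , drop = FALSE],
              ref = x$ref[i, j, drop = FALSE],
              alt = x$alt[i, j, drop = FALSE])
}

#' Individual genotype matrix
#'
#' Genotypes coded 0/1/2 (alternate-allele dosage) or `NA`, individuals
#' in rows and SNPs in columns, optionally with the underlying phased
#' haplotypes (two rows per individual, alleles 0/1).
#'
#' @param geno integer matrix individuals x SNPs.
#' @param snps SNP table as in [pool_counts()].
#' @param haplotypes optional 0/1 matrix with `2 * nrow(geno)` rows.
#' @param phased logical; are `haplotypes` truly phased?
#' @param pool optional per-individual pool id.
#' @param hap_group optional per-haplotype truth label (simulation only).
#' @return an object of class `genotype_matrix`.
#' @export
genotype_matrix <- function(geno, snps, haplotypes = NULL, phased = FALSE,
                            pool = NULL, hap_group = NULL) {
  stopifnot(ncol(geno) == nrow(snps))
  if (!is.null(haplotypes)) {
    stopifnot(nrow(haplotypes) == 2 * nrow(geno),
              ncol(haplotypes) == ncol(geno))
    h1 <- haplotypes[seq(1, nrow(haplotypes), 2), , drop = FALSE]
    h2 <- haplotypes[seq(2, nrow(haplotypes), 2), , drop = FALSE]
    ok <- is.na(geno) | (h1 + h2) == geno
    if (!all(ok)) stop("haplotypes do not decompose to the genotypes")
  }
  structure(list(geno = geno, snps = snps, haplotypes = haplotypes,
                 phased = phased, pool = pool, hap_group = hap_group),
            class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf("genotype_matrix: %d individuals x %d SNPs (%s)\n",
              nrow(x$geno), ncol(x$geno),
              if (isTRUE(x$phased)) "phased" else "unphased"))
  invisible(x)
}

#' Per-window read-depth matrix
#'
#' @param windows data frame `chrom`, `start`, `end` (1-based inclusive)
#'   on a non-overlapping, genome-ordered grid.
#' @param depth numeric matrix windows x pools of mean depth.
#' @param mappability numeric vector in `[0, 1]`, one value per window.
#' @return an object of class `depth_matrix`.
#' @export
depth_matrix <- function(windows, depth, mappability = NULL) {
  stopifnot(nrow(windows) == nrow(depth))
  if (is.null(mappability)) mappability <- rep(1, nrow(windows))
  stopifnot(length(mappability) == nrow(windows),
            all(mappability >= 0 & mappability <= 1))
  for (sc in unique(windows$chrom)) {
    w <- windows[windows$chrom == sc, ]
    if (nrow(w) > 1 && any(w$start[-1] <= w$end[-nrow(w)]))
      stop("overlapping windows on ", sc)
  }
  structure(list(windows = windows, depth = depth, mappability = mappability),
            class = "depth_matrix")
}

validate_pop_table <- function(pops) {
  req <- c("pool", "n_fish", "salinity", "season", "superpool")
  if (!all(req %in% names(pops)))
    stop("population table needs columns: ", paste(req, collapse = ", "))
  stopifnot(all(pops$n_fish >= 1), all(pops$salinity >= 0),
            all(pops$season %in% c("spring", "summer", "autumn", "unknown")),
            !anyDuplicated(pops$pool))
  invisible(pops)
}

#' Read and write sync-style pooled count files
#'
#' The sync dialect used here is one row per SNP: scaffold, 1-based
#' position, reference base, then one `A:T:C:G:N:del` count string per
#' pool.  Only biallelic SNPs are representable; on reading, rows whose
#' count strings carry reads on more than two bases are skipped with a
#' warning.
#'
#' @param path file path.
#' @param counts a [pool_counts()] object.
#' @param pools optional pool ids for the columns on reading.
#' @return `read_sync()` returns a [pool_counts()]; `write_sync()`
#'   returns `path` invisibly.
#' @export
read_sync <- function(path, pools = NULL) {
  if (!file.exists(path)) stop("no such file: ", path)
  raw <- utils::read.table(path, sep = "\t", header = FALSE,
                           colClasses = "character", quote = "")
  if (ncol(raw) < 4) stop("sync file needs >= 4 columns")
  n_pool <- ncol(raw) - 3L
  if (!is.null(pools) && length(pools) != n_pool)
    stop("file has ", n_pool, " pool columns, expected ", length(pools))
  if (is.null(pools)) pools <- sprintf("pool%d", seq_len(n_pool))
  bases <- c("A", "T", "C", "G")
  n <- nrow(raw)
  cnt <- array(NA_integer_, c(n, n_pool, 6L))
  for (j in seq_len(n_pool)) {
    parts <- strsplit(raw[[3L + j]], ":", fixed = TRUE)
    bad_len <- lengths(parts) != 6L
    if (any(bad_len))
      stop("malformed count string at line ", which(bad_len)[1])
    v <- suppressWarnings(as.integer(unlist(parts)))
    m <- matrix(v, ncol = 6L, byrow = TRUE)
    bad <- which(rowSums(is.na(m)) > 0 | rowSums(m < 0, na.rm = TRUE) > 0)
    if (length(bad))
      stop("non-integer or negative count at line ", bad[1],
           " (pool column ", j, ")")
    cnt[, j, ] <- m
  }
  base_tot <- apply(cnt[, , 1:4, drop = FALSE], c(1L, 3L), sum)
  n_alleles <- rowSums(base_tot > 0)
  multi <- n_alleles > 2L
  if (any(multi))
    warning(sum(multi), " SNP(s) with more than two alleles skipped")
  keep <- which(!multi & n_alleles >= 1L)
  ref_base <- toupper(raw[[3L]])
  ord <- apply(base_tot, 1L, function(z) order(z, decreasing = TRUE))
  snps <- data.frame(chrom = raw[[1L]][keep],
                     pos = as.integer(raw[[2L]][keep]),
                     ref = ref_base[keep], alt = NA_character_,
                     stringsAsFactors = FALSE)
  ref_m <- alt_m <- matrix(0L, length(keep), n_pool,
                           dimnames = list(NULL, pools))
  for (t in seq_along(keep)) {
    i <- keep[t]
    ri <- match(ref_base[i], bases)
    if (is.na(ri)) stop("bad reference base at line ", i)
    others <- setdiff(order(base_tot[i, ], decreasing = TRUE), ri)
    ai <- others[1]
    snps$alt[t] <- bases[ai]
    ref_m[t, ] <- cnt[i, , ri]
    alt_m[t, ] <- cnt[i, , ai]
  }
  pool_counts(snps = snps, ref = ref_m, alt = alt_m)
}

#' @rdname read_sync
#' @export
write_sync <- function(counts, path) {
  stopifnot(inherits(counts, "pool_counts"))
  bases <- c("A", "T", "C", "G")
  ri <- match(counts$snps$ref, bases)
  ai <- match(counts$snps$alt, bases)
  n <- nrow(counts$snps)
  cols <- vapply(seq_along(counts$pools), function(j) {
    m <- matrix(0L, n, 6L)
    m[cbind(seq_len(n), ri)] <- counts$ref[, j]
    m[cbind(seq_len(n), ai)] <- counts$alt[, j]
    apply(m, 1L, paste, collapse = ":")
  }, character(n))
  df <- cbind(counts$snps[, c("chrom", "pos", "ref")], cols)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read individual genotypes from a VCF
#'
#' Parses the GT field of a VCF 4.x file into alternate-allele dosages;
#' phased records (`|` separator throughout) also populate the haplotype
#' matrix.
#'
#' @param path VCF file path (plain or gzipped).
#' @return a [genotype_matrix()] (individuals x SNPs).
#' @export
read_vcf_genotypes <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  if (ncol(v@gt) < 2 || !grepl("GT", v@gt[1, "FORMAT"]))
    stop("VCF has no GT field")
  gt <- vcfR::extract.gt(v, element = "GT")
  if (is.null(gt)) stop("VCF has no GT field")
  snps <- data.frame(chrom = vcfR::getCHROM(v), pos = vcfR::getPOS(v),
                     ref = vcfR::getREF(v), alt = vcfR::getALT(v),
                     stringsAsFactors = FALSE)
  phased <- all(grepl("|", gt, fixed = TRUE) | is.na(gt))
  a1 <- substr(gt, 1, 1); a2 <- substr(gt, 3, 3)
  to_int <- function(z) { z[z == "."] <- NA; as.integer(z) }
  m1 <- matrix(to_int(a1), nrow = nrow(gt)); m2 <- matrix(to_int(a2), nrow = nrow(gt))
  geno <- t(m1 + m2)                       # individuals x SNPs
  rownames(geno) <- colnames(gt)
  haps <- NULL
  if (phased) {
    n_ind <- nrow(geno)
    haps <- matrix(0L, 2L * n_ind, ncol(geno))
    haps[seq(1, 2 * n_ind, 2), ] <- t(m1)
    haps[seq(2, 2 * n_ind, 2), ] <- t(m2)
  }
  genotype_matrix(geno = geno, snps = snps, haplotypes = haps,
                  phased = phased)
}

#' Write genotypes (and phase, if present) to a VCF file
#'
#' @param g a [genotype_matrix()].
#' @param path output path (plain text).
#' @return `path`, invisibly.
#' @export
write_vcf_genotypes <- function(g, path) {
  stopifnot(inherits(g, "genotype_matrix"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
               paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                       "INFO", "FORMAT", rownames(g$geno)), collapse = "\t")),
             con)
  sep <- if (isTRUE(g$phased)) "|" else "/"
  n_ind <- nrow(g$geno)
  for (s in seq_len(ncol(g$geno))) {
    if (!is.null(g$haplotypes)) {
      a1 <- g$haplotypes[seq(1, 2 * n_ind, 2), s]
      a2 <- g$haplotypes[seq(2, 2 * n_ind, 2), s]
    } else {
      gg <- g$geno[, s]
      a1 <- as.integer(gg >= 1); a2 <- as.integer(gg == 2)
    }
    gt <- paste(ifelse(is.na(a1), ".", a1), ifelse(is.na(a2), ".", a2),
                sep = sep)
    writeLines(paste(c(g$snps$chrom[s], g$snps$pos[s], ".", g$snps$ref[s],
                       g$snps$alt[s], ".", "PASS", ".", "GT", gt),
                     collapse = "\t"), con)
  }
  invisible(path)
}

#' Read and write BED intervals
#'
#' BED is half-open and 0-based; the internal convention is 1-based
#' inclusive, so a BED record `s1 0 1000` becomes the interval
#' `s1:1-1000`.  The conversion is an exact bijection.
#'
#' @param path file path.
#' @param intervals data frame `chrom`, `start`, `end` (1-based
#'   inclusive), plus optional extra columns written as BED names/scores.
#' @return `read_bed_intervals()` returns a data frame `chrom`, `start`,
#'   `end` in internal coordinates (plus a `name` column if present).
#' @export
read_bed_intervals <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  raw <- utils::read.table(path, sep = "\t", header = FALSE,
                           stringsAsFactors = FALSE)
  if (ncol(raw) < 3) stop("BED needs >= 3 columns")
  if (any(raw[[3]] <= raw[[2]])) stop("BED end <= start")
  out <- data.frame(chrom = raw[[1]], start = raw[[2]] + 1L, end = raw[[3]],
                    stringsAsFactors = FALSE)
  if (ncol(raw) >= 4) out$name <- raw[[4]]
  out
}

#' @rdname read_bed_intervals
#' @export
write_bed <- function(intervals, path) {
  stopifnot(all(c("chrom", "start", "end") %in% names(intervals)),
            all(intervals$start >= 1), all(intervals$end >= intervals$start))
  df <- data.frame(intervals$chrom, intervals$start - 1L, intervals$end)
  extra <- setdiff(names(intervals), c("chrom", "start", "end"))
  for (e in extra) df[[e]] <- intervals[[e]]
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read and write the per-pool metadata table
#'
#' Tab-separated with columns `pool`, `n_fish`, `salinity` (permil),
#' `season` (spring/summer/autumn/unknown) and `superpool`.
#'
#' @param pops the metadata data frame.
#' @param path file path.
#' @return `read_metadata()` returns the validated data frame.
#' @export
read_metadata <- function(path) {
  pops <- utils::read.table(path, sep = "\t", header = TRUE,
                            stringsAsFactors = FALSE)
  validate_pop_table(pops)
}

#' @rdname read_metadata
#' @export
write_metadata <- function(pops, path) {
  validate_pop_table(pops)
  utils::write.table(pops, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read and write a depth matrix as TSV (+ mappability BED)
#'
#' @param dm a [depth_matrix()].
#' @param path TSV path; columns `chrom`, `start`, `end`, `mappability`,
#'   then one column per pool.
#' @return `read_depth_matrix()` returns a [depth_matrix()].
#' @export
write_depth_matrix <- function(dm, path) {
  stopifnot(inherits(dm, "depth_matrix"))
  df <- cbind(dm$windows, mappability = dm$mappability,
              as.data.frame(dm$depth))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_depth_matrix
#' @export
read_depth_matrix <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE, check.names = FALSE)
  depth_matrix(windows = df[, c("chrom", "start", "end")],
               depth = as.matrix(df[, -(1:4), drop = FALSE]),
               mappability = df$mappability)
}

#' Write a phylogenetic tree in Newick format
#'
#' Thin wrapper over [ape::write.tree()] so every tree produced by the
#' package round-trips through standard Newick with branch lengths.
#'
#' @param tree an [ape::phylo] object.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_newick <- function(tree, path) {
  stopifnot(inherits(tree, "phylo"))
  ape::write.tree(tree, file = path)
  invisible(path)
}
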
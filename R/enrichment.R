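#' Annotation-category enrichment across dAF bins
#'
#' Sorts SNPs into absolute allele-frequency-difference (dAF) bins of
#' width `bin_width` (left-closed; a value on an edge goes right, and
#' the last bin is closed on both sides so dAF = 1 is kept) and, for
#' each functional category in each bin, compares the observed SNP count
#' with the expected count p(category) x n(bin).  M = log2(obs/exp) is
#' the enrichment; significance is a 1-df chi-square on the 2 x 2 table
#' (in-bin vs out-of-bin x in-category vs out-of-category).  Cells with
#' expected < 5 are flagged.
#'
#' @param daf per-SNP dAF values in `[0, 1]` (SNPs with missing calls in
#'   any population must be removed upstream).
#' @param categories per-SNP category labels.
#' @param category_props named genome-wide category proportions; `NULL`
#'   estimates them from all retained SNPs.
#' @param bin_width dAF bin width (default 0.05).
#' @param merge_utr combine the 5'UTR and 3'UTR classes into one `UTR`
#'   class?
#' @return data frame of class `enrichment_table`: `category`,
#'   `bin_left`, `bin_right`, `n_bin`, `observed`, `expected`, `M`,
#'   `chi2`, `p`, `low_expected`.
#' @export
compute_daf_bins <- function(daf, categories, category_props = NULL,
                             bin_width = 0.05, merge_utr = FALSE) {
  stopifnot(length(daf) == length(categories),
            all(daf >= 0 & daf <= 1, na.rm = TRUE))
  ok <- !is.na(daf) & !is.na(categories)
  daf <- daf[ok]; categories <- as.character(categories[ok])
  if (merge_utr)
    categories[categories %in% c("5'UTR", "3'UTR")] <- "UTR"
  cats <- sort(unique(categories))
  if (is.null(category_props)) {
    category_props <- table(categories) / length(categories)
    category_props <- stats::setNames(as.numeric(category_props),
                                      names(category_props))
  } else if (merge_utr && !"UTR" %in% names(category_props) &&
             all(c("5'UTR", "3'UTR") %in% names(category_props))) {
    category_props <- c(category_props,
                        UTR = unname(category_props["5'UTR"] +
                                       category_props["3'UTR"]))
  }
  if (!all(cats %in% names(category_props)))
    stop("category missing from genome proportions: ",
         paste(setdiff(cats, names(category_props)), collapse = ", "))
  n_bins <- round(1 / bin_width)
  bin <- pmin(floor(daf / bin_width), n_bins - 1L) + 1L  # last bin catches 1
  N <- length(daf)
  rows <- list()
  for (b in seq_len(n_bins)) {
    in_bin <- bin == b
    n_bin <- sum(in_bin)
    for (cat in cats) {
      in_cat <- categories == cat
      obs <- sum(in_bin & in_cat)
      expd <- category_props[[cat]] * n_bin
      a <- as.numeric(obs); bb <- n_bin - obs
      n_cat <- as.numeric(sum(in_cat))
      cc <- n_cat - obs; dd <- N - n_bin - cc
      chi2 <- p <- NA_real_
      if (n_bin > 0 && n_cat > 0 && n_bin < N) {
        e_a <- n_bin * n_cat / N
        e_b <- n_bin - e_a
        e_c <- n_cat - e_a
        e_d <- N - n_bin - e_c
        chi2 <- (a - e_a)^2 / e_a + (bb - e_b)^2 / e_b +
          (cc - e_c)^2 / e_c + (dd - e_d)^2 / e_d
        p <- stats::pchisq(chi2, df = 1, lower.tail = FALSE)
      }
      rows[[length(rows) + 1L]] <- data.frame(
        category = cat, bin_left = round((b - 1L) * bin_width, 10),
        bin_right = round(b * bin_width, 10), n_bin = n_bin, observed = obs,
        expected = unname(expd), M = log2(obs / expd), chi2 = chi2, p = p,
        low_expected = expd < 5, stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  class(out) <- c("enrichment_table", "data.frame")
  out
}

#' Per-category enrichment trajectory and high-dAF gene counts
#'
#' @param table a [compute_daf_bins()] result.
#' @param daf,genes optional per-SNP dAF and gene ids (same length); if
#'   supplied with `categories`, the number of distinct genes hit by
#'   SNPs of `count_category` with dAF above `daf_cut` is reported.
#' @param categories optional per-SNP categories matching `daf`.
#' @param count_category category counted in the gene tally.
#' @param daf_cut dAF cutoff for the gene tally.
#' @return list with `trajectory` (wide data frame of M by bin x
#'   category) and, when gene ids were given, `n_high_daf_snps` and
#'   `n_genes`.
#' @export
enrichment_summary <- function(table, daf = NULL, genes = NULL,
                               categories = NULL,
                               count_category = "non-synonymous",
                               daf_cut = 0.5) {
  stopifnot(inherits(table, "enrichment_table"))
  traj <- stats::reshape(
    as.data.frame(table)[, c("category", "bin_left", "M")],
    idvar = "bin_left", timevar = "category", direction = "wide")
  names(traj) <- sub("^M\\.", "", names(traj))
  out <- list(trajectory = traj[order(traj$bin_left), ])
  if (!is.null(genes) && !is.null(daf) && !is.null(categories)) {
    hit <- !is.na(daf) & daf > daf_cut & categories == count_category &
      !is.na(genes)
    out$n_high_daf_snps <- sum(hit)
    out$n_genes <- length(unique(genes[hit]))
  }
  out
}
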
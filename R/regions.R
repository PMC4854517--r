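#' Rescale SNP coordinates by subtracting assembly gaps
#'
#' Each position is reduced by the total length of assembly gaps that
#' precede it on its scaffold, so physical distances used for locus
#' clustering are not inflated by runs of unresolved sequence.
#'
#' @param positions sorted 1-based positions on one scaffold.
#' @param gaps data frame `start`, `end` (1-based inclusive,
#'   non-overlapping, sorted) of the scaffold's gaps; `NULL` or empty
#'   for none.
#' @return rescaled positions, same order.
#' @examples
#' rescale_coordinates(5000, data.frame(start = 2000, end = 2999))  # 4000
#' @export
rescale_coordinates <- function(positions, gaps = NULL) {
  if (is.null(gaps) || nrow(gaps) == 0) return(positions)
  stopifnot(all(gaps$end >= gaps$start), !is.unsorted(gaps$start))
  inside <- vapply(positions, function(p)
    any(p >= gaps$start & p <= gaps$end), logical(1))
  if (any(inside))
    stop("position(s) inside an assembly gap: ",
         paste(utils::head(positions[inside], 3), collapse = ", "))
  glen <- gaps$end - gaps$start + 1L
  cum <- cumsum(glen)
  k <- findInterval(positions, gaps$end)
  positions - ifelse(k > 0, cum[pmax(k, 1L)], 0L)
}

#' Cluster significant SNPs into independent loci
#'
#' SNPs below `p_cut` are single-linkage clustered on gap-rescaled
#' distance within each scaffold: consecutive significant SNPs separated
#' by at least `min_sep` (with no significant SNP between them) start a
#' new locus.  Scaffolds never merge, except through an explicit
#' `merge_map`.  Loci are reported in original coordinates.
#'
#' @param stats a [scan_contrast()] result (or any data frame with
#'   `chrom`, `pos`, `p`).
#' @param gaps optional named list of per-scaffold gap tables (see
#'   [rescale_coordinates()]), or a data frame with a `chrom` column.
#' @param p_cut SNP inclusion threshold (default the stringent 1e-20).
#' @param min_sep minimum rescaled separation defining independence (bp).
#' @param merge_map optional data frame `from`, `to`, `offset`: scaffold
#'   `from` is relocated onto `to` with positions shifted by `offset`
#'   (manual curation of scaffolds known to overlap).
#' @return data frame of class `region_calls`: `chrom`, `start`, `end`,
#'   `n_snps`, `peak_p`, `type`.
#' @export
cluster_independent_loci <- function(stats, gaps = NULL, p_cut = 1e-20,
                                     min_sep = 2e4, merge_map = NULL) {
  stopifnot(all(c("chrom", "pos", "p") %in% names(stats)))
  sig <- stats[!is.na(stats$p) & stats$p < p_cut, c("chrom", "pos", "p")]
  if (!is.null(merge_map)) {
    for (r in seq_len(nrow(merge_map))) {
      hit <- sig$chrom == merge_map$from[r]
      sig$pos[hit] <- sig$pos[hit] + merge_map$offset[r]
      sig$chrom[hit] <- merge_map$to[r]
    }
  }
  out <- list()
  if (is.data.frame(gaps) && "chrom" %in% names(gaps))
    gaps <- split(gaps[, c("start", "end")], gaps$chrom)
  for (sc in unique(sig$chrom)) {
    d <- sig[sig$chrom == sc, ]
    d <- d[order(d$pos), ]
    g <- if (is.null(gaps)) NULL else gaps[[sc]]
    rp <- rescale_coordinates(d$pos, g)
    new_locus <- c(TRUE, diff(rp) >= min_sep)
    id <- cumsum(new_locus)
    for (k in unique(id)) {
      dd <- d[id == k, ]
      out[[length(out) + 1L]] <- data.frame(
        chrom = sc, start = min(dd$pos), end = max(dd$pos),
        n_snps = nrow(dd), peak_p = min(dd$p), type = "independent_locus",
        stringsAsFactors = FALSE)
    }
  }
  res <- if (length(out)) do.call(rbind, out) else
    data.frame(chrom = character(0), start = integer(0), end = integer(0),
               n_snps = integer(0), peak_p = numeric(0), type = character(0),
               stringsAsFactors = FALSE)
  res <- res[order(res$chrom, res$start), ]
  rownames(res) <- NULL
  class(res) <- c("region_calls", "data.frame")
  res
}

#' @export
print.region_calls <- function(x, ...) {
  cat(sprintf("%d region call(s)\n", nrow(x)))
  if (nrow(x)) print.data.frame(utils::head(as.data.frame(x), 10))
  invisible(x)
}
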
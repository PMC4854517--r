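#' Normalise a depth matrix against a reference pool
#'
#' Every pool's windows are multiplied by (reference pool mean depth /
#' pool mean depth), so all pool means equal the reference mean
#' afterwards; the reference pool (by convention the one with the
#' highest average depth) is unchanged.  Idempotent.
#'
#' @param dm a [depth_matrix()].
#' @param reference_pool pool id; `NULL` picks the pool with the highest
#'   mean depth.
#' @return the normalised [depth_matrix()], with attribute
#'   `reference_pool`.
#' @export
normalize_depth <- function(dm, reference_pool = NULL) {
  stopifnot(inherits(dm, "depth_matrix"))
  means <- colMeans(dm$depth)
  if (is.null(reference_pool))
    reference_pool <- names(which.max(means))
  if (!reference_pool %in% colnames(dm$depth))
    stop("reference pool not present: ", reference_pool)
  if (any(means == 0)) stop("pool with zero mean depth")
  f <- means[reference_pool] / means
  dm$depth <- sweep(dm$depth, 2L, f, `*`)
  attr(dm, "reference_pool") <- reference_pool
  dm
}

#' Per-window two-group depth ANOVA
#'
#' One-way analysis of variance of normalised window depth across the
#' two contrast groups, computed per window; windows whose all-pool mean
#' depth falls below `low_floor` (default 20% of the overall mean) are
#' excluded first, with the excluded count reported.  M is the log2
#' ratio of group-B to group-A mean depth.
#'
#' @param dm a normalised [depth_matrix()].
#' @param groups per-pool group labels (two levels; order of the sorted
#'   levels fixes the M orientation: B over A).
#' @param low_floor absolute depth floor; `NULL` uses
#'   `low_frac * mean(depth)`.
#' @param low_frac fraction of the overall mean used when `low_floor`
#'   is `NULL`.
#' @return data frame: window coordinates, `mean_A`, `mean_B`, `M`,
#'   `F`, `p`, `mappability`; one row per retained window.
#' @export
window_anova <- function(dm, groups, low_floor = NULL, low_frac = 0.2) {
  stopifnot(inherits(dm, "depth_matrix"),
            length(groups) == ncol(dm$depth))
  lev <- sort(unique(as.character(groups)))
  if (length(lev) != 2) stop("need exactly two groups")
  nA <- sum(groups == lev[1]); nB <- sum(groups == lev[2])
  stopifnot(nA >= 2, nB >= 2)
  if (is.null(low_floor)) low_floor <- low_frac * mean(dm$depth)
  keep <- rowMeans(dm$depth) >= low_floor
  message(sum(!keep), " window(s) excluded due to low depth")
  D <- dm$depth[keep, , drop = FALSE]
  A <- D[, groups == lev[1], drop = FALSE]
  B <- D[, groups == lev[2], drop = FALSE]
  mA <- rowMeans(A); mB <- rowMeans(B)
  n <- nA + nB
  grand <- (nA * mA + nB * mB) / n
  ssb <- nA * (mA - grand)^2 + nB * (mB - grand)^2
  ssw <- rowSums((A - mA)^2) + rowSums((B - mB)^2)
  Fv <- (ssb / 1) / (ssw / (n - 2))
  p <- stats::pf(Fv, 1, n - 2, lower.tail = FALSE)
  zero <- ssw == 0 & ssb == 0   # no variance anywhere: no evidence
  Fv[zero] <- 0; p[zero] <- 1
  out <- cbind(dm$windows[keep, , drop = FALSE],
               data.frame(mean_A = mA, mean_B = mB,
                          M = log2(mB / mA), F = Fv, p = p,
                          mappability = dm$mappability[keep]))
  attr(out, "groups") <- stats::setNames(lev, c("A", "B"))
  rownames(out) <- NULL
  out
}

#' Call CNV regions from window ANOVA results
#'
#' Windows passing both the p-value and |M| cuts are merged into regions
#' when adjacent or separated by at most one non-significant window on
#' the same scaffold.  Region mappability is the mean over all windows
#' in the region span; regions below `map_cut` are flagged, not removed.
#'
#' @param ws a [window_anova()] result.
#' @param p_cut ANOVA p-value cutoff.
#' @param m_cut cutoff on |M|.
#' @param map_cut mappability flag threshold.
#' @param max_gap maximum number of intervening non-significant windows
#'   still merged.
#' @return data frame of class `region_calls`: `chrom`, `start`, `end`,
#'   `n_windows`, `peak_p`, `M`, `mappability`, `low_mappability`,
#'   `type`.
#' @export
call_cnv_regions <- function(ws, p_cut = 0.001, m_cut = 0.6, map_cut = 0.5,
                             max_gap = 1) {
  sig <- which(!is.na(ws$p) & ws$p < p_cut & abs(ws$M) > m_cut)
  rows <- list()
  if (length(sig)) {
    win_size <- ws$end[1] - ws$start[1] + 1
    sc <- ws$chrom[sig]
    # windows are on a fixed grid: index within scaffold by start coordinate
    idx <- (ws$start[sig] - 1) %/% win_size
    o <- order(sc, idx)
    sig <- sig[o]; sc <- sc[o]; idx <- idx[o]
    new_region <- c(TRUE, sc[-1] != sc[-length(sc)] |
                      diff(idx) > max_gap + 1)
    id <- cumsum(new_region)
    for (k in unique(id)) {
      i <- sig[id == k]
      span <- which(ws$chrom == ws$chrom[i[1]] &
                      ws$start >= min(ws$start[i]) &
                      ws$end <= max(ws$end[i]))
      mp <- mean(ws$mappability[span])
      rows[[length(rows) + 1L]] <- data.frame(
        chrom = ws$chrom[i[1]], start = min(ws$start[i]),
        end = max(ws$end[i]), n_windows = length(i),
        peak_p = min(ws$p[i]), M = ws$M[i[which.min(ws$p[i])]],
        mappability = mp, low_mappability = mp < map_cut,
        type = "cnv", stringsAsFactors = FALSE)
    }
  }
  res <- if (length(rows)) do.call(rbind, rows) else
    data.frame(chrom = character(0), start = integer(0), end = integer(0),
               n_windows = integer(0), peak_p = numeric(0), M = numeric(0),
               mappability = numeric(0), low_mappability = logical(0),
               type = character(0), stringsAsFactors = FALSE)
  class(res) <- c("region_calls", "data.frame")
  res
}
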
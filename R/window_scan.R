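#' Map alignment columns to ungapped reference coordinates
#'
#' Each alignment column is assigned the 1-based position of the reference
#' (E. coli) base at that column; columns where the reference carries a gap
#' take the position of the nearest preceding reference base. Columns before
#' the first reference base map to 0 and are flagged.
#'
#' @param alignment alignment `data.frame` (`id`, `gapped_sequence`).
#' @param reference_id id of the designated reference record.
#' @return integer vector, one entry per column; attribute `"flagged"` is a
#'   logical vector marking columns before the first reference base.
#' @export
map_to_reference_coords <- function(alignment, reference_id) {
  i <- match(reference_id, alignment$id)
  if (is.na(i)) stop("reference id '", reference_id, "' not in alignment")
  ref <- strsplit(alignment$gapped_sequence[i], "", fixed = TRUE)[[1L]]
  pos <- cumsum(ref != "-")
  flagged <- pos == 0L
  attr(pos, "flagged") <- flagged
  pos
}

#' Consensus of a window defined by mismatch-tolerant frequency
#'
#' Among the slices actually observed in the window, the frequency of a
#' distinct slice is the number of member slices within `max_mm` mismatches
#' of it; the consensus is the most frequent slice. The gap `-` is a fifth
#' symbol; ambiguity codes mismatch every symbol including themselves. Ties
#' are broken lexicographically with `-` ordered before `A`.
#'
#' @param slices character vector of equal-width window slices.
#' @param max_mm mismatch allowance (default 1).
#' @return list with `consensus` and `consensus_freq`.
#' @export
window_consensus <- function(slices, max_mm = 1L) {
  if (length(slices) == 0L) stop("empty slice list")
  if (length(unique(nchar(slices))) != 1L) stop("slices differ in width")
  cnt <- table(slices)
  distinct <- sort(names(cnt), method = "radix")
  counts <- as.integer(cnt[distinct])
  if (length(distinct) == 1L) {
    return(list(consensus = distinct, consensus_freq = counts))
  }
  dm <- .char_matrix(distinct)
  freq <- vapply(seq_along(distinct), function(i) {
    sum(counts[.dist_to(dm, dm[i, ]) <= max_mm])
  }, integer(1))
  best <- which.max(freq) # first maximum in lexicographic order
  list(consensus = distinct[[best]], consensus_freq = freq[[best]])
}

#' Per-phylum coverage rate of a consensus within a mismatch allowance
#'
#' @param consensus window consensus string.
#' @param slices member slices (same width as the consensus).
#' @param phyla phylum label per slice (`NA` excluded).
#' @param max_mm mismatch allowance (default 1).
#' @return named numeric vector: percentage of members within `max_mm`
#'   mismatches, per phylum with at least one member.
#' @export
phylum_coverage_rate <- function(consensus, slices, phyla, max_mm = 1L) {
  stopifnot(length(slices) == length(phyla))
  if (nchar(consensus) != nchar(slices[[1L]])) {
    stop("consensus width differs from slice width")
  }
  has <- !is.na(phyla) & nzchar(phyla)
  if (!any(has)) return(stats::setNames(numeric(0), character(0)))
  d <- .dist_to(.char_matrix(slices[has]),
                strsplit(consensus, "", fixed = TRUE)[[1L]])
  ok <- d <= max_mm
  agg <- tapply(ok, phyla[has], function(z) 100 * mean(z))
  stats::setNames(as.numeric(agg), names(agg))
}

#' Display bin of a coverage percentage
#'
#' Bins follow the conventional conservation-plot palette: black below 50,
#' blue below 80, green below 90, yellow below 100 and red at exactly 100.
#'
#' @param coverage numeric vector of percentages in `[0, 100]`.
#' @return character vector of bin names.
#' @export
bin_coverage <- function(coverage) {
  ifelse(coverage < 50, "black",
  ifelse(coverage < 80, "blue",
  ifelse(coverage < 90, "green",
  ifelse(coverage < 100, "yellow", "red"))))
}

#' Sequence variability of a window, in bits
#'
#' Per column, empirical frequencies over the five symbols A, C, G, T and
#' `-` are formed (ambiguity codes are excluded and the counts
#' renormalized), the column score is the Shannon entropy in bits (or the
#' relative entropy against the uniform five-symbol background with
#' `method = "kl_uniform"`), and the window variability is the sum of
#' column scores.
#'
#' @param slices character vector of equal-width window slices.
#' @param method `"shannon"` (default) or `"kl_uniform"`.
#' @return non-negative numeric scalar (bits).
#' @export
window_variability <- function(slices, method = c("shannon", "kl_uniform")) {
  method <- match.arg(method)
  if (length(slices) == 0L) stop("empty slice list")
  m <- .char_matrix(slices)
  col_score <- vapply(seq_len(ncol(m)), function(j) {
    x <- m[, j]
    x <- x[x %in% .CORE5]
    if (length(x) == 0L) return(0)
    p <- as.numeric(table(x)) / length(x)
    h <- -sum(p * log2(p))
    if (method == "shannon") h else log2(5) - h
  }, numeric(1))
  sum(col_score)
}

#' Sliding-window scan of a labelled alignment
#'
#' Slides a `width`-nt window with a step of 1 column across the alignment,
#' computing for each start column the mismatch-tolerant consensus, its
#' frequency, the per-phylum coverage rate, the entropy variability, and
#' the reference (E. coli) coordinate of the window start.
#'
#' @param alignment alignment `data.frame` (`id`, `gapped_sequence`).
#' @param taxonomy taxonomy `data.frame` mapping ids to lineages; records
#'   whose id does not resolve to a phylum contribute to the consensus but
#'   not to any coverage group.
#' @param width window width in columns (default 15).
#' @param max_mm mismatch allowance (default 1).
#' @param reference_id id of the reference record for coordinates.
#' @param method variability method, see [window_variability()].
#' @return `data.frame` with one row per window: `start_col`, `ref_pos`,
#'   `ref_pos_flagged`, `consensus`, `consensus_freq`, `variability`, and
#'   one `cov_<phylum>` column per phylum.
#' @export
scan_windows <- function(alignment, taxonomy = NULL, width = 15L, max_mm = 1L,
                         reference_id, method = "shannon") {
  L <- nchar(alignment$gapped_sequence[[1L]])
  if (L < width) stop("alignment shorter than window width")
  colmap <- map_to_reference_coords(alignment, reference_id)
  flagged <- attr(colmap, "flagged")

  phyla <- rep(NA_character_, nrow(alignment))
  if (!is.null(taxonomy)) {
    idx <- match(alignment$id, taxonomy$id)
    phyla[!is.na(idx)] <- taxonomy$phylum[idx[!is.na(idx)]]
  }
  phy_levels <- sort(unique(phyla[!is.na(phyla) & nzchar(phyla)]))

  m <- .char_matrix(alignment$gapped_sequence)
  n_win <- L - width + 1L
  starts <- seq_len(n_win)

  consensus <- character(n_win)
  freq <- integer(n_win)
  vari <- numeric(n_win)
  cov <- matrix(NA_real_, n_win, length(phy_levels),
                dimnames = list(NULL, phy_levels))
  for (s in starts) {
    sub <- m[, s:(s + width - 1L), drop = FALSE]
    slices <- do.call(paste0, as.data.frame(sub, stringsAsFactors = FALSE))
    wc <- window_consensus(slices, max_mm = max_mm)
    consensus[s] <- wc$consensus
    freq[s] <- wc$consensus_freq
    vari[s] <- window_variability(slices, method = method)
    if (length(phy_levels)) {
      pc <- phylum_coverage_rate(wc$consensus, slices, phyla, max_mm = max_mm)
      cov[s, names(pc)] <- pc
    }
  }
  out <- data.frame(start_col = starts,
                    ref_pos = as.integer(colmap[starts]),
                    ref_pos_flagged = flagged[starts],
                    consensus = consensus,
                    consensus_freq = freq,
                    variability = vari,
                    stringsAsFactors = FALSE)
  if (length(phy_levels)) {
    covdf <- as.data.frame(cov)
    names(covdf) <- paste0("cov_", phy_levels)
    out <- cbind(out, covdf)
  }
  attr(out, "width") <- as.integer(width)
  attr(out, "max_mm") <- as.integer(max_mm)
  out
}

#' Select conserved candidate windows
#'
#' A window is a primer candidate when its consensus is a synthesizable
#' oligo (gap-free and ambiguity-free) and its coverage is at least
#' `min_coverage` percent in at least `min_phylum_fraction` of the phyla.
#' Optionally, windows outside a reference-position keep-interval (regions
#' missing from many database records, or beyond read reach) are dropped.
#'
#' @param windows output of [scan_windows()].
#' @param min_coverage per-phylum coverage threshold, percent (default 90).
#' @param min_phylum_fraction fraction of phyla that must reach the
#'   threshold (default 0.9).
#' @param ref_pos_range optional `c(lo, hi)` keep-interval on `ref_pos`;
#'   flagged (pre-reference) windows are always dropped when set.
#' @return the selected subset, ordered by `start_col`.
#' @export
select_candidates <- function(windows, min_coverage = 90,
                              min_phylum_fraction = 0.9,
                              ref_pos_range = NULL) {
  concrete <- .is_concrete(windows$consensus)
  covcols <- grep("^cov_", names(windows), value = TRUE)
  if (length(covcols)) {
    covmat <- as.matrix(windows[, covcols, drop = FALSE])
    frac <- rowMeans(covmat >= min_coverage, na.rm = TRUE)
    ok_cov <- !is.na(frac) & frac >= min_phylum_fraction
  } else {
    ok_cov <- rep(TRUE, nrow(windows))
  }
  keep <- concrete & ok_cov
  if (!is.null(ref_pos_range)) {
    keep <- keep & !windows$ref_pos_flagged &
      windows$ref_pos >= ref_pos_range[[1L]] &
      windows$ref_pos <= ref_pos_range[[2L]]
  }
  out <- windows[keep, , drop = FALSE]
  out[order(out$start_col), , drop = FALSE]
}

#' Write a window table to TSV
#' @param windows output of [scan_windows()].
#' @param path output file.
#' @export
write_windows_tsv <- function(windows, path) {
  utils::write.table(windows, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
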
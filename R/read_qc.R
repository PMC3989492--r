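#' Read a FASTQ file into a read table
#'
#' @param path FASTQ file (Sanger Phred+33 qualities).
#' @return `data.frame` with columns `id`, `sequence`, `quality`.
#' @export
read_fastq_reads <- function(path) {
  # the reader warns about dropped metadata columns on plain FASTQ; benign
  x <- suppressWarnings(Biostrings::readQualityScaledDNAStringSet(path))
  data.frame(id = names(x),
             sequence = as.character(x),
             quality = as.character(Biostrings::quality(x)),
             stringsAsFactors = FALSE)
}

#' Write a read table to FASTQ (Sanger Phred+33)
#' @param reads `data.frame` with `id`, `sequence`, `quality`.
#' @param path output file.
#' @export
write_fastq_reads <- function(reads, path) {
  x <- Biostrings::QualityScaledDNAStringSet(
    Biostrings::DNAStringSet(reads$sequence),
    Biostrings::PhredQuality(reads$quality)
  )
  names(x) <- reads$id
  Biostrings::writeQualityScaledXStringSet(x, path)
  invisible(path)
}

#' Quality-filter long-read amplicon reads
#'
#' Removes reads that (in this fixed rule order, each read counted once
#' under its first rule): (1) contain any non-A/C/G/T base; (2) are shorter
#' than `len_min` or longer than `len_max`; (3) have an arithmetic mean
#' Phred quality strictly below `min_mean_q` (a mean of exactly
#' `min_mean_q` is kept). Reads without qualities cannot be scored and are
#' removed, counted separately as `unscorable`.
#'
#' @param reads read `data.frame` (`id`, `sequence`, `quality`).
#' @param len_min,len_max length bounds, nt (inclusive).
#' @param min_mean_q mean-quality cutoff (default 20); `NULL` disables the
#'   quality rule.
#' @return list with `kept` and `report` (named counts `ambiguity`,
#'   `length`, `quality`, `unscorable`, `kept`).
#' @export
filter_amplicon_reads <- function(reads, len_min, len_max, min_mean_q = 20) {
  ambig <- !.is_concrete(reads$sequence)
  len <- nchar(reads$sequence)
  bad_len <- len < len_min | len > len_max
  if (is.null(min_mean_q)) {
    unscorable <- rep(FALSE, nrow(reads))
    low_q <- rep(FALSE, nrow(reads))
  } else {
    q <- reads$quality
    unscorable <- is.na(q) | !nzchar(q)
    meanq <- rep(NA_real_, nrow(reads))
    meanq[!unscorable] <- vapply(q[!unscorable],
                                 function(s) mean(.phred(s)), numeric(1),
                                 USE.NAMES = FALSE)
    low_q <- !unscorable & meanq < min_mean_q
  }
  rule <- ifelse(ambig, "ambiguity",
          ifelse(bad_len, "length",
          ifelse(low_q, "quality",
          ifelse(unscorable, "unscorable", "keep"))))
  kept <- reads[rule == "keep", , drop = FALSE]
  list(kept = kept,
       report = c(ambiguity = sum(rule == "ambiguity"),
                  length = sum(rule == "length"),
                  quality = sum(rule == "quality"),
                  unscorable = sum(rule == "unscorable"),
                  kept = nrow(kept)))
}

# best qualifying offset of `oligo` in `seq`, restricted to offsets in
# [lo, hi]; returns the offset with the fewest mismatches (ties broken
# towards `prefer`, "first" or "last"), or NA when none is within max_mm
.find_site <- function(oligo, seq, max_mm, lo, hi, prefer = "first") {
  prof <- .mm_profile(oligo, seq)
  if (length(prof) == 0L) return(NA_integer_)
  lo <- max(1L, lo)
  hi <- min(length(prof), hi)
  if (lo > hi) return(NA_integer_)
  prof <- prof[lo:hi]
  best <- min(prof)
  if (best > max_mm) return(NA_integer_)
  at <- which(prof == best)
  off <- if (prefer == "first") at[[1L]] else at[[length(at)]]
  lo + off - 1L
}

#' Trim primer sequences from amplicon reads, normalizing orientation
#'
#' The forward oligo is searched (within `max_mm` mismatches) starting in
#' the first `search_window` nt of the read; if absent there, the read's
#' reverse complement is searched and, when found, the read is flipped to
#' the sense strand first. Everything through the end of the forward match
#' is removed. The reverse complement of the reverse oligo is then searched
#' in the last `search_window` nt and removed when present. Reads with no
#' forward-oligo site on either strand are dropped.
#'
#' @param reads read `data.frame` (`id`, `sequence`, `quality`; quality may
#'   be `NA`).
#' @param forward_oligo,reverse_oligo concrete synthesizable oligos (the
#'   reverse oligo as it would be ordered, i.e. reverse-complement of the
#'   sense-strand site).
#' @param max_mm mismatch allowance (default 2).
#' @param search_window how far from each end a primer may start (default
#'   30 nt).
#' @return list with `kept` (trimmed reads plus an `orientation` column,
#'   `"as-is"` or `"flipped"`), `dropped` (reads with no forward site) and
#'   `report` (named counts `kept`, `flipped`, `dropped_no_forward`).
#' @export
trim_primers <- function(reads, forward_oligo, reverse_oligo,
                         max_mm = 2L, search_window = 30L) {
  stopifnot(.is_concrete(forward_oligo), .is_concrete(reverse_oligo))
  wf <- nchar(forward_oligo)
  rc_rev <- revcomp(reverse_oligo)
  wr <- nchar(rc_rev)
  has_q <- "quality" %in% names(reads)

  n <- nrow(reads)
  keep <- logical(n)
  orientation <- character(n)
  seq_out <- character(n)
  qual_out <- rep(NA_character_, n)
  for (i in seq_len(n)) {
    s <- reads$sequence[[i]]
    q <- if (has_q) reads$quality[[i]] else NA_character_
    ori <- "as-is"
    off <- .find_site(forward_oligo, s, max_mm, 1L, search_window, "first")
    if (is.na(off)) {
      s2 <- revcomp(s)
      off <- .find_site(forward_oligo, s2, max_mm, 1L, search_window, "first")
      if (!is.na(off)) {
        s <- s2
        if (!is.na(q)) q <- .reverse_string(q)
        ori <- "flipped"
      }
    }
    if (is.na(off)) next
    start <- off + wf
    L <- nchar(s)
    end <- L
    roff <- .find_site(rc_rev, s, max_mm, L - search_window + 1L,
                       L - wr + 1L, "last")
    if (!is.na(roff) && roff >= start) end <- roff - 1L
    if (start > end) next
    keep[i] <- TRUE
    orientation[i] <- ori
    seq_out[i] <- substr(s, start, end)
    if (!is.na(q)) qual_out[i] <- substr(q, start, end)
  }
  kept <- reads[keep, , drop = FALSE]
  kept$sequence <- seq_out[keep]
  if (has_q) kept$quality <- qual_out[keep]
  kept$orientation <- orientation[keep]
  list(kept = kept,
       dropped = reads[!keep, , drop = FALSE],
       report = c(kept = sum(keep),
                  flipped = sum(orientation[keep] == "flipped"),
                  dropped_no_forward = sum(!keep)))
}

#' Quality-filter short-read pairs
#'
#' A pair is removed when (in this fixed rule order): a mate is missing;
#' either mate failed purity filtering; or either mate carries more than
#' `max_b` bases at the low-quality flag value among its first `head_n`
#' bases (exactly `max_b` such bases is kept).
#'
#' @param pairs `data.frame` with columns `pair_id`, `seq1`, `qual1`,
#'   `purity_ok1`, `seq2`, `qual2`, `purity_ok2`.
#' @param b_flag_quality the Phred value of the read-segment quality
#'   indicator (default 2, the "B" flag of early short-read pipelines).
#' @param head_n how many leading bases to inspect (default 60).
#' @param max_b maximum tolerated flagged bases (default 1).
#' @return list with `kept` and `report` (named counts `missing_mate`,
#'   `purity`, `b_flag`, `kept`).
#' @export
filter_short_read_pairs <- function(pairs, b_flag_quality = 2L,
                                    head_n = 60L, max_b = 1L) {
  n_b <- function(qual) {
    vapply(qual, function(q) {
      if (is.na(q) || !nzchar(q)) return(NA_integer_)
      p <- .phred(q)
      sum(p[seq_len(min(head_n, length(p)))] == b_flag_quality)
    }, integer(1), USE.NAMES = FALSE)
  }
  missing <- is.na(pairs$seq1) | !nzchar(pairs$seq1) |
    is.na(pairs$seq2) | !nzchar(pairs$seq2)
  purity_bad <- !missing & (!pairs$purity_ok1 | !pairs$purity_ok2)
  b1 <- n_b(pairs$qual1)
  b2 <- n_b(pairs$qual2)
  b_bad <- !missing & !purity_bad &
    ((!is.na(b1) & b1 > max_b) | (!is.na(b2) & b2 > max_b))
  keep <- !missing & !purity_bad & !b_bad
  list(kept = pairs[keep, , drop = FALSE],
       report = c(missing_mate = sum(missing),
                  purity = sum(purity_bad),
                  b_flag = sum(b_bad),
                  kept = sum(keep)))
}
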
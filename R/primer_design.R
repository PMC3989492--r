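#' Merge neighbouring candidate windows into longer primer candidates
#'
#' Windows at consecutive reference start positions whose consensus
#' sequences agree on every overlapping base are merged into one candidate
#' spanning their union, extending the primer by one base per window. When
#' a `coverage_fn` is supplied, a merge is accepted only if, for every
#' phylum, the merged candidate's coverage is at least the minimum
#' constituent coverage for that phylum minus `tolerance`; otherwise the
#' run is split greedily left-to-right into the longest acceptable
#' prefixes. Runs are also split wherever consensus sequences disagree on
#' the overlap.
#'
#' @param windows `data.frame` with columns `ref_pos` (window start, 1-based
#'   reference coordinate) and `consensus` (equal-width, gap-free strings),
#'   sorted or sortable by `ref_pos`.
#' @param coverage_fn optional function taking a candidate sequence and
#'   returning a named numeric vector of per-phylum coverage percentages
#'   (evaluated at the prokaryotic mismatch allowance).
#' @param tolerance permitted per-phylum coverage drop, in percentage
#'   points (default 0).
#' @return candidate `data.frame`: `sequence`, `ref_start`, `ref_end`,
#'   `width`, `n_windows`, `provenance` (list column of constituent window
#'   start positions).
#' @export
merge_neighbouring <- function(windows, coverage_fn = NULL, tolerance = 0) {
  stopifnot(all(c("ref_pos", "consensus") %in% names(windows)))
  windows <- windows[order(windows$ref_pos), , drop = FALSE]
  cons <- windows$consensus
  pos <- as.integer(windows$ref_pos)
  if (!all(.is_concrete(cons))) {
    stop("window consensus sequences must be gap-free and ambiguity-free")
  }
  w <- unique(nchar(cons))
  if (length(w) != 1L) stop("windows differ in width")
  n <- length(cons)

  # adjacency: consecutive reference start and agreement on the overlap
  linked <- if (n > 1L) {
    diff(pos) == 1L &
      substr(cons[-n], 2L, w) == substr(cons[-1L], 1L, w - 1L)
  } else {
    logical(0)
  }

  cov_cache <- new.env(parent = emptyenv())
  cov_of <- function(s) {
    if (is.null(coverage_fn)) return(NULL)
    if (!is.null(cov_cache[[s]])) return(cov_cache[[s]])
    v <- coverage_fn(s)
    cov_cache[[s]] <- v
    v
  }
  merged_seq <- function(i, j) {
    if (j == i) return(cons[[i]])
    paste0(cons[[i]], paste(substr(cons[(i + 1L):j], w, w), collapse = ""))
  }
  acceptable <- function(i, j) {
    if (is.null(coverage_fn) || j == i) return(TRUE)
    floors <- Reduce(pmin, lapply(cons[i:j], cov_of))
    merged <- cov_of(merged_seq(i, j))
    shared <- intersect(names(floors), names(merged))
    all(merged[shared] >= floors[shared] - tolerance)
  }

  out <- list()
  i <- 1L
  while (i <= n) {
    j <- i
    while (j < n && linked[[j]] && acceptable(i, j + 1L)) j <- j + 1L
    s <- merged_seq(i, j)
    out[[length(out) + 1L]] <- data.frame(
      sequence = s,
      ref_start = pos[[i]],
      ref_end = pos[[i]] + nchar(s) - 1L,
      width = nchar(s),
      n_windows = j - i + 1L,
      stringsAsFactors = FALSE
    )
    out[[length(out)]]$provenance <- I(list(pos[i:j]))
    i <- j + 1L
  }
  do.call(rbind, out)
}

#' Resolve a degenerate (IUPAC) primer to its best concrete form
#'
#' Enumerates every concrete expansion of the IUPAC primer and returns the
#' variant with the best coverage for the reference records, scored as the
#' unweighted mean of per-phylum genus-majority coverage. Ties go to the
#' lexicographically smallest variant. The report lists every variant's
#' score so any other objective can be audited.
#'
#' @param primer_iupac primer string over the IUPAC nucleotide alphabet.
#' @param records prokaryotic record `data.frame` with genus and phylum.
#' @param max_mm mismatch allowance for the coverage evaluation (default 1).
#' @param orientation matching orientation.
#' @param cap maximum number of expansions (default 1024); exceeding it is
#'   an error instructing the user to raise the cap.
#' @return list with `primer` (best concrete variant) and `report`
#'   (`data.frame`: `variant`, `mean_coverage`).
#' @export
resolve_degenerate <- function(primer_iupac, records, max_mm = 1L,
                               orientation = "forward", cap = 1024L) {
  primer_iupac <- toupper(primer_iupac)
  variants <- iupac_expand(primer_iupac, cap = cap)
  score <- vapply(variants, function(v) {
    gc <- genus_coverage(v, records, max_mm = max_mm,
                         orientation = orientation)
    mean(gc$coverage)
  }, numeric(1), USE.NAMES = FALSE)
  ord <- order(-score, variants, method = "radix")
  list(
    primer = variants[[ord[[1L]]]],
    report = data.frame(variant = variants, mean_coverage = score,
                        stringsAsFactors = FALSE)
  )
}

#' Expand an IUPAC nucleotide string to all concrete sequences
#'
#' @param x IUPAC string.
#' @param cap maximum number of expansions permitted.
#' @return character vector of A/C/G/T sequences, in lexicographic order.
#' @export
iupac_expand <- function(x, cap = 1024L) {
  map <- Biostrings::IUPAC_CODE_MAP
  ch <- strsplit(toupper(x), "", fixed = TRUE)[[1L]]
  if (!all(ch %in% names(map))) {
    stop("non-IUPAC character in primer: ", x)
  }
  sets <- lapply(ch, function(c1) sort(strsplit(map[[c1]], "")[[1L]]))
  n <- prod(vapply(sets, length, integer(1)))
  if (n > cap) {
    stop("primer expands to ", n, " variants, above the cap of ", cap,
         "; raise `cap` to proceed")
  }
  grid <- expand.grid(rev(sets), stringsAsFactors = FALSE)
  out <- do.call(paste0, rev(grid))
  sort(out, method = "radix")
}

#' Pair forward and reverse primer candidates under amplicon-length limits
#'
#' Forms every forward x reverse combination whose amplicon span (reverse
#' end minus forward start, inclusive) lies within `[min_span, max_span]`
#' and whose regions do not overlap, ranked by descending mean prokaryotic
#' coverage then descending span. Candidates are held in sense-strand
#' orientation; the synthesizable reverse oligo (reverse complement) is
#' emitted alongside its source.
#'
#' @param forwards,reverses candidate `data.frame`s (`sequence`,
#'   `ref_start`, `ref_end`, optional `mean_coverage`).
#' @param min_span minimum amplicon span, nt.
#' @param max_span maximum amplicon span, nt (default 550, matching a
#'   long-read amplicon platform's high-quality read length).
#' @return ranked `data.frame` of pairs: forward and reverse coordinates
#'   and sequences, `reverse_oligo`, `amplicon_span`, `mean_coverage`.
#'   Empty (with a message) when no combination is admissible.
#' @export
pair_primers <- function(forwards, reverses, min_span, max_span = 550L) {
  empty <- data.frame(
    forward_seq = character(0), forward_start = integer(0),
    forward_end = integer(0), reverse_seq = character(0),
    reverse_oligo = character(0), reverse_start = integer(0),
    reverse_end = integer(0), amplicon_span = integer(0),
    mean_coverage = numeric(0), stringsAsFactors = FALSE
  )
  if (is.null(forwards) || is.null(reverses) ||
      nrow(forwards) == 0L || nrow(reverses) == 0L) {
    message("no admissible primer pair: empty candidate list")
    return(empty)
  }
  covf <- if (is.null(forwards$mean_coverage)) rep(0, nrow(forwards)) else forwards$mean_coverage
  covr <- if (is.null(reverses$mean_coverage)) rep(0, nrow(reverses)) else reverses$mean_coverage
  grid <- expand.grid(f = seq_len(nrow(forwards)), r = seq_len(nrow(reverses)))
  f <- grid$f
  r <- grid$r
  span <- reverses$ref_end[r] - forwards$ref_start[f] + 1L
  ok <- forwards$ref_end[f] < reverses$ref_start[r] &
    span >= min_span & span <= max_span &
    span > nchar(forwards$sequence[f]) + nchar(reverses$sequence[r])
  if (!any(ok)) {
    message("no admissible primer pair: no combination with span in [",
            min_span, ", ", max_span, "]")
    return(empty)
  }
  f <- f[ok]
  r <- r[ok]
  span <- span[ok]
  pair_cov <- (covf[f] + covr[r]) / 2
  out <- data.frame(
    forward_seq = forwards$sequence[f],
    forward_start = forwards$ref_start[f],
    forward_end = forwards$ref_end[f],
    reverse_seq = reverses$sequence[r],
    reverse_oligo = revcomp(reverses$sequence[r]),
    reverse_start = reverses$ref_start[r],
    reverse_end = reverses$ref_end[r],
    amplicon_span = as.integer(span),
    mean_coverage = pair_cov,
    stringsAsFactors = FALSE
  )
  ord <- order(-out$mean_coverage, -out$amplicon_span,
               out$forward_seq, out$reverse_seq, method = "radix")
  out <- out[ord, , drop = FALSE]
  rownames(out) <- NULL
  out
}
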
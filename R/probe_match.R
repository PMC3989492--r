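#' Minimum mismatch count of a primer against a template
#'
#' Slides the primer (forward) or its reverse complement (reverse
#' orientation) across every same-length substring of the sense-strand
#' template and returns the minimum Hamming distance. Insertions and
#' deletions are not modelled.
#'
#' @param primer concrete primer (A/C/G/T only; resolve degenerate primers
#'   first, see [resolve_degenerate()]).
#' @param template template sequence.
#' @param orientation `"forward"` or `"reverse"`.
#' @return integer minimum mismatch count, or `NA_integer_` when the primer
#'   does not fit in the template (no site).
#' @export
min_mismatch <- function(primer, template,
                         orientation = c("forward", "reverse")) {
  orientation <- match.arg(orientation)
  if (!.is_concrete(primer)) {
    stop("primer must be a concrete A/C/G/T sequence")
  }
  if (orientation == "reverse") primer <- revcomp(primer)
  prof <- .mm_profile(primer, template)
  if (length(prof) == 0L) return(NA_integer_)
  min(prof)
}

# vectorized minimum mismatch of one primer over many templates
.min_mm_many <- function(primer, templates, orientation = "forward") {
  if (orientation == "reverse") primer <- revcomp(primer)
  vapply(templates, function(tpl) {
    prof <- .mm_profile(primer, tpl)
    if (length(prof) == 0L) NA_integer_ else min(prof)
  }, integer(1), USE.NAMES = FALSE)
}

#' Per-sequence coverage of a primer over grouped reference records
#'
#' For each group, the percentage of records containing a primer site
#' within `max_mm` mismatches.
#'
#' @param primer concrete primer.
#' @param records normalized, ambiguity-free record `data.frame`.
#' @param max_mm mismatch allowance.
#' @param orientation matching orientation, see [min_mismatch()].
#' @param group_by record column defining the groups (default `"origin"`).
#' @return coverage `data.frame`: `group`, `matched`, `total`, `coverage`,
#'   `metric = "per_sequence"`, `max_mm`.
#' @export
sequence_coverage <- function(primer, records, max_mm = 2L,
                              orientation = "forward", group_by = "origin") {
  mm <- .min_mm_many(primer, records$sequence, orientation)
  ok <- !is.na(mm) & mm <= max_mm
  groups <- records[[group_by]]
  keep <- !is.na(groups) & nzchar(groups)
  if (any(!keep)) warning(sum(!keep), " record(s) without a group omitted")
  tab <- tapply(ok[keep], groups[keep], function(z) c(sum(z), length(z)))
  if (is.null(tab) || length(tab) == 0L) {
    return(data.frame(group = character(0), matched = integer(0),
                      total = integer(0), coverage = numeric(0),
                      metric = character(0), max_mm = integer(0),
                      stringsAsFactors = FALSE))
  }
  matched <- vapply(tab, `[[`, numeric(1), 1L)
  total <- vapply(tab, `[[`, numeric(1), 2L)
  data.frame(group = names(tab),
             matched = as.integer(matched), total = as.integer(total),
             coverage = 100 * matched / total,
             metric = "per_sequence", max_mm = as.integer(max_mm),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Genus-majority coverage of a primer, per phylum
#'
#' Per phylum, the percentage of genera in which a strict majority of
#' member sequences (more than half; exactly half does not count) contain a
#' primer site within `max_mm` mismatches.
#'
#' @param primer concrete primer.
#' @param records record `data.frame`; every record must carry `genus` and
#'   `phylum`.
#' @param max_mm mismatch allowance (default 1).
#' @param orientation matching orientation.
#' @return coverage `data.frame`: `group` (phylum), `matched` (covered
#'   genera), `total` (genera), `coverage`, `metric = "genus_majority"`.
#' @export
genus_coverage <- function(primer, records, max_mm = 1L,
                           orientation = "forward") {
  ok_rec <- !is.na(records$genus) & nzchar(records$genus) &
    !is.na(records$phylum) & nzchar(records$phylum)
  if (any(!ok_rec)) {
    stop("genus_coverage requires genus and phylum on every record")
  }
  mm <- .min_mm_many(primer, records$sequence, orientation)
  hit <- !is.na(mm) & mm <= max_mm
  key <- paste(records$phylum, records$genus, sep = "\r")
  genus_cov <- tapply(hit, key, function(z) sum(z) > length(z) / 2)
  genus_phy <- vapply(strsplit(names(genus_cov), "\r", fixed = TRUE),
                      `[[`, character(1), 1L)
  tab <- tapply(as.logical(genus_cov), genus_phy,
                function(z) c(sum(z), length(z)))
  matched <- vapply(tab, `[[`, numeric(1), 1L)
  total <- vapply(tab, `[[`, numeric(1), 2L)
  data.frame(group = names(tab),
             matched = as.integer(matched), total = as.integer(total),
             coverage = 100 * matched / total,
             metric = "genus_majority", max_mm = as.integer(max_mm),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Exclude candidates that cover eukaryote or mitochondrial rRNA genes
#'
#' A candidate is excluded when its per-sequence coverage within `max_mm`
#' mismatches exceeds `max_cov` percent in the mitochondrial or in the
#' eukaryotic reference set; a candidate at exactly `max_cov` is kept.
#'
#' @param candidates candidate `data.frame` with a `sequence` column
#'   (sense-strand; matched in forward orientation).
#' @param mito_records,euk_records record `data.frame`s (either may have
#'   zero rows, in which case that set imposes no constraint).
#' @param max_mm mismatch allowance (default 2).
#' @param max_cov coverage threshold, percent (default 50).
#' @return list with `kept` and `excluded` (the latter with columns
#'   `mito_coverage`, `euk_coverage`, `reason`); both retain candidate
#'   columns plus the measured coverages.
#' @export
eukaryote_exclusion_filter <- function(candidates, mito_records, euk_records,
                                       max_mm = 2L, max_cov = 50) {
  one_cov <- function(seq, recs) {
    if (is.null(recs) || nrow(recs) == 0L) return(NA_real_)
    mm <- .min_mm_many(seq, recs$sequence, "forward")
    100 * mean(!is.na(mm) & mm <= max_mm)
  }
  mito_cov <- vapply(candidates$sequence, one_cov, numeric(1),
                     recs = mito_records, USE.NAMES = FALSE)
  euk_cov <- vapply(candidates$sequence, one_cov, numeric(1),
                    recs = euk_records, USE.NAMES = FALSE)
  out <- candidates
  out$mito_coverage <- mito_cov
  out$euk_coverage <- euk_cov
  excl <- (!is.na(mito_cov) & mito_cov > max_cov) |
    (!is.na(euk_cov) & euk_cov > max_cov)
  reason <- character(nrow(out))
  reason[!is.na(mito_cov) & mito_cov > max_cov] <- "mitochondrial coverage"
  both <- (!is.na(mito_cov) & mito_cov > max_cov) &
    (!is.na(euk_cov) & euk_cov > max_cov)
  reason[!is.na(euk_cov) & euk_cov > max_cov] <- "eukaryotic coverage"
  reason[both] <- "mitochondrial and eukaryotic coverage"
  excluded <- out[excl, , drop = FALSE]
  if (nrow(excluded)) excluded$reason <- reason[excl]
  list(kept = out[!excl, , drop = FALSE], excluded = excluded)
}

#' Coverage matrix of primers against grouped reference sets
#'
#' Rows are primers; columns are bacterial/archaeal phyla (genus-majority
#' coverage at `prok_max_mm`) followed by the chloroplast, mitochondrion
#' and eukaryote groups (per-sequence coverage at `euk_max_mm`).
#'
#' @param primers `data.frame` with columns `id`, `sequence`, and
#'   optionally `orientation` (default forward).
#' @param records record `data.frame` covering all groups; prokaryotic
#'   records (origin bacteria/archaea) need genus and phylum.
#' @param prok_max_mm mismatch allowance for prokaryotic coverage (default 1).
#' @param euk_max_mm mismatch allowance for organelle/eukaryote coverage
#'   (default 2).
#' @return numeric matrix of percentages with primer ids as row names.
#' @export
coverage_matrix <- function(primers, records, prok_max_mm = 1L,
                            euk_max_mm = 2L) {
  if (is.null(primers) || nrow(primers) == 0L) {
    return(matrix(numeric(0), 0L, 0L))
  }
  if (is.null(primers$orientation)) primers$orientation <- "forward"
  prok <- records[records$origin %in% c("bacteria", "archaea"), , drop = FALSE]
  euk_groups <- c("chloroplast", "mitochondrion", "eukaryote")
  euks <- records[records$origin %in% euk_groups, , drop = FALSE]
  rows <- lapply(seq_len(nrow(primers)), function(i) {
    p <- primers$sequence[[i]]
    ori <- primers$orientation[[i]]
    vals <- numeric(0)
    if (nrow(prok)) {
      gc <- genus_coverage(p, prok, max_mm = prok_max_mm, orientation = ori)
      vals <- c(vals, stats::setNames(gc$coverage, gc$group))
    }
    if (nrow(euks)) {
      sc <- sequence_coverage(p, euks, max_mm = euk_max_mm,
                              orientation = ori, group_by = "origin")
      vals <- c(vals, stats::setNames(sc$coverage, sc$group))
    }
    vals
  })
  cols <- unique(unlist(lapply(rows, names)))
  mat <- matrix(NA_real_, nrow(primers), length(cols),
                dimnames = list(primers$id, cols))
  for (i in seq_along(rows)) mat[i, names(rows[[i]])] <- rows[[i]]
  mat
}
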
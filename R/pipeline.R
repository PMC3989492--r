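#' Full universal-primer design pipeline
#'
#' Chains the discovery steps: sliding-window scan of the labelled
#' alignment, selection of conserved gap-free windows within the
#' reference-position keep-interval, merging of neighbouring windows under
#' a per-phylum coverage floor, exclusion of candidates that cover
#' mitochondrial or eukaryotic rRNA genes, and pairing of the survivors
#' under amplicon-length constraints. Candidate coverage is the
#' genus-majority metric over the prokaryotic reference records; ranking
#' uses its mean over phyla.
#'
#' @param alignment labelled alignment (`id`, `gapped_sequence`).
#' @param taxonomy taxonomy table for the alignment and references.
#' @param references unaligned record `data.frame` over all origin groups.
#' @param reference_id id of the coordinate reference record.
#' @param width,max_mm window scan parameters (defaults 15 and 1).
#' @param min_coverage,min_phylum_fraction window selection thresholds.
#' @param ref_pos_range keep-interval on reference positions (default
#'   `c(30, 1200)`: terminal regions missing from many database records
#'   and beyond amplicon read reach are excluded).
#' @param prok_max_mm mismatch allowance for prokaryotic coverage (1).
#' @param euk_max_mm,max_euk_cov eukaryote-exclusion parameters (2
#'   mismatches, 50 percent).
#' @param min_span,max_span amplicon span limits, nt.
#' @param merge_tolerance permitted per-phylum coverage drop when merging.
#' @return list with `windows`, `selected`, `candidates`, `kept`,
#'   `excluded`, `pairs`.
#' @export
design_universal_primers <- function(alignment, taxonomy, references,
                                     reference_id,
                                     width = 15L, max_mm = 1L,
                                     min_coverage = 90,
                                     min_phylum_fraction = 0.9,
                                     ref_pos_range = c(30L, 1200L),
                                     prok_max_mm = 1L,
                                     euk_max_mm = 2L, max_euk_cov = 50,
                                     min_span = 300L, max_span = 550L,
                                     merge_tolerance = 0) {
  windows <- scan_windows(alignment, taxonomy, width = width,
                          max_mm = max_mm, reference_id = reference_id)
  selected <- select_candidates(windows, min_coverage = min_coverage,
                                min_phylum_fraction = min_phylum_fraction,
                                ref_pos_range = ref_pos_range)
  prok <- references[references$origin %in% c("bacteria", "archaea"), ,
                     drop = FALSE]
  prok <- prok[!is.na(prok$genus) & !is.na(prok$phylum), , drop = FALSE]
  covfn <- function(s) {
    gc <- genus_coverage(s, prok, max_mm = prok_max_mm,
                         orientation = "forward")
    stats::setNames(gc$coverage, gc$group)
  }
  candidates <- if (nrow(selected)) {
    merge_neighbouring(selected, coverage_fn = covfn,
                       tolerance = merge_tolerance)
  } else {
    NULL
  }
  if (!is.null(candidates) && nrow(candidates)) {
    candidates$mean_coverage <-
      vapply(candidates$sequence, function(s) mean(covfn(s)), numeric(1),
             USE.NAMES = FALSE)
  }
  mito <- references[references$origin == "mitochondrion", , drop = FALSE]
  euk <- references[references$origin == "eukaryote", , drop = FALSE]
  flt <- if (!is.null(candidates) && nrow(candidates)) {
    eukaryote_exclusion_filter(candidates, mito, euk,
                               max_mm = euk_max_mm, max_cov = max_euk_cov)
  } else {
    list(kept = candidates, excluded = candidates)
  }
  pairs <- pair_primers(flt$kept, flt$kept,
                        min_span = min_span, max_span = max_span)
  list(windows = windows, selected = selected, candidates = candidates,
       kept = flt$kept, excluded = flt$excluded, pairs = pairs)
}
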
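#' Filter similarity hits by e-value and alignment length
#'
#' Keeps hits with e-value strictly below `max_evalue` (a hit at exactly
#' the threshold is removed) and alignment length of at least `min_alnlen`
#' (inclusive). Rows with missing values in either field are skipped and
#' counted in the `"n_malformed"` attribute.
#'
#' @param hits hit `data.frame` (see [read_blast_hits()]).
#' @param max_evalue e-value threshold (strict `<`).
#' @param min_alnlen alignment-length threshold (inclusive `>=`).
#' @return filtered hits.
#' @export
filter_hits <- function(hits, max_evalue, min_alnlen) {
  bad <- is.na(hits$evalue) | is.na(hits$length)
  ok <- !bad & hits$evalue < max_evalue & hits$length >= min_alnlen
  out <- hits[ok, , drop = FALSE]
  attr(out, "n_malformed") <- sum(bad)
  out
}

# join subject lineage/gene_class onto hits; restrict to SSU rRNA subjects
.hits_with_lineage <- function(hits, subjects) {
  if (!is.null(subjects)) {
    idx <- match(hits$sseqid, subjects$sseqid)
    hits$phylum <- subjects$phylum[idx]
    hits$genus <- subjects$genus[idx]
    if (!is.null(subjects$gene_class)) {
      hits$gene_class <- subjects$gene_class[idx]
    }
  }
  if (!is.null(hits$gene_class)) {
    hits <- hits[!is.na(hits$gene_class) & hits$gene_class == "SSU_rRNA", ,
                 drop = FALSE]
  }
  hits
}

# fractional best-hit assignment at one rank tier
.assign_tier <- function(h, rank, min_identity) {
  taxa <- h[[rank]]
  ok <- !is.na(taxa) & nzchar(taxa) & h$pident >= min_identity
  if (!any(ok)) {
    return(list(fractions = stats::setNames(numeric(0), character(0)),
                strand = NA_character_))
  }
  h <- h[ok, , drop = FALSE]
  best <- h$bitscore == max(h$bitscore)
  hb <- h[best, , drop = FALSE]
  frac <- tapply(rep(1 / nrow(hb), nrow(hb)), hb[[rank]], sum)
  strand <- hb$strand[order(hb$sseqid, method = "radix")][[1L]]
  list(fractions = stats::setNames(as.numeric(frac), names(frac)),
       strand = strand)
}

#' Assign one read to taxa from its filtered hits
#'
#' Two tiers are evaluated independently: the genus tier uses only hits
#' with identity at least `genus_min_identity`, the phylum tier those with
#' at least `phylum_min_identity`. Within a tier, the hits with the best
#' bit score are found and each contributes `1/n_best` to its taxon (tied
#' best hits in the same taxon accumulate). A read with no qualifying hit
#' is unassigned at that tier. Only hits to SSU rRNA subjects are
#' considered when gene-class metadata is available.
#'
#' @param hits hits of a single query (already e-value/length filtered).
#' @param subjects optional subject metadata (`sseqid`, `phylum`, `genus`,
#'   `gene_class`).
#' @param genus_min_identity,phylum_min_identity identity tiers, percent
#'   (defaults 94 and 85).
#' @return list with `genus` and `phylum`, each a named numeric vector of
#'   fractions summing to 1 (or empty if unassigned), plus `genus_strand`
#'   and `phylum_strand` (strand of the best hit, for pair consistency).
#' @export
assign_read <- function(hits, subjects = NULL,
                        genus_min_identity = 94, phylum_min_identity = 85) {
  h <- .hits_with_lineage(hits, subjects)
  g <- .assign_tier(h, "genus", genus_min_identity)
  p <- .assign_tier(h, "phylum", phylum_min_identity)
  list(genus = g$fractions, phylum = p$fractions,
       genus_strand = g$strand, phylum_strand = p$strand)
}

#' Assign every read in a hit table
#'
#' @param hits filtered hit `data.frame` for many queries.
#' @param subjects subject metadata.
#' @param genus_min_identity,phylum_min_identity identity tiers.
#' @return named list (by query id) of [assign_read()] results.
#' @export
assign_reads <- function(hits, subjects = NULL,
                         genus_min_identity = 94, phylum_min_identity = 85) {
  h <- .hits_with_lineage(hits, subjects)
  lapply(split(h, h$qseqid), function(hq) {
    g <- .assign_tier(hq, "genus", genus_min_identity)
    p <- .assign_tier(hq, "phylum", phylum_min_identity)
    list(genus = g$fractions, phylum = p$fractions,
         genus_strand = g$strand, phylum_strand = p$strand)
  })
}

#' Assign read pairs with taxon and direction consistency
#'
#' Query ids must follow the `<pair>/1`, `<pair>/2` convention. At each
#' tier, a pair contributes one unit to a taxon only when both mates are
#' assigned (each concentrated on that single taxon, i.e. untied), the
#' taxon is the same, and the mates' best-hit strands are consistent
#' (opposite by default, the geometry of paired ends facing each other on
#' one template). The distance between the mates is never considered.
#'
#' @param hits filtered hit `data.frame` for both mates of many pairs.
#' @param subjects subject metadata.
#' @param genus_min_identity,phylum_min_identity identity tiers.
#' @param opposite_strands if `TRUE` (default) mates must align to opposite
#'   strands; set `FALSE` for same-strand chemistry.
#' @return named list (by pair id) of per-pair assignments in the same
#'   shape as [assign_read()] (unit fractions), suitable for
#'   [build_profile()].
#' @export
assign_pairs <- function(hits, subjects = NULL,
                         genus_min_identity = 94, phylum_min_identity = 85,
                         opposite_strands = TRUE) {
  per_read <- assign_reads(hits, subjects,
                           genus_min_identity, phylum_min_identity)
  qids <- names(per_read)
  mate <- sub("^.*/", "", qids)
  pair_id <- sub("/[12]$", "", qids)
  out <- list()
  for (pid in unique(pair_id)) {
    a1 <- per_read[[paste0(pid, "/1")]]
    a2 <- per_read[[paste0(pid, "/2")]]
    res <- list(genus = stats::setNames(numeric(0), character(0)),
                phylum = stats::setNames(numeric(0), character(0)))
    for (tier in c("genus", "phylum")) {
      if (is.null(a1) || is.null(a2)) next
      f1 <- a1[[tier]]
      f2 <- a2[[tier]]
      if (length(f1) != 1L || length(f2) != 1L) next
      if (names(f1) != names(f2)) next
      s1 <- a1[[paste0(tier, "_strand")]]
      s2 <- a2[[paste0(tier, "_strand")]]
      strand_ok <- if (opposite_strands) s1 != s2 else s1 == s2
      if (is.na(strand_ok) || !strand_ok) next
      res[[tier]] <- stats::setNames(1, names(f1))
    }
    out[[pid]] <- res
  }
  out
}

#' Build a taxonomic profile from read assignments
#'
#' Sums the fractional contributions of every assignment at the requested
#' rank.
#'
#' @param assignments list of per-read (or per-pair) assignments as
#'   produced by [assign_reads()] or [assign_pairs()].
#' @param rank `"phylum"` or `"genus"`.
#' @return an object of class `taxonomic_profile`: list with `rank`,
#'   `abundance` (named numeric), `assigned_total`, `input_read_count`.
#' @export
build_profile <- function(assignments, rank = c("phylum", "genus")) {
  rank <- match.arg(rank)
  acc <- new.env(parent = emptyenv())
  for (a in assignments) {
    f <- a[[rank]]
    for (tx in names(f)) {
      acc[[tx]] <- (if (is.null(acc[[tx]])) 0 else acc[[tx]]) + f[[tx]]
    }
  }
  taxa <- sort(ls(acc), method = "radix")
  ab <- stats::setNames(vapply(taxa, function(tx) acc[[tx]], numeric(1)),
                        taxa)
  structure(list(rank = rank, abundance = ab,
                 assigned_total = sum(ab),
                 input_read_count = length(assignments)),
            class = "taxonomic_profile")
}

#' @export
print.taxonomic_profile <- function(x, ...) {
  cat("Taxonomic profile at the ", x$rank, " level\n", sep = "")
  cat("  reads in: ", x$input_read_count,
      "; assigned mass: ", format(x$assigned_total), "\n", sep = "")
  ab <- sort(x$abundance, decreasing = TRUE)
  for (tx in names(ab)) {
    cat(sprintf("  %-28s %10.3f\n", tx, ab[[tx]]))
  }
  invisible(x)
}

#' Spearman comparison of two taxonomic profiles
#'
#' Computes the Spearman rank correlation of the two abundance vectors over
#' a common taxon list (default: the union of taxa, with absentees counted
#' as zero), with average ranks for ties.
#'
#' @param p1,p2 `taxonomic_profile` objects at the same rank.
#' @param taxa optional taxon list to compare over.
#' @return Spearman rho (numeric scalar).
#' @export
compare_profiles <- function(p1, p2, taxa = NULL) {
  stopifnot(inherits(p1, "taxonomic_profile"),
            inherits(p2, "taxonomic_profile"))
  if (!identical(p1$rank, p2$rank)) stop("profiles are at different ranks")
  if (is.null(taxa)) taxa <- union(names(p1$abundance), names(p2$abundance))
  if (length(taxa) < 3L) {
    stop("fewer than 3 taxa: rank correlation is meaningless")
  }
  get <- function(p) {
    v <- p$abundance[taxa]
    v[is.na(v)] <- 0
    as.numeric(v)
  }
  stats::cor(get(p1), get(p2), method = "spearman")
}

#' Rank-abundance table of a profile
#'
#' Taxa sorted by descending abundance with competition ranking: tied taxa
#' share the smaller rank and the following ranks are skipped.
#'
#' @param profile a `taxonomic_profile`.
#' @param top_n truncate to the `top_n` best-ranked taxa (default all).
#' @return `data.frame` with `taxon`, `abundance`, `rank`.
#' @export
rank_abundance <- function(profile, top_n = Inf) {
  stopifnot(inherits(profile, "taxonomic_profile"))
  ab <- profile$abundance
  if (length(ab) == 0L) stop("empty profile")
  rk <- rank(-ab, ties.method = "min")
  ord <- order(rk, names(ab), method = "radix")
  out <- data.frame(taxon = names(ab)[ord],
                    abundance = as.numeric(ab[ord]),
                    rank = as.integer(rk[ord]),
                    stringsAsFactors = FALSE)
  utils::head(out, top_n)
}

#' Write a taxonomic profile to TSV
#' @param profile a `taxonomic_profile`.
#' @param path output file.
#' @export
write_profile_tsv <- function(profile, path) {
  utils::write.table(
    data.frame(taxon = names(profile$abundance),
               abundance = as.numeric(profile$abundance)),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
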
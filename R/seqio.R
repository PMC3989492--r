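#' Construct a table of sequence records
#'
#' The package's working container for unaligned reference sequences is a
#' plain `data.frame` with one row per record and the columns `id`,
#' `sequence`, `domain`, `phylum`, `genus`, `species`, `origin` and
#' `gene_class`. Lineage fields may be `NA`. `origin` is one of
#' `"bacteria"`, `"archaea"`, `"eukaryote"`, `"mitochondrion"`,
#' `"chloroplast"`; `gene_class` is `"SSU_rRNA"` or `"other"`.
#'
#' @param id,sequence character vectors (required, equal length).
#' @param domain,phylum,genus,species optional lineage fields.
#' @param origin,gene_class record provenance labels.
#' @return a `data.frame` of sequence records.
#' @export
seq_records <- function(id, sequence,
                        domain = NA_character_, phylum = NA_character_,
                        genus = NA_character_, species = NA_character_,
                        origin = "bacteria", gene_class = "SSU_rRNA") {
  stopifnot(length(id) == length(sequence))
  empty_to_na <- function(x) {
    x <- as.character(x)
    x[!is.na(x) & !nzchar(x)] <- NA_character_
    x
  }
  data.frame(
    id = as.character(id),
    sequence = toupper(as.character(sequence)),
    domain = empty_to_na(rep_len(domain, length(id))),
    phylum = empty_to_na(rep_len(phylum, length(id))),
    genus = empty_to_na(rep_len(genus, length(id))),
    species = empty_to_na(rep_len(species, length(id))),
    origin = rep_len(as.character(origin), length(id)),
    gene_class = rep_len(as.character(gene_class), length(id)),
    stringsAsFactors = FALSE
  )
}

#' Read sequences from a FASTA file into a record table
#'
#' @param path FASTA file. Gapped alignment FASTA is accepted; gaps are kept.
#' @param taxonomy optional taxonomy table (see [read_taxonomy_tsv()]) used
#'   to attach lineages by record id.
#' @param origin,gene_class labels applied to every record.
#' @return a record `data.frame` as produced by [seq_records()].
#' @export
read_fasta_records <- function(path, taxonomy = NULL,
                               origin = "bacteria", gene_class = "SSU_rRNA") {
  ss <- Biostrings::readBStringSet(path)
  rec <- seq_records(id = names(ss), sequence = as.character(ss),
                     origin = origin, gene_class = gene_class)
  if (!is.null(taxonomy)) rec <- attach_taxonomy(rec, taxonomy)
  rec
}

#' Write a record table (or alignment) to FASTA
#'
#' @param records record `data.frame`; the sequence column written is
#'   `gapped_sequence` if present, else `sequence`.
#' @param path output file.
#' @export
write_fasta_records <- function(records, path) {
  col <- if ("gapped_sequence" %in% names(records)) "gapped_sequence" else "sequence"
  ss <- Biostrings::BStringSet(records[[col]])
  names(ss) <- records$id
  Biostrings::writeXStringSet(ss, path)
  invisible(path)
}

#' Read a gapped multiple sequence alignment from FASTA
#'
#' @param path alignment FASTA; gap character `-`.
#' @return `data.frame` with columns `id`, `gapped_sequence`; all sequences
#'   are checked for equal gapped length.
#' @export
read_alignment_fasta <- function(path) {
  ss <- Biostrings::readBStringSet(path)
  aln <- data.frame(id = names(ss),
                    gapped_sequence = toupper(as.character(ss)),
                    stringsAsFactors = FALSE)
  if (length(unique(nchar(aln$gapped_sequence))) > 1L) {
    stop("alignment records differ in gapped length")
  }
  if (any(!nzchar(gsub("-", "", aln$gapped_sequence, fixed = TRUE)))) {
    stop("alignment contains an all-gap record")
  }
  aln
}

#' Read a taxonomy table
#'
#' Format: two tab-separated columns, `id` and a semicolon-delimited lineage
#' `domain;phylum;genus;species`; trailing lineage fields may be empty.
#'
#' @param path TSV file.
#' @return `data.frame` with columns `id`, `domain`, `phylum`, `genus`,
#'   `species` (`NA` for empty fields).
#' @export
read_taxonomy_tsv <- function(path) {
  raw <- utils::read.delim(path, header = FALSE, sep = "\t",
                           stringsAsFactors = FALSE,
                           col.names = c("id", "lineage"),
                           quote = "", comment.char = "")
  parts <- strsplit(as.character(raw$lineage), ";", fixed = TRUE)
  field <- function(i) {
    x <- vapply(parts, function(p) if (length(p) >= i) p[[i]] else "", character(1))
    x <- trimws(x)
    x[!nzchar(x)] <- NA_character_
    x
  }
  data.frame(id = as.character(raw$id),
             domain = field(1), phylum = field(2),
             genus = field(3), species = field(4),
             stringsAsFactors = FALSE)
}

#' Write a taxonomy table in the `id<TAB>domain;phylum;genus;species` format
#' @param taxonomy taxonomy `data.frame`.
#' @param path output file.
#' @export
write_taxonomy_tsv <- function(taxonomy, path) {
  blank <- function(x) ifelse(is.na(x), "", x)
  lineage <- paste(blank(taxonomy$domain), blank(taxonomy$phylum),
                   blank(taxonomy$genus), blank(taxonomy$species), sep = ";")
  utils::write.table(data.frame(taxonomy$id, lineage),
                     path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Attach lineages from a taxonomy table to a record table by id
#' @param records record `data.frame`.
#' @param taxonomy taxonomy `data.frame` (id, domain, phylum, genus, species).
#' @return records with lineage columns filled where the id resolves.
#' @export
attach_taxonomy <- function(records, taxonomy) {
  idx <- match(records$id, taxonomy$id)
  for (f in c("domain", "phylum", "genus", "species")) {
    hit <- !is.na(idx)
    records[[f]][hit] <- taxonomy[[f]][idx[hit]]
  }
  records
}

#' Normalize rRNA sequences: uracil to thymine, upper case
#'
#' RNA-alphabet reference sequences are converted to DNA alphabet before any
#' matching: every U is replaced by T and the sequence is uppercased. No
#' other character is altered.
#'
#' @param records a record `data.frame`, or a plain character vector.
#' @return same shape as the input, normalized.
#' @export
normalize_rrna <- function(records) {
  norm1 <- function(x) {
    if (any(is.na(x)) || any(!nzchar(x))) {
      stop("malformed record: empty sequence")
    }
    chartr("u", "T", chartr("U", "T", toupper(x)))
  }
  if (is.character(records)) return(norm1(records))
  records$sequence <- norm1(records$sequence)
  records
}

#' Discard records containing ambiguous nucleotides
#'
#' Keeps only records whose sequence is entirely over A/C/G/T; records with
#' any IUPAC ambiguity code (N, Y, R, ...) are dropped.
#'
#' @param records record `data.frame` (normalized).
#' @return the subset of unambiguous records.
#' @export
discard_ambiguous <- function(records) {
  records[.is_concrete(records$sequence), , drop = FALSE]
}

#' Randomly keep one record per taxon at a given rank
#'
#' Reduces taxonomic redundancy by keeping exactly one record per distinct
#' value of `rank` (species or genus), chosen uniformly at random. Records
#' lacking the rank are dropped and counted in the report.
#'
#' @param records record `data.frame` with the rank column populated.
#' @param rank `"species"` or `"genus"`.
#' @param seed integer seed; the choice is deterministic for a fixed seed.
#' @return list with `records` (one per taxon, original order preserved) and
#'   `report` (named counts: `input`, `kept`, `dropped_missing_rank`).
#' @export
subsample_one_per_taxon <- function(records, rank = c("species", "genus"), seed) {
  rank <- match.arg(rank)
  stopifnot(!missing(seed))
  vals <- records[[rank]]
  has <- !is.na(vals) & nzchar(vals)
  if (any(!has)) {
    warning(sum(!has), " record(s) lacking ", rank, " were dropped")
  }
  pool <- records[has, , drop = FALSE]
  set.seed(as.integer(seed))
  keep_idx <- unlist(lapply(split(seq_len(nrow(pool)), pool[[rank]]),
                            function(ix) if (length(ix) == 1L) ix else sample(ix, 1L)),
                     use.names = FALSE)
  keep_idx <- sort(keep_idx)
  list(
    records = pool[keep_idx, , drop = FALSE],
    report = c(input = nrow(records), kept = length(keep_idx),
               dropped_missing_rank = sum(!has))
  )
}

#' Curate a reference sequence database
#'
#' Removes records that are (in this fixed rule order): (1) unclassified at
#' the genus level (genus absent or literally "unclassified", any case);
#' (2) longer than `max_len` nucleotides (a record of exactly `max_len` is
#' kept); (3) containing a single-base homopolymer run longer than
#' `homopolymer_max`. A record tripping several rules is counted once, under
#' the first rule in that order.
#'
#' @param records normalized record `data.frame` with lineages attached.
#' @param max_len maximum retained sequence length (default 2000).
#' @param homopolymer_max longest retained single-base run (default 14).
#' @return list with `kept` (record `data.frame`) and `report` (named counts
#'   `unclassified`, `length`, `homopolymer`, plus `kept`).
#' @export
curate_reference_db <- function(records, max_len = 2000L, homopolymer_max = 14L) {
  g <- records$genus
  uncl <- is.na(g) | !nzchar(g) | tolower(g) == "unclassified"
  too_long <- nchar(records$sequence) > max_len
  has_run <- vapply(records$sequence, function(s) {
    r <- rle(strsplit(s, "", fixed = TRUE)[[1L]])
    any(r$lengths > homopolymer_max)
  }, logical(1), USE.NAMES = FALSE)
  first_rule <- ifelse(uncl, "unclassified",
                ifelse(too_long, "length",
                ifelse(has_run, "homopolymer", "keep")))
  kept <- records[first_rule == "keep", , drop = FALSE]
  list(
    kept = kept,
    report = c(unclassified = sum(first_rule == "unclassified"),
               length = sum(first_rule == "length"),
               homopolymer = sum(first_rule == "homopolymer"),
               kept = nrow(kept))
  )
}

#' Read a 12-column blast-tabular hit file
#'
#' Standard tabular dialect: qseqid, sseqid, pident, length, mismatch,
#' gapopen, qstart, qend, sstart, send, evalue, bitscore. Subject strand is
#' inferred from the subject coordinates (`sstart > send` means minus).
#' Malformed rows (non-numeric numeric fields) are skipped and counted in
#' the `"n_malformed"` attribute.
#'
#' @param path hit file (TSV, no header).
#' @return hits `data.frame` with an added `strand` column.
#' @export
read_blast_hits <- function(path) {
  cols <- c("qseqid", "sseqid", "pident", "length", "mismatch", "gapopen",
            "qstart", "qend", "sstart", "send", "evalue", "bitscore")
  raw <- utils::read.delim(path, header = FALSE, sep = "\t",
                           stringsAsFactors = FALSE, quote = "",
                           comment.char = "", col.names = cols,
                           colClasses = "character")
  num <- c("pident", "length", "mismatch", "gapopen", "qstart", "qend",
           "sstart", "send", "evalue", "bitscore")
  for (f in num) raw[[f]] <- suppressWarnings(as.numeric(raw[[f]]))
  bad <- rowSums(is.na(raw[num])) > 0
  hits <- raw[!bad, , drop = FALSE]
  hits$length <- as.integer(hits$length)
  hits$strand <- ifelse(hits$sstart > hits$send, "-", "+")
  attr(hits, "n_malformed") <- sum(bad)
  hits
}

#' Read subject metadata (subject id, lineage, gene class) from TSV
#'
#' Columns: `sseqid`, `phylum`, `genus`, `gene_class` (tab-separated, with
#' header).
#'
#' @param path TSV file.
#' @return `data.frame`.
#' @export
read_subject_metadata <- function(path) {
  utils::read.delim(path, header = TRUE, sep = "\t",
                    stringsAsFactors = FALSE, quote = "", comment.char = "")
}
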
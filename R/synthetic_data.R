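#' Specification of a synthetic microbial community
#'
#' Defines everything the generators need: the prokaryotic taxa (one row
#' per genus, with phylum, relative abundance and number of member
#' sequences), the planted conserved motifs, the eukaryote-like reference
#' sets, the sequence background and the read error model. The defaults
#' describe a small mock community of 5 phyla x 4 genera with two members
#' each, 10 eukaryote references, a 10% per-site background divergence and
#' conserved motifs that eukaryote copies miss by at least 3 substitutions
#' while a "broad-range" decoy stays within 2.
#'
#' Planted motifs carry a `role`: `"universal"` motifs are conserved in
#' prokaryotes (at most `prok_motif_max_mm` substitutions) and forced to at
#' least `euk_motif_min_mm` substitutions in every eukaryote-like record;
#' `"broad"` motifs are conserved in prokaryotes and kept within
#' `broad_motif_max_mm_euk` substitutions in eukaryote-like records.
#' Each motif is flanked by gap-rich alignment columns (insertions relative
#' to the reference), the analogue of the indel-prone borders of conserved
#' 16S stems, so conserved windows end exactly at the motif boundary.
#'
#' @param taxa `data.frame` with columns `phylum`, `genus`, `abundance`
#'   (positive, summing to 1) and optionally `n_members` (default 2) and
#'   `domain`.
#' @param motifs `data.frame` with columns `name`, `ref_pos` (1-based
#'   ungapped reference position), `sequence`, `role` (`"universal"` or
#'   `"broad"`).
#' @param template_length length of the ungapped reference template, nt.
#' @param gc background GC content.
#' @param background_divergence per-site substitution probability of a
#'   prokaryote member relative to the template, outside motifs.
#' @param euk_divergence the same for eukaryote-like records.
#' @param prok_motif_max_mm maximal planted substitutions inside a motif in
#'   a prokaryote member (default 0).
#' @param euk_motif_min_mm minimal forced substitutions inside a universal
#'   motif in a eukaryote-like record (default 3).
#' @param broad_motif_max_mm_euk maximal planted substitutions inside a
#'   broad motif in a eukaryote-like record (default 2).
#' @param n_euk,n_mito,n_chloro numbers of eukaryote-like reference
#'   records per origin group.
#' @param flank_gap_cols gap-rich insertion columns on each side of each
#'   motif (default 2).
#' @param flank_gap_frac fraction of prokaryote records gapped in a flank
#'   column (default 0.7).
#' @param n_deletion_cols background columns where a random third of the
#'   prokaryote records carry a deletion (default 3).
#' @param read_error_rate substitution error rate for simulated reads.
#' @param reference_id id of the ungapped reference record (the E. coli
#'   analogue).
#' @param seed default seed for the generators.
#' @return a `community_spec` object (validated list).
#' @export
community_spec <- function(taxa = default_taxa(),
                           motifs = default_motifs(),
                           template_length = 1200L,
                           gc = 0.5,
                           background_divergence = 0.10,
                           euk_divergence = 0.30,
                           prok_motif_max_mm = 0L,
                           euk_motif_min_mm = 3L,
                           broad_motif_max_mm_euk = 2L,
                           n_euk = 10L, n_mito = 0L, n_chloro = 0L,
                           flank_gap_cols = 2L, flank_gap_frac = 0.7,
                           n_deletion_cols = 3L,
                           read_error_rate = 0,
                           reference_id = "REF_16S",
                           seed = 42L) {
  stopifnot(all(c("phylum", "genus", "abundance") %in% names(taxa)))
  if (any(taxa$abundance <= 0) || abs(sum(taxa$abundance) - 1) > 1e-9) {
    stop("taxon abundances must be positive and sum to 1")
  }
  if (is.null(taxa$n_members)) taxa$n_members <- 2L
  if (is.null(taxa$domain)) taxa$domain <- "Bacteria"
  stopifnot(all(c("name", "ref_pos", "sequence", "role") %in% names(motifs)))
  motifs$sequence <- toupper(motifs$sequence)
  stopifnot(all(.is_concrete(motifs$sequence)),
            all(motifs$role %in% c("universal", "broad")))
  ends <- motifs$ref_pos + nchar(motifs$sequence) - 1L
  if (any(motifs$ref_pos < flank_gap_cols + 2L) ||
      any(ends > template_length - flank_gap_cols - 1L)) {
    stop("motif (with flanks) outside the template")
  }
  ord <- order(motifs$ref_pos)
  mo <- motifs[ord, , drop = FALSE]
  if (nrow(mo) > 1L &&
      any(mo$ref_pos[-1L] <= (mo$ref_pos + nchar(mo$sequence) - 1L +
                              2L * flank_gap_cols)[-nrow(mo)])) {
    stop("motifs (with flanks) overlap")
  }
  if (any(nchar(motifs$sequence) < euk_motif_min_mm)) {
    stop("contradictory divergence constraint: motif shorter than the ",
         "minimum forced eukaryote mismatch count")
  }
  structure(list(taxa = taxa, motifs = motifs,
                 template_length = as.integer(template_length), gc = gc,
                 background_divergence = background_divergence,
                 euk_divergence = euk_divergence,
                 prok_motif_max_mm = as.integer(prok_motif_max_mm),
                 euk_motif_min_mm = as.integer(euk_motif_min_mm),
                 broad_motif_max_mm_euk = as.integer(broad_motif_max_mm_euk),
                 n_euk = as.integer(n_euk), n_mito = as.integer(n_mito),
                 n_chloro = as.integer(n_chloro),
                 flank_gap_cols = as.integer(flank_gap_cols),
                 flank_gap_frac = flank_gap_frac,
                 n_deletion_cols = as.integer(n_deletion_cols),
                 read_error_rate = read_error_rate,
                 reference_id = reference_id,
                 seed = as.integer(seed)),
            class = "community_spec")
}

#' Default taxon table: 5 phyla x 4 genera, equal abundances
#' @param n_phyla,genera_per_phylum,n_members community dimensions.
#' @return taxon `data.frame` for [community_spec()].
#' @export
default_taxa <- function(n_phyla = 5L, genera_per_phylum = 4L,
                         n_members = 2L) {
  phyla <- sprintf("Phylum%02d", seq_len(n_phyla))
  df <- expand.grid(gi = seq_len(genera_per_phylum), phylum = phyla,
                    stringsAsFactors = FALSE)
  df$genus <- sprintf("%s_Genus%02d", df$phylum, df$gi)
  df$domain <- ifelse(df$phylum == phyla[[n_phyla]], "Archaea", "Bacteria")
  n <- nrow(df)
  data.frame(domain = df$domain, phylum = df$phylum, genus = df$genus,
             abundance = rep(1 / n, n), n_members = n_members,
             stringsAsFactors = FALSE)
}

#' Default planted motifs: a forward and a reverse universal motif plus a
#' broad-range decoy
#' @return motif `data.frame` for [community_spec()].
#' @export
default_motifs <- function() {
  data.frame(
    name = c("fwd_universal", "broad_decoy", "rev_universal"),
    ref_pos = c(150L, 350L, 560L),
    sequence = c("CTACGGGAGGCTGCAGT", "GTGCCAGCAGCCGCGG", "GGATTAGATACCCTGGT"),
    role = c("universal", "broad", "universal"),
    stringsAsFactors = FALSE
  )
}

.BASES <- c("A", "C", "G", "T")

# substitute positions `at` of char vector s with a different random base
.mutate_at <- function(s, at) {
  if (length(at) == 0L) return(s)
  cur <- s[at]
  s[at] <- vapply(cur, function(b) sample(setdiff(.BASES, b), 1L),
                  character(1), USE.NAMES = FALSE)
  s
}

# union of motif position indices on the template
.motif_positions <- function(spec) {
  unlist(lapply(seq_len(nrow(spec$motifs)), function(i) {
    p <- spec$motifs$ref_pos[[i]]
    p:(p + nchar(spec$motifs$sequence[[i]]) - 1L)
  }), use.names = FALSE)
}

#' Generate a labelled alignment and reference sequence sets
#'
#' Builds a random reference template with the spec's motifs planted,
#' derives one diverged copy per prokaryote taxon member (motifs conserved
#' within `prok_motif_max_mm`), one per eukaryote-like record (universal
#' motifs broken by at least `euk_motif_min_mm` substitutions, broad motifs
#' kept within `broad_motif_max_mm_euk`), assembles the prokaryote copies
#' plus the ungapped reference into a gapped alignment (gap-rich insertion
#' columns flank every motif; a few background columns carry deletions),
#' and returns the unaligned record sets for probe matching. Byte-identical
#' output for a fixed seed.
#'
#' @param spec a [community_spec()].
#' @param seed integer seed (default `spec$seed`).
#' @return list with `alignment` (`id`, `gapped_sequence`), `taxonomy`,
#'   `references` (record `data.frame` over all origin groups), `motifs`
#'   (the spec's motif table), `reference_id`, and `spec`.
#' @export
generate_alignment <- function(spec, seed = spec$seed) {
  stopifnot(inherits(spec, "community_spec"))
  set.seed(as.integer(seed))
  L <- spec$template_length
  pbase <- c((1 - spec$gc) / 2, spec$gc / 2, spec$gc / 2, (1 - spec$gc) / 2)
  master <- sample(.BASES, L, replace = TRUE, prob = pbase)
  mot <- spec$motifs
  for (i in seq_len(nrow(mot))) {
    p <- mot$ref_pos[[i]]
    ch <- strsplit(mot$sequence[[i]], "", fixed = TRUE)[[1L]]
    master[p:(p + length(ch) - 1L)] <- ch
  }
  motif_pos <- .motif_positions(spec)
  bg_pos <- setdiff(seq_len(L), motif_pos)

  derive <- function(divergence, motif_rule) {
    s <- master
    mut <- bg_pos[stats::runif(length(bg_pos)) < divergence]
    s <- .mutate_at(s, mut)
    for (i in seq_len(nrow(mot))) {
      p <- mot$ref_pos[[i]]
      len <- nchar(mot$sequence[[i]])
      k <- motif_rule(mot$role[[i]], len)
      if (k > 0L) {
        s <- .mutate_at(s, sample(p:(p + len - 1L), k))
      }
    }
    s
  }
  prok_rule <- function(role, len) {
    sample.int(spec$prok_motif_max_mm + 1L, 1L) - 1L
  }
  euk_rule <- function(role, len) {
    if (role == "universal") {
      spec$euk_motif_min_mm
    } else {
      sample.int(spec$broad_motif_max_mm_euk + 1L, 1L) - 1L
    }
  }

  taxa <- spec$taxa
  prok <- list()
  tax_rows <- list()
  for (t in seq_len(nrow(taxa))) {
    for (m in seq_len(taxa$n_members[[t]])) {
      id <- sprintf("%s_m%02d", taxa$genus[[t]], m)
      prok[[id]] <- derive(spec$background_divergence, prok_rule)
      tax_rows[[id]] <- data.frame(
        id = id, domain = taxa$domain[[t]], phylum = taxa$phylum[[t]],
        genus = taxa$genus[[t]],
        species = paste0(taxa$genus[[t]], "_sp"),
        stringsAsFactors = FALSE)
    }
  }

  euk_sets <- list(eukaryote = spec$n_euk, mitochondrion = spec$n_mito,
                   chloroplast = spec$n_chloro)
  euk_recs <- list()
  for (org in names(euk_sets)) {
    n <- euk_sets[[org]]
    if (n == 0L) next
    for (k in seq_len(n)) {
      id <- sprintf("%s_%02d", toupper(substr(org, 1L, 4L)), k)
      euk_recs[[id]] <- list(origin = org,
                             seq = derive(spec$euk_divergence, euk_rule))
    }
  }

  # gapped alignment: prokaryote members + ungapped reference
  ids <- c(names(prok), spec$reference_id)
  rows <- c(prok, list(master))
  names(rows) <- ids
  alnmat <- do.call(rbind, rows)

  # deletion columns in a random third of the prokaryote rows
  if (spec$n_deletion_cols > 0L && length(bg_pos) > spec$n_deletion_cols) {
    del_cols <- sample(bg_pos, spec$n_deletion_cols)
    for (cc in del_cols) {
      hit <- stats::runif(length(prok)) < 1 / 3
      alnmat[which(hit), cc] <- "-"
    }
  }

  # gap-rich insertion columns flanking each motif: reference gapped,
  # most prokaryote rows gapped, the rest carrying a random base
  ins_at <- integer(0)   # insert AFTER this template column
  for (i in seq_len(nrow(mot))) {
    p <- mot$ref_pos[[i]]
    e <- p + nchar(mot$sequence[[i]]) - 1L
    ins_at <- c(ins_at, rep(p - 1L, spec$flank_gap_cols),
                rep(e, spec$flank_gap_cols))
  }
  ins_at <- sort(ins_at)
  nrows <- nrow(alnmat)
  pieces <- list()
  prev <- 0L
  for (a in unique(ins_at)) {
    pieces[[length(pieces) + 1L]] <- alnmat[, (prev + 1L):a, drop = FALSE]
    for (k in seq_len(sum(ins_at == a))) {
      col <- ifelse(stats::runif(nrows) < spec$flank_gap_frac, "-",
                    sample(.BASES, nrows, replace = TRUE))
      col[[nrows]] <- "-"  # the reference never gains an insertion base
      pieces[[length(pieces) + 1L]] <- matrix(col, ncol = 1L)
    }
    prev <- a
  }
  pieces[[length(pieces) + 1L]] <- alnmat[, (prev + 1L):L, drop = FALSE]
  alnmat <- do.call(cbind, pieces)

  alignment <- data.frame(
    id = ids,
    gapped_sequence = apply(alnmat, 1L, paste, collapse = ""),
    stringsAsFactors = FALSE)
  rownames(alignment) <- NULL

  taxonomy <- do.call(rbind, tax_rows)
  taxonomy <- rbind(taxonomy,
                    data.frame(id = spec$reference_id,
                               domain = "Bacteria", phylum = NA_character_,
                               genus = NA_character_, species = NA_character_,
                               stringsAsFactors = FALSE))
  rownames(taxonomy) <- NULL

  prok_ref <- seq_records(
    id = names(prok),
    sequence = vapply(prok, paste, character(1), collapse = ""),
    origin = "bacteria", gene_class = "SSU_rRNA")
  prok_ref <- attach_taxonomy(prok_ref, taxonomy)
  prok_ref$origin <- ifelse(prok_ref$domain == "Archaea",
                            "archaea", "bacteria")
  if (length(euk_recs)) {
    euk_ref <- seq_records(
      id = names(euk_recs),
      sequence = vapply(euk_recs, function(r) paste(r$seq, collapse = ""),
                        character(1)),
      origin = vapply(euk_recs, `[[`, character(1), "origin"),
      gene_class = "SSU_rRNA")
    euk_ref$domain <- "Eukaryota"
    references <- rbind(prok_ref, euk_ref)
  } else {
    references <- prok_ref
  }
  rownames(references) <- NULL

  list(alignment = alignment, taxonomy = taxonomy, references = references,
       motifs = mot, reference_id = spec$reference_id, spec = spec)
}

#' Simulate amplicon reads and paired short reads from a community
#'
#' Amplicon reads are built as forward oligo + template insert + reverse
#' complement of the reverse oligo, taken from a member template sampled by
#' taxon abundance, with substitution errors at the spec's rate, random
#' strand flips, and Phred+33 qualities. Configurable fractions of reads
#' are forced to violate each amplicon filter (ambiguous base, length
#' bound, mean quality). Paired short reads are sampled from templates with
#' opposite mate strands; fractions can be forced to fail purity or carry
#' low-quality flag bases. Deterministic for a fixed seed.
#'
#' @param gen output of [generate_alignment()].
#' @param primer_pair list or one-row `data.frame` with `forward_seq` (or
#'   `forward`) and `reverse_oligo` elements.
#' @param n_amplicon,n_pairs read counts.
#' @param error_rate substitution error rate (default from the spec).
#' @param flip_prob probability an amplicon read is reverse-complemented.
#' @param base_quality Phred score of ordinary bases (default 35).
#' @param frac_ambiguous,frac_length_violation,frac_low_quality fractions
#'   of amplicon reads forced to fail each filter rule (in rule order;
#'   disjoint sets).
#' @param len_min length bound used when forcing length violations.
#' @param read_length,fragment_length short-read geometry, nt.
#' @param frac_purity_fail,frac_bflag fractions of pairs forced to fail
#'   purity filtering or to carry two flag-quality bases in the first 60 nt.
#' @param seed integer seed (default `spec$seed + 1`).
#' @return list with `amplicon` (read `data.frame` plus truth columns
#'   `true_phylum`, `true_genus`, `flipped`, `insert`), and `pairs`
#'   (`data.frame` for [filter_short_read_pairs()] plus truth columns).
#' @export
generate_reads <- function(gen, primer_pair,
                           n_amplicon = 200L, n_pairs = 200L,
                           error_rate = gen$spec$read_error_rate,
                           flip_prob = 0.5, base_quality = 35L,
                           frac_ambiguous = 0, frac_length_violation = 0,
                           frac_low_quality = 0, len_min = 350L,
                           read_length = 76L, fragment_length = 200L,
                           frac_purity_fail = 0, frac_bflag = 0,
                           seed = gen$spec$seed + 1L) {
  set.seed(as.integer(seed))
  fwd <- if (!is.null(primer_pair$forward_seq)) primer_pair$forward_seq else primer_pair$forward
  rev_oligo <- primer_pair$reverse_oligo
  stopifnot(.is_concrete(fwd), .is_concrete(rev_oligo))
  rc_rev <- revcomp(rev_oligo)

  taxa <- gen$spec$taxa
  prok <- gen$references[gen$references$origin %in% c("bacteria", "archaea"), ]
  # template inserts per taxon member: locate the primer sites once
  site_of <- function(tpl) {
    pf <- .mm_profile(fwd, tpl)
    pr <- .mm_profile(rc_rev, tpl)
    fo <- which.min(pf)
    ro <- which.min(pr)
    if (min(pf) > 2L || min(pr) > 2L) return(NULL)
    c(start = fo, end = ro + nchar(rc_rev) - 1L)
  }
  sites <- lapply(prok$sequence, site_of)
  bad <- vapply(sites, is.null, logical(1))
  if (any(bad)) {
    stop("no primer site in template(s) of: ",
         paste(unique(prok$genus[bad]), collapse = ", "))
  }

  add_errors <- function(ch, rate) {
    if (rate <= 0) return(ch)
    .mutate_at(ch, which(stats::runif(length(ch)) < rate))
  }

  # sample member templates by taxon abundance
  prok_tax_idx <- match(prok$genus, taxa$genus)
  w <- taxa$abundance[prok_tax_idx] /
    tapply(rep(1, nrow(prok)), prok$genus, sum)[prok$genus]
  pick <- sample.int(nrow(prok), n_amplicon, replace = TRUE,
                     prob = as.numeric(w))

  n_amb <- round(frac_ambiguous * n_amplicon)
  n_len <- round(frac_length_violation * n_amplicon)
  n_lowq <- round(frac_low_quality * n_amplicon)
  viol <- rep("none", n_amplicon)
  if (n_amb + n_len + n_lowq > n_amplicon) {
    stop("violation fractions exceed 1")
  }
  viol[seq_len(n_amb)] <- "ambiguous"
  if (n_len) viol[n_amb + seq_len(n_len)] <- "length"
  if (n_lowq) viol[n_amb + n_len + seq_len(n_lowq)] <- "low_quality"
  viol <- sample(viol)  # decouple violation from template identity

  amp <- vector("list", n_amplicon)
  for (i in seq_len(n_amplicon)) {
    k <- pick[[i]]
    tpl <- prok$sequence[[k]]
    st <- sites[[k]]
    amplicon <- strsplit(substr(tpl, st[["start"]], st[["end"]]), "",
                         fixed = TRUE)[[1L]]
    insert <- substr(tpl, st[["start"]] + nchar(fwd),
                     st[["end"]] - nchar(rc_rev))
    amplicon <- add_errors(amplicon, error_rate)
    qual <- base_quality + sample(-2:2, length(amplicon), replace = TRUE)
    if (viol[[i]] == "ambiguous") {
      amplicon[[sample.int(length(amplicon), 1L)]] <- "N"
    } else if (viol[[i]] == "length") {
      keep <- max(1L, len_min - 10L)
      amplicon <- amplicon[seq_len(min(keep, length(amplicon)))]
      qual <- qual[seq_along(amplicon)]
    } else if (viol[[i]] == "low_quality") {
      qual <- rep(10L, length(amplicon))
    }
    s <- paste(amplicon, collapse = "")
    q <- .phred_string(qual)
    flipped <- stats::runif(1) < flip_prob
    if (flipped) {
      s <- revcomp(s)
      q <- .reverse_string(q)
    }
    amp[[i]] <- data.frame(
      id = sprintf("AMP%05d", i), sequence = s, quality = q,
      true_phylum = prok$phylum[[k]], true_genus = prok$genus[[k]],
      flipped = flipped, insert = insert, violation = viol[[i]],
      stringsAsFactors = FALSE)
  }
  amplicon_df <- do.call(rbind, amp)

  pr <- vector("list", n_pairs)
  n_pur <- round(frac_purity_fail * n_pairs)
  n_bfl <- round(frac_bflag * n_pairs)
  pviol <- rep("none", n_pairs)
  if (n_pur + n_bfl > n_pairs) stop("violation fractions exceed 1")
  pviol[seq_len(n_pur)] <- "purity"
  if (n_bfl) pviol[n_pur + seq_len(n_bfl)] <- "bflag"
  pviol <- sample(pviol)
  pick2 <- sample.int(nrow(prok), n_pairs, replace = TRUE,
                      prob = as.numeric(w))
  for (i in seq_len(n_pairs)) {
    k <- pick2[[i]]
    tpl <- prok$sequence[[k]]
    L <- nchar(tpl)
    flen <- min(fragment_length, L)
    pos <- sample.int(L - flen + 1L, 1L)
    frag <- substr(tpl, pos, pos + flen - 1L)
    m1 <- strsplit(substr(frag, 1L, read_length), "", fixed = TRUE)[[1L]]
    m2 <- strsplit(revcomp(substr(frag, flen - read_length + 1L, flen)), "",
                   fixed = TRUE)[[1L]]
    m1 <- add_errors(m1, error_rate)
    m2 <- add_errors(m2, error_rate)
    q1 <- base_quality + sample(-2:2, length(m1), replace = TRUE)
    q2 <- base_quality + sample(-2:2, length(m2), replace = TRUE)
    purity1 <- TRUE
    if (pviol[[i]] == "purity") purity1 <- FALSE
    if (pviol[[i]] == "bflag") q1[sample.int(min(60L, length(q1)), 2L)] <- 2L
    pr[[i]] <- data.frame(
      pair_id = sprintf("PAIR%05d", i),
      seq1 = paste(m1, collapse = ""), qual1 = .phred_string(q1),
      purity_ok1 = purity1,
      seq2 = paste(m2, collapse = ""), qual2 = .phred_string(q2),
      purity_ok2 = TRUE,
      true_phylum = prok$phylum[[k]], true_genus = prok$genus[[k]],
      violation = pviol[[i]], stringsAsFactors = FALSE)
  }
  pairs_df <- do.call(rbind, pr)

  list(amplicon = amplicon_df, pairs = pairs_df)
}

#' Generate a mock similarity-hit table encoding known read origins
#'
#' Every read receives a best hit to the subject of its true genus; tie
#' groups and decoy hits are configurable. The emitted table follows the
#' 12-column blast-tabular dialect and comes with subject metadata and the
#' ground-truth table, so profile-recovery can be checked exactly.
#'
#' @param truth `data.frame` with columns `id`, `true_phylum`,
#'   `true_genus` (for pairs, one row per pair; mate hits are emitted as
#'   `<id>/1` and `<id>/2` with opposite strands when `paired = TRUE`).
#' @param tie_fraction fraction of reads given a second, equal-bitscore hit
#'   in a different genus (mass then splits 50/50).
#' @param best_identity percent identity of the true best hit (default
#'   99; set below the genus tier, e.g. 90, to make reads genus-unassigned
#'   but phylum-assigned).
#' @param decoy if `TRUE`, every read also gets a lower-bitscore hit to a
#'   different genus (must never attract mass).
#' @param aln_len alignment length reported for every hit.
#' @param paired emit mate-wise hits for read pairs.
#' @param seed integer seed.
#' @return list with `hits`, `subjects`, `truth` (the input, with the tie
#'   partner genus recorded in `tie_genus`).
#' @export
generate_hits <- function(truth, tie_fraction = 0, best_identity = 99,
                          decoy = FALSE, aln_len = 400L, paired = FALSE,
                          seed = 7L) {
  set.seed(as.integer(seed))
  taxa <- unique(truth[, c("true_phylum", "true_genus")])
  subjects <- data.frame(
    sseqid = paste0("SUBJ_", taxa$true_genus),
    phylum = taxa$true_phylum, genus = taxa$true_genus,
    gene_class = "SSU_rRNA", stringsAsFactors = FALSE)
  n <- nrow(truth)
  is_tie <- stats::runif(n) < tie_fraction
  other <- vapply(truth$true_genus, function(g) {
    pool <- setdiff(subjects$genus, g)
    if (length(pool) == 0L) NA_character_ else sample(pool, 1L)
  }, character(1), USE.NAMES = FALSE)
  truth$tie_genus <- ifelse(is_tie, other, NA_character_)

  mk_hit <- function(qid, genus, bitscore, pident, strand) {
    sstart <- 100L
    send <- sstart + aln_len - 1L
    if (strand == "-") { tmp <- sstart; sstart <- send; send <- tmp }
    data.frame(qseqid = qid, sseqid = paste0("SUBJ_", genus),
               pident = pident, length = aln_len, mismatch = 0L,
               gapopen = 0L, qstart = 1L, qend = aln_len,
               sstart = sstart, send = send,
               evalue = 1e-50, bitscore = bitscore,
               strand = strand, stringsAsFactors = FALSE)
  }
  rows <- list()
  for (i in seq_len(n)) {
    qids <- if (paired) paste0(truth$id[[i]], c("/1", "/2")) else truth$id[[i]]
    strands <- if (paired) c("+", "-") else "+"
    for (j in seq_along(qids)) {
      rows[[length(rows) + 1L]] <-
        mk_hit(qids[[j]], truth$true_genus[[i]], 500, best_identity,
               strands[[j]])
      if (is_tie[[i]] && !is.na(truth$tie_genus[[i]])) {
        rows[[length(rows) + 1L]] <-
          mk_hit(qids[[j]], truth$tie_genus[[i]], 500, best_identity,
                 strands[[j]])
      }
      if (decoy && !is.na(other[[i]])) {
        rows[[length(rows) + 1L]] <-
          mk_hit(qids[[j]], other[[i]], 300, best_identity, strands[[j]])
      }
    }
  }
  list(hits = do.call(rbind, rows), subjects = subjects, truth = truth)
}
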
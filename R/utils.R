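#' Reverse complement of nucleotide sequences
#'
#' Complements IUPAC nucleotide codes and reverses each string. Gap
#' characters (`-`) are preserved in place value but reversed with the rest
#' of the sequence.
#'
#' @param x character vector of sequences (upper or lower case).
#' @return character vector of reverse-complemented sequences.
#' @examples
#' revcomp("ACGT")       # "ACGT"
#' revcomp("AAACGTRY")   # "RYACGTTT"
#' @export
revcomp <- function(x) {
  stopifnot(is.character(x))
  comp <- chartr(
    "ACGTRYSWKMBDHVNacgtryswkmbdhvn",
    "TGCAYRSWMKVHDBNtgcayrswmkvhdbn",
    x
  )
  out <- vapply(
    strsplit(comp, "", fixed = TRUE),
    function(ch) paste(rev(ch), collapse = ""),
    character(1)
  )
  out[is.na(x)] <- NA_character_
  out
}

# the five window-scan symbols; anything else is an ambiguity code
.CORE5 <- c("A", "C", "G", "T", "-")

# split equal-length strings into an n x width character matrix
.char_matrix <- function(seqs) {
  w <- nchar(seqs[[1L]])
  matrix(unlist(strsplit(seqs, "", fixed = TRUE), use.names = FALSE),
         ncol = w, byrow = TRUE)
}

# Hamming-style distance of every row of `mat` to `target` (char vector).
# Ambiguity codes (anything outside A/C/G/T/-) mismatch every symbol,
# including themselves.
.dist_to <- function(mat, target) {
  n <- nrow(mat)
  w <- ncol(mat)
  tm <- matrix(target, n, w, byrow = TRUE)
  amb_m <- matrix(!(mat %in% .CORE5), n, w)
  amb_t <- matrix(!(target %in% .CORE5), n, w, byrow = TRUE)
  as.integer(rowSums((mat != tm) | amb_m | amb_t))
}

.is_concrete <- function(x) {
  !is.na(x) & grepl("^[ACGT]+$", x)
}

# per-offset mismatch counts of a concrete primer against a template
# (sense strand, ungapped Hamming at every offset); integer(0) if the
# primer does not fit
.mm_profile <- function(primer, template) {
  w <- nchar(primer)
  L <- nchar(template)
  if (w < 1L || w > L) return(integer(0))
  p <- utf8ToInt(primer)
  t <- utf8ToInt(template)
  n_off <- L - w + 1L
  mm <- integer(n_off)
  for (i in seq_len(w)) {
    mm <- mm + (t[i:(i + n_off - 1L)] != p[i])
  }
  mm
}

# decode a Phred+33 quality string to integer scores
.phred <- function(q) {
  if (is.na(q) || !nzchar(q)) return(integer(0))
  utf8ToInt(q) - 33L
}

# encode integer scores to Phred+33
.phred_string <- function(scores) {
  intToUtf8(pmin(pmax(scores, 0L), 93L) + 33L)
}

.reverse_string <- function(x) {
  vapply(strsplit(x, "", fixed = TRUE),
         function(ch) paste(rev(ch), collapse = ""), character(1))
}
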
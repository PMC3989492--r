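# Independent brute-force oracles, written against the definitions rather
# than the package implementation: per-character loops, no shared helpers.

oracle_revcomp <- function(x) {
  map <- c(A = "T", C = "G", G = "C", T = "A")
  ch <- strsplit(x, "")[[1]]
  paste(rev(unname(map[ch])), collapse = "")
}

# minimum Hamming distance of primer (or its reverse complement) over all
# offsets of template; NA when the primer does not fit
oracle_min_mismatch <- function(primer, template, orientation = "forward") {
  if (orientation == "reverse") primer <- oracle_revcomp(primer)
  p <- strsplit(primer, "")[[1]]
  t <- strsplit(template, "")[[1]]
  w <- length(p)
  if (w > length(t)) return(NA_integer_)
  best <- w
  for (off in 0:(length(t) - w)) {
    d <- 0L
    for (i in 1:w) if (t[off + i] != p[i]) d <- d + 1L
    if (d < best) best <- d
  }
  best
}

# slice distance with the window-scan rules: gap is a fifth symbol, any
# other non-ACGT character mismatches everything including itself
oracle_slice_dist <- function(a, b) {
  core <- c("A", "C", "G", "T", "-")
  av <- strsplit(a, "")[[1]]
  bv <- strsplit(b, "")[[1]]
  d <- 0L
  for (i in seq_along(av)) {
    if (!(av[i] %in% core) || !(bv[i] %in% core) || av[i] != bv[i]) {
      d <- d + 1L
    }
  }
  d
}

# enumerate every distinct observed slice, count neighbours within max_mm,
# break frequency ties lexicographically ("-" sorts before "A")
oracle_consensus <- function(slices, max_mm = 1) {
  distinct <- sort(unique(slices), method = "radix")
  best_seq <- NULL
  best_freq <- -1L
  for (s in distinct) {
    f <- 0L
    for (t in slices) if (oracle_slice_dist(s, t) <= max_mm) f <- f + 1L
    if (f > best_freq) {
      best_freq <- f
      best_seq <- s
    }
  }
  list(consensus = best_seq, consensus_freq = best_freq)
}

random_dna <- function(n, alphabet = c("A", "C", "G", "T")) {
  paste(sample(alphabet, n, replace = TRUE), collapse = "")
}
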
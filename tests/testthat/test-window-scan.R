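test_that("reference coordinate map walks gaps correctly", {
  aln <- data.frame(id = c("ref", "x"),
                    gapped_sequence = c("ACGT", "TTTT"))
  expect_equal(as.integer(map_to_reference_coords(aln, "ref")), 1:4)

  aln$gapped_sequence[1] <- "AC-GT"
  aln$gapped_sequence[2] <- "ACCGT"
  m <- map_to_reference_coords(aln, "ref")
  expect_equal(as.integer(m), c(1, 2, 2, 3, 4))

  aln$gapped_sequence[1] <- "--AC"
  aln$gapped_sequence[2] <- "GGAC"
  m <- map_to_reference_coords(aln, "ref")
  expect_equal(as.integer(m), c(0, 0, 1, 2))
  expect_equal(attr(m, "flagged"), c(TRUE, TRUE, FALSE, FALSE))

  expect_error(map_to_reference_coords(aln, "absent"), "not in alignment")
})

test_that("window consensus matches the worked examples", {
  u <- rep("ACGTACGTACGTACG", 4)
  expect_equal(window_consensus(u),
               list(consensus = "ACGTACGTACGTACG", consensus_freq = 4L))

  s <- c(rep("AAAAAAAAAAAAAAA", 3), rep("AAAAAAAAAAAAAAT", 2),
         "CCCCCCCCCCCCCCC")
  wc <- window_consensus(s, max_mm = 1)
  expect_equal(wc$consensus, "AAAAAAAAAAAAAAA")  # tie at 5, lexicographic
  expect_equal(wc$consensus_freq, 5L)

  g <- c("AC-TA", "AC-TA", "ACGTA")
  wc <- window_consensus(g, max_mm = 1)  # gap is a fifth symbol
  expect_equal(wc$consensus, "AC-TA")
  expect_equal(wc$consensus_freq, 3L)

  expect_error(window_consensus(character(0)), "empty")
})

test_that("window consensus equals the brute-force oracle on random data", {
  set.seed(101)
  for (rep in 1:60) {
    n <- sample(3:12, 1)
    w <- sample(4:8, 1)
    mm <- sample(0:2, 1)
    slices <- replicate(n, random_dna(w, c("A", "C", "G", "T", "-")))
    got <- window_consensus(slices, max_mm = mm)
    want <- oracle_consensus(slices, max_mm = mm)
    expect_identical(got$consensus, want$consensus)
    expect_equal(got$consensus_freq, want$consensus_freq)
  }
})

test_that("consensus frequency is non-decreasing in the mismatch allowance", {
  set.seed(77)
  for (rep in 1:20) {
    slices <- replicate(8, random_dna(6, c("A", "C", "G", "T", "-")))
    freqs <- vapply(0:3, function(mm) {
      window_consensus(slices, max_mm = mm)$consensus_freq
    }, integer(1))
    expect_true(all(diff(freqs) >= 0))
  }
})

test_that("phylum coverage counts members within the allowance", {
  slices <- c("AAAA", "AAAT", "AATT", "TTTT")
  phyla <- c("P1", "P1", "P2", "P2")
  cov <- phylum_coverage_rate("AAAA", slices, phyla, max_mm = 1)
  expect_equal(unname(cov["P1"]), 100)
  expect_equal(unname(cov["P2"]), 0)
  cov2 <- phylum_coverage_rate("AAAA", slices, rep("P", 4), max_mm = 1)
  expect_equal(unname(cov2["P"]), 50)  # 2 of 4 members
  # ambiguity codes mismatch everything, including themselves
  expect_equal(unname(phylum_coverage_rate("AANA", c("AANA"), "P", 0)), 0)
})

test_that("coverage display bins follow the conservation palette", {
  expect_equal(bin_coverage(c(0, 49.9, 50, 79, 85, 95, 99.9, 100)),
               c("black", "black", "blue", "blue", "green", "yellow",
                 "yellow", "red"))
})

test_that("window variability is summed per-column entropy in bits", {
  expect_equal(window_variability(rep("AAAA", 5)), 0)
  expect_equal(window_variability(c("AAAA", "AAAT")), 1)  # one 50/50 column
  expect_equal(window_variability(c("A", "A", "C", "G")), 1.5)
  # gap participates as a fifth symbol; bound is width * log2(5)
  set.seed(3)
  for (rep in 1:10) {
    slices <- replicate(6, random_dna(5, c("A", "C", "G", "T", "-")))
    v <- window_variability(slices)
    expect_gte(v, 0)
    expect_lte(v, 5 * log2(5) + 1e-12)
  }
  # relative entropy to the uniform 5-symbol background is the complement
  s <- c("AC-TA", "ACGTA", "TCGTA")
  expect_equal(window_variability(s, "kl_uniform"),
               5 * log2(5) - window_variability(s, "shannon"))
})

test_that("scan produces one window per start column with coordinates", {
  aln <- data.frame(
    id = c("ref", "a", "b"),
    gapped_sequence = c(strrep("ACGTA", 4), strrep("ACGTA", 4),
                        strrep("ACGTT", 4)))
  tax <- data.frame(id = c("ref", "a", "b"), domain = "Bacteria",
                    phylum = c("P1", "P1", "P2"), genus = NA, species = NA)
  w <- scan_windows(aln, tax, width = 15, max_mm = 1, reference_id = "ref")
  expect_equal(nrow(w), 6)  # L - width + 1 = 20 - 15 + 1
  expect_equal(w$start_col, 1:6)
  expect_equal(w$ref_pos, 1:6)
  w1 <- scan_windows(aln[, ], tax, width = 20, reference_id = "ref")
  expect_equal(nrow(w1), 1)
  expect_error(scan_windows(aln, tax, width = 30, reference_id = "ref"),
               "shorter")
})

test_that("a planted invariant window reaches 100% coverage in every phylum", {
  set.seed(9)
  motif <- "GATTACAGATTACAG"  # 15 nt, planted in every record
  mk <- function() paste0(random_dna(10), motif, random_dna(10))
  aln <- data.frame(id = c("ref", paste0("r", 1:6)),
                    gapped_sequence = c(mk(), replicate(6, mk())))
  tax <- data.frame(id = aln$id, domain = "Bacteria",
                    phylum = c(NA, rep(c("P1", "P2", "P3"), 2)),
                    genus = NA, species = NA)
  w <- scan_windows(aln, tax, reference_id = "ref")
  at <- w[w$start_col == 11, ]
  expect_equal(at$consensus, motif)
  expect_equal(unname(unlist(at[, c("cov_P1", "cov_P2", "cov_P3")])),
               c(100, 100, 100))
})

test_that("candidate selection rejects gapped consensi and weak coverage", {
  w <- data.frame(
    start_col = 1:4, ref_pos = 1:4, ref_pos_flagged = FALSE,
    consensus = c("ACGTACGTACGTACG", "ACGT-CGTACGTACG",
                  "ACGTACGTACGTACT", "ACGTACGTACGTACC"),
    consensus_freq = 4L, variability = 0,
    cov_P1 = c(100, 100, 85, 95), cov_P2 = c(100, 100, 85, 50))
  sel <- select_candidates(w, min_coverage = 90, min_phylum_fraction = 0.9)
  # gapped consensus rejected regardless of coverage; 85% in half the
  # phyla rejected; high coverage in only one of two phyla rejected
  expect_equal(sel$start_col, 1L)
  # keep-interval on reference positions
  w$cov_P1 <- w$cov_P2 <- 100
  w$consensus <- "ACGTACGTACGTACG"
  sel2 <- select_candidates(w, ref_pos_range = c(2, 3))
  expect_equal(sel2$ref_pos, 2:3)
})
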
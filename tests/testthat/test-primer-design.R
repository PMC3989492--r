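test_that("merging neighbouring windows reproduces the 342F/806R oligos", {
  fwd <- data.frame(ref_pos = c(342L, 343L),
                    consensus = c("CTACGGGGGGCAGCA", "TACGGGGGGCAGCAG"))
  out <- merge_neighbouring(fwd)
  expect_equal(nrow(out), 1)
  expect_equal(out$sequence, "CTACGGGGGGCAGCAG")
  expect_equal(out$width, 16L)
  expect_equal(out$ref_start, 342L)
  expect_equal(out$ref_end, 357L)

  rev <- data.frame(ref_pos = 790:792,
                    consensus = c("GGACTACCGGGGTAT", "GACTACCGGGGTATC",
                                  "ACTACCGGGGTATCT"))
  out2 <- merge_neighbouring(rev)
  expect_equal(out2$sequence, "GGACTACCGGGGTATCT")
  expect_equal(out2$width, 17L)
  expect_equal(out2$ref_end, 806L)
})

test_that("an isolated window becomes a candidate of its own width", {
  w <- data.frame(ref_pos = 100L, consensus = "ACGTACGTACGTACG")
  out <- merge_neighbouring(w)
  expect_equal(out$sequence, w$consensus)
  expect_equal(out$ref_end, 114L)
  expect_equal(out$n_windows, 1L)
})

test_that("runs split at overlap disagreement and coverage degradation", {
  # consensus at 101 disagrees with 100 on the overlap -> split, no error
  w <- data.frame(ref_pos = c(100L, 101L),
                  consensus = c("AAAAAAAAAAAAAAA", "CCCCCCCCCCCCCCC"))
  out <- merge_neighbouring(w)
  expect_equal(nrow(out), 2)
  expect_equal(out$width, c(15L, 15L))

  # a coverage function that punishes merged length: no merge survives
  w2 <- data.frame(ref_pos = c(100L, 101L, 102L),
                   consensus = c("AAAAAAAAAAAAAAA", "AAAAAAAAAAAAAAT",
                                 "AAAAAAAAAAAAATT"))
  drop_on_merge <- function(s) c(P1 = if (nchar(s) > 15) 50 else 100)
  out2 <- merge_neighbouring(w2, coverage_fn = drop_on_merge)
  expect_equal(nrow(out2), 3)
  # with a tolerant floor the full run merges again
  out3 <- merge_neighbouring(w2, coverage_fn = drop_on_merge, tolerance = 50)
  expect_equal(nrow(out3), 1)
  expect_equal(out3$sequence, "AAAAAAAAAAAAAAATT")

  # merging never lowers any phylum below the constituent floor - tolerance
  cov_of <- function(s) c(P1 = 100 - 2 * (nchar(s) - 15), P2 = 90)
  out4 <- merge_neighbouring(w2, coverage_fn = cov_of, tolerance = 2)
  for (i in seq_len(nrow(out4))) {
    runpos <- out4$provenance[[i]]
    floors <- Reduce(pmin, lapply(runpos, function(p) {
      cov_of(w2$consensus[w2$ref_pos == p])
    }))
    expect_true(all(cov_of(out4$sequence[i]) >= floors - 2))
  }
})

test_that("a fully merged run has width + n_windows - 1 bases", {
  set.seed(55)
  for (rep in 1:10) {
    w <- sample(8:15, 1)
    n <- sample(2:6, 1)
    long <- random_dna(w + n - 1)
    win <- data.frame(
      ref_pos = seq_len(n) + 50L,
      consensus = vapply(seq_len(n), function(i) substr(long, i, i + w - 1),
                         character(1)))
    out <- merge_neighbouring(win)
    expect_equal(nrow(out), 1)
    expect_equal(out$width, w + n - 1L)
    expect_equal(out$sequence, long)
    expect_equal(out$provenance[[1]], win$ref_pos)
  }
})

test_that("degenerate primers resolve to the best-coverage variant", {
  # one genus per record, one phylum: coverage counts genera hit exactly
  recs <- seq_records(id = paste0("r", 1:4),
                      sequence = c("ACG", "ACG", "ACG", "ATG"),
                      phylum = "P1", genus = paste0("g", 1:4),
                      origin = "bacteria")
  out <- resolve_degenerate("AYG", recs, max_mm = 0)
  expect_equal(out$primer, "ACG")
  expect_equal(nrow(out$report), 2)

  # all variants tied -> lexicographically smallest
  none <- seq_records(id = "x", sequence = "TTT", phylum = "P1",
                      genus = "g", origin = "bacteria")
  expect_equal(resolve_degenerate("ANG", none, max_mm = 0)$primer, "AAG")

  # no ambiguity codes: unchanged, single-row report
  out2 <- resolve_degenerate("ACG", recs, max_mm = 0)
  expect_equal(out2$primer, "ACG")
  expect_equal(nrow(out2$report), 1)

  # the winner's coverage is maximal over the exhaustive report
  set.seed(66)
  recs2 <- seq_records(id = paste0("r", 1:8),
                       sequence = replicate(8, random_dna(30)),
                       phylum = rep(c("P1", "P2"), each = 4),
                       genus = paste0("g", 1:8), origin = "bacteria")
  out3 <- resolve_degenerate("ACRYGW", recs2, max_mm = 1)
  best <- out3$report$mean_coverage[out3$report$variant == out3$primer]
  expect_true(all(out3$report$mean_coverage <= best))

  expect_error(resolve_degenerate("NNNNNNNN", recs, cap = 1024), "cap")
})

test_that("primer pairing enforces span limits and emits the reverse oligo", {
  f <- data.frame(sequence = "CTACGGGGGGCAGCAG", ref_start = 342L,
                  ref_end = 357L, mean_coverage = 95)
  r <- data.frame(sequence = "GGACTACCGGGGTATCT", ref_start = 790L,
                  ref_end = 806L, mean_coverage = 90)
  p <- pair_primers(f, r, min_span = 350, max_span = 550)
  expect_equal(p$amplicon_span, 465L)  # 806 - 342 + 1
  expect_equal(p$reverse_oligo, "AGATACCCCGGTAGTCC")
  expect_equal(p$mean_coverage, 92.5)

  # forward end at or after reverse start is rejected
  expect_equal(nrow(suppressMessages(pair_primers(r, f, min_span = 1,
                                                  max_span = 5000))), 0)
  # span ceiling below every span -> empty with diagnostic
  expect_message(out <- pair_primers(f, r, min_span = 1, max_span = 100),
                 "no admissible")
  expect_equal(nrow(out), 0)
})

test_that("pair ranking is stable under candidate order permutation", {
  set.seed(12)
  f <- data.frame(sequence = c("AAAAAAAAAA", "CCCCCCCCCC", "GGGGGGGGGG"),
                  ref_start = c(100L, 120L, 140L),
                  ref_end = c(109L, 129L, 149L),
                  mean_coverage = c(90, 95, 95))
  r <- data.frame(sequence = c("TTTTTTTTTT", "ACACACACAC"),
                  ref_start = c(400L, 480L), ref_end = c(409L, 489L),
                  mean_coverage = c(80, 85))
  base <- pair_primers(f, r, min_span = 100, max_span = 500)
  for (i in 1:5) {
    shuf <- pair_primers(f[sample(3), ], r[sample(2), ],
                         min_span = 100, max_span = 500)
    expect_equal(shuf, base)
  }
})
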
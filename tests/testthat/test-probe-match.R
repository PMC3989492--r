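test_that("min_mismatch handles exact sites, strands and no-site", {
  expect_equal(min_mismatch("ACGT", "TTACGTTT"), 0L)
  tpl <- paste0("AAAA", "ACGTACGTACGTACGT", "AAAA")
  tpl1 <- sub("ACGTACGTACGTACGT", "ACGTACGAACGTACGT", tpl)
  expect_equal(min_mismatch("ACGTACGTACGTACGT", tpl1), 1L)
  # reverse orientation finds the reverse complement on the sense strand
  p <- "ACCGGTTA"
  tpl2 <- paste0("GGGG", oracle_revcomp(p), "GGGG")
  expect_equal(min_mismatch(p, tpl2, orientation = "reverse"), 0L)
  expect_true(is.na(min_mismatch("ACGTACGT", "ACG")))
  expect_error(min_mismatch("ACNT", "ACGTACGT"), "concrete")
})

test_that("min_mismatch agrees with the all-offsets oracle on random strings", {
  set.seed(202)
  for (rep in 1:80) {
    w <- sample(4:18, 1)
    L <- sample(w:200, 1)
    p <- random_dna(w)
    tpl <- random_dna(L)
    ori <- sample(c("forward", "reverse"), 1)
    expect_equal(min_mismatch(p, tpl, ori), oracle_min_mismatch(p, tpl, ori))
  }
})

test_that("primer and reverse complement with swapped orientation agree", {
  set.seed(33)
  for (rep in 1:25) {
    p <- random_dna(10)
    tpl <- random_dna(60)
    expect_equal(min_mismatch(p, tpl, "forward"),
                 min_mismatch(revcomp(p), tpl, "reverse"))
  }
})

test_that("sequence coverage counts records within the allowance", {
  p <- "ACGTACGT"
  recs <- seq_records(
    id = paste0("r", 1:4),
    sequence = c(paste0("TT", p, "TT"),            # 0 mm
                 paste0("TT", "ACGTACGA", "TT"),   # 1 mm
                 paste0("TT", "ACGAACGA", "TT"),   # 2 mm
                 strrep("G", 30)),                 # far
    origin = "eukaryote")
  cov <- sequence_coverage(p, recs, max_mm = 2)
  expect_equal(cov$coverage, 75)
  expect_equal(cov$matched, 3L)
  cov0 <- sequence_coverage(p, recs[1:3, ], max_mm = 0)
  expect_equal(cov0$coverage, 100 / 3)
  # a primer at >= 3 mismatches from every best site covers nothing
  far <- seq_records(id = "x", sequence = strrep("G", 40), origin = "eukaryote")
  expect_equal(sequence_coverage("AAAAAAAA", far, max_mm = 2)$coverage, 0)
})

test_that("genus coverage requires a strict majority of members", {
  p <- "ACGTACGT"
  hit <- paste0("TT", p, "TT")
  miss <- strrep("G", 20)
  recs <- seq_records(
    id = paste0("r", 1:5),
    sequence = c(hit, hit, miss, hit, miss),
    phylum = "P1",
    genus = c("A", "A", "A", "B", "B"),
    origin = "bacteria")
  # genus A: 2/3 match (majority); genus B: 1/2 (exactly half, no majority)
  gc <- genus_coverage(p, recs, max_mm = 1)
  expect_equal(gc$coverage, 50)
  all_hit <- recs
  all_hit$sequence <- hit
  expect_equal(genus_coverage(p, all_hit)$coverage, 100)
  none <- recs
  none$sequence <- miss
  expect_equal(genus_coverage(p, none)$coverage, 0)
  # duplicating a fully-matching genus member preserves the majority
  dup <- rbind(all_hit, all_hit[1, ])
  expect_equal(genus_coverage(p, dup)$coverage, 100)
})

test_that("coverage metrics are non-decreasing in max_mm", {
  set.seed(404)
  for (rep in 1:10) {
    p <- random_dna(10)
    recs <- seq_records(
      id = paste0("r", 1:12),
      sequence = replicate(12, random_dna(80)),
      phylum = rep(c("P1", "P2"), each = 6),
      genus = rep(c("g1", "g2", "g3", "g4"), each = 3),
      origin = "bacteria")
    sc <- vapply(0:3, function(mm) {
      mean(sequence_coverage(p, recs, max_mm = mm)$coverage)
    }, numeric(1))
    gcv <- vapply(0:3, function(mm) {
      mean(genus_coverage(p, recs, max_mm = mm)$coverage)
    }, numeric(1))
    expect_true(all(diff(sc) >= 0))
    expect_true(all(diff(gcv) >= 0))
  }
})

test_that("eukaryote exclusion removes >50% coverage, keeps exactly 50%", {
  cand <- data.frame(sequence = c("AAAAAAAA", "CCCCCCCC", "GGGGGGGG"),
                     stringsAsFactors = FALSE)
  mk <- function(seqs, origin) seq_records(id = seq_along(seqs),
                                           sequence = seqs, origin = origin)
  # 12 eukaryote records: A-primer site in 6 (exactly 50% -> kept),
  # C-primer site in 5 (<50% -> kept), G-primer nowhere (0% -> kept)
  euk12 <- mk(c(rep("TTAAAAAAAATT", 6), rep("GGCCCCCCCCGG", 5),
                strrep("T", 12)), "eukaryote")
  out <- eukaryote_exclusion_filter(cand, mito_records = NULL,
                                    euk_records = euk12,
                                    max_mm = 2, max_cov = 50)
  expect_equal(nrow(out$kept), 3)
  out2 <- eukaryote_exclusion_filter(
    cand, mito_records = NULL,
    euk_records = mk(c(rep("TTAAAAAAAATT", 6), rep("GGCCCCCCCCGG", 4)),
                     "eukaryote"),
    max_mm = 2, max_cov = 50)
  # now A-primer covers 6/10 = 60% -> excluded; C covers 40% -> kept
  expect_equal(out2$excluded$sequence, "AAAAAAAA")
  expect_equal(out2$excluded$reason, "eukaryotic coverage")
  expect_setequal(out2$kept$sequence, c("CCCCCCCC", "GGGGGGGG"))
  # mitochondrial coverage alone also excludes
  out3 <- eukaryote_exclusion_filter(
    cand[1, , drop = FALSE],
    mito_records = mk(rep("TTAAAAAAAATT", 4), "mitochondrion"),
    euk_records = NULL, max_mm = 2, max_cov = 50)
  expect_equal(out3$excluded$reason, "mitochondrial coverage")
})

test_that("coverage matrix separates prokaryote and eukaryote metrics", {
  p <- "ACGTACGTACGT"
  prok <- seq_records(id = paste0("b", 1:4),
                      sequence = rep(paste0("TT", p, "TT"), 4),
                      phylum = rep(c("P1", "P2"), 2),
                      genus = paste0("g", 1:4), origin = "bacteria")
  euk <- seq_records(id = paste0("e", 1:3),
                     sequence = rep(strrep("G", 30), 3), origin = "eukaryote")
  m <- coverage_matrix(data.frame(id = "cand", sequence = p),
                       rbind(prok, euk))
  expect_equal(unname(m["cand", c("P1", "P2")]), c(100, 100))
  expect_equal(unname(m["cand", "eukaryote"]), 0)
  # empty primer list -> empty matrix; record order does not matter
  expect_equal(dim(coverage_matrix(data.frame(id = character(0),
                                              sequence = character(0)),
                                   prok)), c(0, 0))
  set.seed(5)
  shuf <- rbind(prok, euk)[sample(7), ]
  m2 <- coverage_matrix(data.frame(id = "cand", sequence = p), shuf)
  expect_equal(m2[, colnames(m)], m[1, ])
})
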
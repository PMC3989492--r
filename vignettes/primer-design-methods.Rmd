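---
title: "Designing non-degenerate universal 16S primers: methods and design choices"
author: "primerforge"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Designing non-degenerate universal 16S primers: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(primerforge)
```

## The problem

Amplicon surveys of microbial communities rest on "universal" PCR primers
that anneal to regions of the 16S rRNA gene conserved across bacteria and
archaea. Many published universal primers, however, also match eukaryotic
nuclear (18S) and organelle (mitochondrial, chloroplastic) small-subunit
rRNA genes, which are homologous to 16S. In host-associated or
eukaryote-rich samples this diverts a large fraction of sequencing capacity
to non-target templates and biases the inferred community. `primerforge`
implements a discovery pipeline for *non-degenerate* (single concrete
sequence) universal primers that are conserved across prokaryotic phyla
while sitting at three or more mismatches from eukaryote and organelle
rRNAs — the working assumption, taken from PCR practice, being that three
or more primer–template mismatches prevent amplification. It also provides
the downstream machinery to profile communities from the resulting
amplicons (or from shotgun read pairs) and to compare profiles across
experiments.

## Window scan over a labelled alignment

The discovery substrate is a multiple sequence alignment of full-length
16S genes, one sequence per species, each labelled with its phylum, plus a
designated reference record (*E. coli*, the community-standard coordinate
system for 16S positions). A window of 15 columns (the minimum practical
primer length) slides across the alignment with a step of one column. For
each window:

* **Consensus within one mismatch.** Every *observed* slice is a
  consensus candidate; its frequency is the number of member slices within
  `max_mm` (default 1) mismatches. The gap `-` counts as a fifth symbol,
  so indel structure suppresses candidates; IUPAC ambiguity codes mismatch
  every symbol, themselves included — we deliberately do not invent
  expansion semantics for dirty database characters. The consensus is the
  most frequent slice; ties break lexicographically (`-` before `A`) for
  determinism. Restricting candidates to observed slices keeps the
  computation linear in the number of distinct slices rather than
  exponential in the width.

* **Per-phylum coverage rate.** The percentage of member slices within the
  allowance, computed per phylum, answers "would this consensus prime this
  phylum?". The conventional display bins (black < 50%, blue < 80%,
  green < 90%, yellow < 100%, red = 100%) are provided by `bin_coverage()`.

* **Variability.** Column-wise Shannon entropy over the five symbols
  (ambiguity codes excluded, counts renormalized), summed over the window,
  in bits. Descriptions of this statistic sometimes say "relative
  entropy"; against a uniform background over five symbols the two are
  complementary (KL = log2(5) − H per column), so both are available via
  `method = "kl_uniform"`. Shannon is the default because high values
  should mean *variable*, matching the plot semantics.

* **Reference coordinates.** Columns map to the ungapped *E. coli*
  position of the reference base at or before them; columns preceding the
  first reference base map to 0 and are flagged. Windows are labelled by
  the reference position of their first column.

`select_candidates()` keeps windows whose consensus is a synthesizable
oligo (gap- and ambiguity-free) and whose coverage reaches a threshold
(default 90%) in at least a fraction (default 0.9) of phyla. The "almost
all phyla" rule in the literature is qualitative; these two knobs are
explicit, configurable, and recorded in the output. A keep-interval on
reference positions (default 30–1200) drops terminal regions that are
missing from a large share of database records and 3′ regions beyond
amplicon read reach.

## Probe matching and the two coverage metrics

Candidate evaluation against large unaligned reference sets uses
probe-match semantics: the primer (forward) or its reverse complement
(reverse orientation) is compared, ungapped, against every same-length
substring of the sense strand; `min_mismatch()` is the minimum Hamming
distance over offsets. Indels are not modelled — mismatch counts are what
the underlying laboratory rule ("three or more mismatches kill the PCR")
is stated in. Reference records containing ambiguity codes are discarded
upstream (`discard_ambiguous()`), so distance semantics never meet
ambiguity here.

Two metrics serve different databases:

* `sequence_coverage()` — percentage of records with a site within the
  allowance. Used for the eukaryote/organelle sets (allowance 2), where
  taxonomy is sparse.
* `genus_coverage()` — percentage of genera in which a *strict majority*
  of member sequences match within the allowance (default 1). Used for
  the prokaryotic database, whose heavy redundancy would otherwise let a
  few over-sequenced species dominate; exactly half the members does not
  count as a majority.

`eukaryote_exclusion_filter()` drops candidates whose per-sequence
coverage within two mismatches exceeds 50% of mitochondrial or of
eukaryotic records; exactly 50% survives, because the rule is "more
than half". Chloroplast rRNAs are so close to 16S that excluding their
coverage is generally hopeless; they are reported but not used to
exclude.

## Merging, degenerate resolution, pairing

Neighbouring selected windows whose consensi agree on the overlap are
merged into longer candidates (`merge_neighbouring()`), one base per
window. "Maintaining the coverage" during merging is operationalized as a
floor: for every phylum, the merged candidate's coverage may not fall
below the minimum over its constituents minus a tolerance (default 0) —
the weakest reading that still forbids degradation. When a merge would
violate the floor, the run splits greedily left-to-right into the longest
acceptable prefixes.

Published degenerate primers can be compared on an equal footing by
`resolve_degenerate()`, which enumerates all concrete IUPAC expansions
(capped, default 1024) and picks the variant with the best mean per-phylum
genus-majority coverage, ties to the lexicographically smallest variant;
the full per-variant report is returned so any other objective can be
audited.

`pair_primers()` forms all forward × reverse combinations whose amplicon
span (reverse end − forward start + 1, in reference coordinates) lies in
`[min_span, max_span]` (default ceiling 550 nt, the high-quality read
length of long-read amplicon platforms; longer amplicons also assign more
accurately, so ranking prefers longer spans after coverage). Candidates
live in sense-strand orientation throughout; the synthesizable reverse
oligo is emitted as a derived reverse-complement field, which avoids
silent double-complementing.

## Read processing

`filter_amplicon_reads()` applies the long-read amplicon filters in a
fixed order (ambiguous base, length window, mean quality), counting each
removed read once under its first rule. The mean-quality rule is a strict
"less than" on the arithmetic mean of Phred scores, applied before
trimming; reads lacking qualities are unscorable and counted separately.
`trim_primers()` replaces an alignment-based trimmer with a
bounded-mismatch terminal search (defaults: 2 mismatches, primer start
within 30 nt of the read end), flipping antisense reads to the sense
strand first; reads without a forward-primer site are dropped. This is
functionally equivalent to score-threshold trimming for full-length
primer remnants and is fully configurable. Chimera screening is out of
scope; an upstream exclusion list can be applied before assignment.
`filter_short_read_pairs()` removes pairs failing purity filtering or
carrying more than one base at the flag quality (Phred 2, the
read-segment indicator of early short-read pipelines — configurable) in
the first 60 nt of either mate.

## Fractional best-hit assignment

Assignment consumes 12-column blast-tabular hit files; the similarity
search itself is external (it is an engine, not the contribution).
`filter_hits()` applies the e-value threshold strictly (`<`) and the
alignment-length threshold inclusively (`≥`), exactly as such thresholds
are printed. Two identity tiers are evaluated independently: genus at
≥ 94% identity, phylum at ≥ 85%; a read can be phylum-assigned yet
genus-unassigned, and a genus is never inherited from phylum-level hits.
Within a tier the best-bitscore hits share the read's unit mass equally
(`1/n_best` each; tied hits in one taxon accumulate), so every assigned
read contributes exactly 1. For read pairs, a pair contributes one unit
only when both mates are assigned to the same taxon, both to SSU rRNA
subjects, and the mates' best-hit strands are opposite (paired ends face
each other on one template; a same-strand mode exists for other
chemistries). A mate whose assignment is split by a tie disqualifies the
pair at that tier — the conservative reading of "identified as the same
taxon". Mate distance is ignored, since some taxa carry long insertions
in the gene.

Profiles (`build_profile()`) are additive by construction;
`compare_profiles()` computes Spearman's rank correlation over the union
of taxa (absentees as zero, average ranks for ties), which is symmetric
and scale-invariant; `rank_abundance()` uses competition ranking (ties
share the smaller rank, following ranks skipped).

## The synthetic community generator

`community_spec()`/`generate_alignment()` emulate every input so the
pipeline runs end-to-end offline: a random template of 1200 nt (long
enough to place a forward motif, a decoy, and a reverse motif with
realistic spans; full-length 16S realism is not needed to exercise any
operation), i.i.d. background with configurable GC, planted motifs, and
per-record divergence. Defaults describe the study conditions of the
package's own end-to-end test: 5 phyla × 4 genera × 2 members at 10%
background divergence, 10 eukaryote-like references at 30% divergence,
universal motifs conserved exactly in prokaryotes and broken by ≥ 3
forced substitutions in every eukaryote-like record, and a "broad-range"
decoy motif kept within 2 substitutions of eukaryote records (so it must
be caught by the exclusion filter, not by selection).

Two structural choices matter. First, each motif is flanked by gap-rich
insertion columns (the reference is gapped there, as are most prokaryote
rows) — the analogue of the indel-prone borders of conserved 16S stems.
Because a one-mismatch allowance would otherwise absorb a single variable
column, windows straddling a motif edge would score 100% coverage and
smear the candidate beyond the planted motif; the gap columns put a `-`
into those windows' consensus, and the gap-free rule rejects them, so
recovery of the planted oligo is exact. Second, a handful of background
columns carry deletions in a third of the rows, exercising gap handling
in consensus and entropy without touching the motifs.

What the generator does *not* emulate: secondary structure, chimeras,
homopolymer/flowgram error models, realistic phylogenetic correlation of
substitutions, or full-length gene scale. Passing tests therefore
demonstrate the correctness of the algorithms under controlled conditions,
not field performance of any particular primer on real communities.

`generate_reads()` builds amplicons as forward oligo + insert + reverse
complement of the reverse oligo with substitution errors, strand flips and
Phred+33 qualities, and can force exact fractions of reads to violate each
filter rule, so filter reports can be checked against planted truth.
`generate_hits()` encodes known read origins into blast-tabular hit files
with configurable tie groups, decoy hits and sub-tier identities, making
profile recovery exactly checkable.

## Numerical and degenerate-input conventions

* All coordinates are 1-based and inclusive, in ungapped reference
  (*E. coli*) numbering; columns before the first reference base map to 0
  and are flagged.
* Length boundary "longer than 2000 nt" keeps a 2000-nt record; the
  homopolymer cutoff (not stated with its source rule) defaults to
  "run > 14 nt removes" and is exposed as a parameter.
* All tie-breaks are deterministic: lexicographic (C-locale radix order)
  for consensus and degenerate resolution, coordinates and sequences as
  final sort keys in pairing.
* Empty inputs return empty outputs (with diagnostics) rather than
  errors, except where the result would be meaningless (consensus of no
  slices, correlation over fewer than three taxa).
* Every stochastic function takes an explicit seed; generators are pure
  functions of (spec, seed).

## Problem sizes used in the test-suite

The shipped tests run the whole pipeline on the default synthetic
community (41 aligned records × ~1200 columns, ~1200 windows), check the
consensus and probe-match implementations against brute-force oracles on
1000 random small instances, and verify mass conservation of fractional
assignment on 10 000 simulated reads — sizes chosen so the full suite
exercises every code path in about a minute on one core.
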
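# primerforge

Discovery and evaluation of **non-degenerate universal primers** for
prokaryotic 16S rRNA genes, with the downstream machinery for taxonomic
profiling of the resulting amplicons — for microbiologists designing
marker-gene surveys of communities where eukaryotic DNA (host tissue,
plant material, protists) competes with the prokaryotic signal.

Broad-range 16S primers often also match eukaryotic 18S and organelle
small-subunit rRNA genes; in eukaryote-rich samples this wastes sequencing
capacity and distorts the community profile. `primerforge` searches for
single concrete primer sequences (no IUPAC degeneracy) that are conserved
across bacterial and archaeal phyla but sit at ≥ 3 mismatches from
eukaryotic and mitochondrial rRNAs — the standard rule being that three or
more primer–template mismatches prevent PCR amplification.

## What it computes

**Discovery** (from a taxonomically labelled multiple sequence alignment
with an *E. coli* coordinate reference):

* sliding 15-nt window scan; per-window consensus *c* defined by
  mismatch-tolerant frequency, `freq(c) = #{slices s : d_H(s, c) ≤ 1}`
  over observed slices, gaps counting as a fifth symbol;
* per-phylum coverage rate `100 · #{members within 1 mismatch} / #members`
  and window variability as summed column-wise Shannon entropy (bits);
* selection of gap-free, high-coverage windows; merging of neighbouring
  windows under a per-phylum coverage floor; pairing under amplicon-span
  limits.

**Evaluation** (probe-match semantics, minimum Hamming distance over all
ungapped offsets, reverse primers via reverse complement):

* per-sequence coverage (eukaryote/organelle sets, 2-mismatch allowance)
  and genus-majority coverage (percentage of genera with a strict majority
  of members matching within 1 mismatch);
* exclusion of candidates covering > 50% of mitochondrial or eukaryotic
  rRNAs; resolution of published degenerate primers to their
  best-coverage concrete variant.

**Profiling**:

* platform-specific read filters, primer trimming with orientation
  normalization, short-read pair purity/flag filters;
* fractional best-hit taxonomic assignment from 12-column blast-tabular
  files (tie mass split `1/n_best`; genus tier ≥ 94% identity, phylum
  tier ≥ 85%, strict `<` on e-value, inclusive `≥` on alignment length);
* profile building, Spearman comparison, rank-abundance tables.

A synthetic-community generator emulates every input (labelled alignments
with planted conserved motifs, diverged eukaryote references, mock reads,
mock hit tables), so the whole pipeline runs offline.

## Worked example

Design primers on a synthetic community of 5 phyla × 4 genera (two
members each) with two planted universal motifs and one "broad-range"
decoy that also matches the 10 eukaryote references:

```r
library(primerforge)

spec <- community_spec(seed = 42)
gen  <- generate_alignment(spec)
res  <- design_universal_primers(gen$alignment, gen$taxonomy,
                                 gen$references,
                                 reference_id = gen$reference_id)

res$candidates[, c("sequence", "ref_start", "ref_end", "mean_coverage")]
#>            sequence ref_start ref_end mean_coverage
#> 1 CTACGGGAGGCTGCAGT       150     166           100
#> 2  GTGCCAGCAGCCGCGG       350     365           100
#> 3 GGATTAGATACCCTGGT       560     576           100

res$excluded[, c("sequence", "euk_coverage", "reason")]
#>           sequence euk_coverage              reason
#> 2 GTGCCAGCAGCCGCGG          100 eukaryotic coverage

res$pairs[, c("forward_seq", "reverse_oligo", "amplicon_span", "mean_coverage")]
#>         forward_seq     reverse_oligo amplicon_span mean_coverage
#> 1 CTACGGGAGGCTGCAGT ACCAGGGTATCTAATCC           427           100
```

Three conserved candidates are found at their planted coordinates with
100% genus-majority coverage in every phylum. The decoy at 350 covers
100% of the eukaryote references within two mismatches and is excluded;
the surviving forward/reverse candidates form one admissible pair (427-nt
amplicon), whose reverse entry is emitted both as the sense-strand region
(`reverse_seq`) and as the synthesizable reverse-complement oligo.

The classic published worked example is also a one-liner — merging the
neighbouring conserved windows at *E. coli* positions 342/343:

```r
merge_neighbouring(data.frame(
  ref_pos   = c(342L, 343L),
  consensus = c("CTACGGGGGGCAGCA", "TACGGGGGGCAGCAG")))
#>           sequence ref_start ref_end width n_windows provenance
#> 1 CTACGGGGGGCAGCAG       342     357    16         2   342, 343
```

which is the 16-nt forward primer 342F; the windows at 790–792 merge the
same way into the 17-nt 806R.

## Command line

A thin CLI over the same functions ships in `inst/cli/primerforge.R`:

```sh
Rscript inst/cli/primerforge.R synth --seed 42 --out synth/
Rscript inst/cli/primerforge.R scan --reference-id REF_16S \
        --out windows.tsv synth/alignment.fasta synth/taxonomy.tsv
Rscript inst/cli/primerforge.R coverage --primer CTACGGGAGGCTGCAGT \
        --max-mm 1 synth/references.fasta synth/references_tax.tsv
```

Subcommands: `curate`, `scan`, `coverage`, `qc-amplicon`, `assign`,
`synth`.

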
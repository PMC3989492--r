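Package: primerforge
Title: Design and Evaluation of Non-Degenerate Universal 16S rRNA Primers
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Discovers non-degenerate universal primer candidates for
    prokaryotic 16S rRNA genes by sliding-window consensus analysis of a
    taxonomically labelled multiple sequence alignment, evaluates candidates
    by mismatch-tolerant probe matching against bacterial, archaeal,
    eukaryotic and organelle rRNA reference sets, merges and pairs
    candidates under amplicon-length constraints, and provides the
    downstream machinery for amplicon and shotgun-read taxonomic profiling:
    platform-specific read filters, primer trimming, fractional best-hit
    assignment from tabular similarity searches, and profile comparison.
    A synthetic-community generator emulates every input so the whole
    pipeline can be exercised end-to-end without external databases.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    Biostrings,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
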
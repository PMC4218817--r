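Package: polyproscan
Title: Polyproline and Amino-Acid Tandem-Repeat Census of Proteomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects maximal homopolymer runs (polyproline stretches and
    tandem repeats of any amino acid) in whole-proteome protein FASTA files,
    converts run lengths to repeat units by the floor(n/3) triplet rule,
    counts non-overlapping Pro-Pro-Gly (PPG) ribosome-stalling motifs, and
    aggregates per-protein profiles into proteome-level repeat statistics:
    run-length distribution tables, unit totals calibrated per 10,000 amino
    acids, unit-threshold gene groups, protein-length distributions, and
    20-amino-acid composition and triplet-unit tables. Parses
    InParanoid-style pairwise ortholog tables, applies the inparalog-score
    1.0 seed filter, and intersects pairwise comparisons into nested
    ortholog pools with per-pool repeat statistics. Ships a synthetic
    proteome generator with planted repeat runs and synthetic multi-species
    ortholog tables carrying exact ground truth, so every pipeline stage is
    testable without downloading any proteome database.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse,
    jsonlite
Config/testthat/edition: 3
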
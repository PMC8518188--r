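Package: hcbha
Title: Iterative Haplotype-Resolved Hybrid Assembly of Complex Metagenomes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Reconstructs (near-)complete genomes from complex metagenomes by
    phasing error-prone long reads and accurate short reads into candidate
    bacterial haplotype bins, hybrid-assembling and polishing each bin
    independently, subtracting the reads of qualified genomes, and iterating
    until the per-iteration qualified abundance falls below a stop threshold.
    Includes a desk-scale built-in long-read overlap assembler and short-read
    pileup polisher, tetranucleotide-frequency hierarchical binning, a
    minimizer-based read phaser, MIMAG-style quality gating and ANI-based
    dereplication, a reference-based evaluation suite (aligned genome
    fraction, purity, misassembly and indel rates, assembly Q-scores), and a
    fully deterministic community and hybrid read-set simulator providing
    ground truth for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    Biostrings,
    mclust,
    withr,
    yaml,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
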
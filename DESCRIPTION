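Package: endosift
Title: Endosymbiont Genome Recovery from Mixed Host-Tissue Sequencing Libraries
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Recovers the genome of an obligate intracellular endosymbiont from a
    paired-end shotgun library dominated by host DNA, without isolating symbiont
    cells. Implements translated-homology contig selection against a related
    reference genome with mitochondrial and host-rRNA decoy filtering (TCSF), and
    iterative read recruitment with from-scratch reassembly to saturation (IMRA),
    on top of a greedy overlap-layout-consensus assembler and a seed-and-extend
    local aligner with Karlin-Altschul E-values. Ships a truth-labelled synthetic
    mixed-library generator, quality filtering, and assembly evaluation metrics
    (length-weighted TP/FN/FP, genome fraction, NGA50, library purity).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    Biostrings,
    S4Vectors
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    yaml
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
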
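Package: gminscan
Title: Genome Scans for Recent Introgression with the G_min Statistic
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Detects recent introgression after secondary contact using
    G_min, the ratio of the minimum to the mean between-population
    haplotype distance in a genomic window, together with Hudson's
    F_ST. Includes a two-population structured-coalescent simulator
    with recombination and an instantaneous (pulse) migration event
    that records which windows contain migrant genealogies, a Z-score
    outlier classifier with sensitivity/specificity evaluation over
    parameter grids, variance partitioning of the simulated statistics,
    and a sliding-window scanner for phased haplotype alignments
    (multi-FASTA or phased VCF) that emits per-window statistics and
    neighbor-joining trees.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    jsonlite,
    tools,
    yaml,
    ape,
    Biostrings,
    vcfR
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
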
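Package: segfam
Title: Simulation and Analysis of High-Identity Segmental-Duplication Gene Families
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for characterizing high-identity multicopy gene families
    across phased haplotype assemblies: discovery of gene-family copies by
    anchor chaining, read-depth copy-number estimation, distance-based paralog
    assignment with bootstrap support, strict-clock node dating, locus
    structural-configuration encoding with DCJ-indel rearrangement distances
    and inversion calling, interlocus gene-conversion tract detection from
    paralogous sequence variants, haplotype-based selection scans (Tajima's D
    and nS_L), long-read isoform and coding-VNTR analysis, and unique k-mer
    paralog-group expression quantification. Includes a coalescent-based
    synthetic-data generator emitting machine-readable ground truth so every
    stage can be validated end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    ape,
    phangorn,
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    jsonlite,
    yaml,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
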
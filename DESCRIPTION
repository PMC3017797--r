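Package: haplorga
Title: Comparative Analysis of Resistance-Gene-Analog Cluster Haplotypes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for comparing the two haplotypes of a disease-resistance
    gene analog (RGA) cluster in a heterozygous plant genome. Detects
    colinear blocks and catalogues SNPs and indels between haplotypes,
    dates haplotype divergence from synonymous substitutions
    (Nei-Gojobori counting, T = pS/2r) and LTR retroelement insertions
    from LTR divergence (Kimura 2-parameter, T = K/2r), annotates LTR
    retrotransposon structure (paired LTRs, TG..CA termini, target-site
    duplications) and microsatellites, classifies NB-LRR gene models by
    completeness, assigns allelic pairs and clades from pairwise identity,
    and locates unequal-recombination breakpoints by sliding-window
    identity shifts. Includes a haplotype-pair simulator with a full
    ground-truth table for validating every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Biostrings,
    GenomicRanges,
    rtracklayer,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    ape,
    optparse,
    jsonlite,
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
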
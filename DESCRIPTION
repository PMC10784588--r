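Package: epscan
Title: Extreme-Phenotype Marker Association with Permutation FDR for Inbred Line Panels
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Statistical pipeline for extreme-phenotype genome-wide association
    in panels of homozygous inbred lines, such as lifespan screens across fly
    reference panels under dietary restriction. Lines are dichotomized into an
    extreme in-case group and a non-case group, each biallelic marker is tested
    with a two-sided Fisher's exact test, and the scan's false-discovery rate is
    estimated empirically by phenotype permutation. Companion tools cover
    survival-curve estimation and log-rank comparison of lifespan cohorts,
    paired-test differential abundance with Storey q-values, a Spearman
    co-abundance screen, and hypergeometric gene-set overlap testing. A
    synthetic-study generator with known ground truth (homozygous genotypes,
    Gompertz lifespans with a diet-specific allele effect, paired omics
    matrices, gene lists) makes every stage testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    survival,
    vcfR,
    rtracklayer,
    GenomicRanges,
    S4Vectors
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
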
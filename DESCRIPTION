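Package: pigpopgen
Title: Population Genomics of Divergent Pig Populations: Diversity, LD
    Blocks, X-Chromosome Haplotypes and Introgression
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Downstream population-genomic analyses for multi-sample
    variant data from divergent domestic and wild pig populations:
    windowed nucleotide diversity (theta-pi, Watterson's theta) and
    Hudson F_ST; pairwise linkage disequilibrium with D-prime confidence
    intervals, genome-wide LD decay and Gabriel confidence-interval
    haplotype-block detection; EM haplotype phasing; reference-relative
    X-chromosome haplotype classification with recombination-interval
    localization; a windowed haplotype-sharing introgression scan with a
    window likelihood-ratio test; population-structure inference
    (p-distance neighbor-joining tree, PCA, EM admixture); and
    differential-variant scans (near-fixation filter, chi-square tests
    with FDR or Bonferroni correction) for trait candidates. Includes a
    seeded synthetic-data generator with planted ground truth
    (introgression tracts, haplotype mosaics, differentiated variants)
    and a toy genome annotation for coding-effect classification.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    jsonlite,
    methods,
    rtracklayer,
    stats,
    utils,
    vcfR,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
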
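Package: pedcross
Title: Crossover Mapping and Sex-Specific Recombination Analysis in
    Three-Generation Pedigrees
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Maps meiotic crossovers at high positional precision from
    genome-wide SNP genotypes segregating in a three-generation pedigree
    (four grandparents, two parents, six offspring). Alleles transmitted to
    each offspring are phased to their grandparent of origin, crossovers are
    localized with a run-length (cumulative continuity score) change-point
    rule with flanking-marker precision intervals, and the calls are
    aggregated into sex-specific chromosome-arm recombination maps (cM and
    cM/Mb) with Z-chromosome pseudoautosomal accounting. Includes
    sex-difference tests (paired t, Mann-Whitney U on telomere distances),
    crossover-versus-gene-feature statistics (length-weighted chi-square
    goodness-of-fit, nearest-gene distances, an interval-constrained
    permutation test), and a pedigree meiosis simulator with telomere-biased
    crossover placement that provides ground truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    methods,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
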
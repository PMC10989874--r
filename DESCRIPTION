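Package: regenmap
Title: GWAS of Zero-Inflated Plant Regeneration Traits from Segmentation Masks
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: An association-mapping pipeline for zero-inflated,
    image-derived plant regeneration traits. Converts semantic
    segmentation masks into per-timepoint callus- and shoot-area
    proportions, prepares traits (replicate merging, Box-Cox and
    rank-based inverse-normal transformations, elbow thresholding,
    trait PCA), computes kinship and structure covariates, and tests
    associations with a REML linear mixed model, a penalized
    quasi-likelihood logistic mixed model (score and Wald tests), and
    weighted-kernel SKAT over staggered windows with adaptive
    Monte-Carlo empirical p-values. Single-SNP p-values are combined
    over 1 kb windows by augmented rank truncation, and significant
    loci are deduplicated into peaks and assigned to nearby genes from
    GFF3 annotation. A synthetic-data module simulates structured
    populations (Balding-Nichols), polygenic liabilities with planted
    causal SNPs, and segmentation masks with known class proportions
    so the whole pipeline is testable end to end.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    png,
    jsonlite,
    vcfR,
    rtracklayer,
    parallel
Suggests:
    testthat (>= 3.0.0),
    withr,
    MASS,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
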
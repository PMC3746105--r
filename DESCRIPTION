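Package: blueiris
Title: Quantitative Iris Colorimetry, Cluster Tests, and Pedigree-Aware
    Association for Convergent Blue-Iris Phenotypes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools to quantify iris pigmentation from photographs as median
    CIE a* and b* chromaticity after excluding specular highlights and shadow
    pixels; to test whether a univariate phenotype distribution is better
    described by two Gaussian clusters than one, using a likelihood-ratio
    statistic calibrated by a parametric bootstrap; to compute pedigree
    kinship coefficients and the numerator relationship matrix; and to run
    per-variant linear mixed-model Wald association tests with a kinship
    random effect, including rank-based inverse-normal phenotype
    transformation and covariate screening. Aligned haplotype sequences can
    be reduced to anchored, polarized variant tables with founder allele
    frequencies. A synthetic-data module generates iris images, pedigrees,
    Mendelian genotypes, kinship-structured phenotypes, and haplotype
    alignments with known ground truth so the whole pipeline can be
    exercised end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    png,
    Biostrings,
    stats,
    utils,
    grDevices
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    tiff,
    mclust,
    jsonlite,
    ggplot2
Config/testthat/edition: 3
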
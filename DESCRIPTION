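Package: grainvar
Title: Genetic Analysis of Within-Plot Grain Size Variance in Wheat
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.org", role = c("aut", "cre"))
Description: Tools to analyse the within-plot variance of individual wheat
    grain size (GSV) as a quantitative trait in its own right: descriptors of
    per-plot grain-size distributions (mean, variance, 5th/95th percentiles),
    spatial adjustment and broad-sense heritability under unreplicated
    augmented field designs, a kinship-corrected single-marker mixed-model
    genome scan with leave-one-chromosome-out relationship matrices,
    LD-block-based QTL interval definition with critical-LD thresholds and
    Hill-Weir decay extension, classification of GSV loci into canopy-driven
    versus variance-specific, and variance partitioning with forward-AIC
    selection.  A seeded simulator of genotype panels, augmented field trials
    and individual grain populations lets the whole chain run and be tested
    without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    data.table,
    jsonlite,
    stats,
    utils
Suggests:
    GenomicRanges,
    lme4,
    SummarizedExperiment,
    testthat (>= 3.0.0),
    VariantAnnotation,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
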
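Package: dispersalkit
Title: Sex-Biased Dispersal Inference from Microsatellite Assignment Indices
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to detect and explain sex-biased dispersal in fragmented
    amphibian populations from codominant microsatellite genotypes. Reads and
    writes GenePop files with a sex-annotated metadata sidecar; computes
    per-population diversity (allelic richness, observed and unbiased expected
    heterozygosity), exact Hardy-Weinberg tests (Levene conditional
    distribution with Monte Carlo fallback), genotypic linkage-disequilibrium
    permutation tests, and two-level AMOVA with permutation significance;
    derives corrected assignment indices (AIc) per individual and tests
    per-island and pooled sex differences with Mann-Whitney U tests and
    Benjamini-Hochberg correction; and links the dispersal disparity statistic
    (dAIc) to island attributes via VIF-screened multiple regression, backward
    stepwise selection under AICc, and two-predictor variance partitioning.
    A forward-time island-model simulator with sex-specific migration and
    microsatellite mutation provides ground-truthed synthetic data sets.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    car,
    jsonlite,
    withr
Config/testthat/edition: 3
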
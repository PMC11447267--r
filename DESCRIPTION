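Package: artewas
Title: Sex-Stratified Epigenome-Wide Association Analysis for ART-Conceived Newborns
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A reusable pipeline for sex-stratified epigenome-wide association
    studies (EWAS) of DNA methylation in newborns conceived by assisted
    reproductive technologies (ART) versus natural conception. Implements
    per-CpG observation-level outlier masking using an unscaled median
    absolute deviation rule, per-CpG linear mixed models with a plate random
    intercept and maternal covariates, Benjamini-Hochberg false discovery
    rate control, ART-by-sex interaction testing including a gene-level
    long-format block-wise permutation test, Kolmogorov-Smirnov comparison of
    methylation difference distributions between sexes, sign-count chi-square
    tests, and candidate CpG set enrichment. Ships a synthetic cohort and
    beta-value generator with known ground truth so every stage is testable
    without access-restricted cohort data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    nlme,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
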
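Package: birdacuity
Title: Phylogenetically Controlled Analysis of Avian Visual Acuity
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Comparative analysis of visual acuity allometry and ecology in
    birds under phylogenetic control. Implements phylogenetic generalized
    least squares (PGLS) under a Brownian-motion covariance with optional
    Pagel's lambda scaling, maximum-likelihood estimation of lambda with a
    likelihood-ratio test, a residual cascade defining relative eye size and
    residual acuity, all-subsets AIC model selection with Akaike weights and
    a collinearity screen, phylogenetic ANOVA with a Brownian simulation null
    and Holm-Bonferroni post hoc contrasts, rule-based ecological classifiers
    (habitat complexity, light level, diet, prey mobility, foraging mode),
    acuity unit conversion and record selection, a synthetic-data generator
    for parameter-recovery studies, and an end-to-end analysis pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    ape,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    nlme,
    optparse,
    phytools,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
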
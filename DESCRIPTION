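Package: coxtransfer
Title: Adaptive Transfer Learning for Deep Cox Survival Networks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Cross-cohort survival modelling with a deep Cox proportional
    hazards network. Cohorts of expression and survival data are summarized by
    12 phenotype and 10 genotype descriptors (the genotype block from a two
    component kernel PCA of the expression matrix), clustered by silhouette
    guided k-means to select source cohorts similar to a target, and a three
    hidden layer Cox network trained by the negative log partial likelihood is
    pre-trained on the selected sources and fine-tuned on the target. Includes
    Harrell's concordance index, median risk stratification with log-rank and
    chi-square association tests, and a multi-cohort synthetic survival data
    generator with planted family structure for end-to-end testing.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    survival,
    cluster,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
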
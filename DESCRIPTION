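Package: traitbiogeo
Title: Trait-Level Biogeography of Planktonic Protists from Metabarcoding and Ensemble Species Distribution Models
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Links trophic strategies of marine planktonic protists
    (mixotrophy, strict phototrophy, strict phagotrophy) to their global
    biogeography. Provides community ubiquity metrics (occupancy, total read
    abundance, Pielou evenness) from metabarcoding read tables, Hellinger
    normalisation, environmental-space PCA with supplementary variables and
    hierarchical classification on component scores, redundancy analysis with
    Escoufier equivalent-vectors species selection and AIC-based predictor
    selection, per-species ensemble distribution models (GLM, GAM, hinge-basis
    regression splines, single-hidden-layer neural networks) with repeated
    stratified cross-validation and Jaccard-index member retention, monthly
    habitat-suitability projection, and trait-level stacking with latitudinal,
    biome and intra-group variability statistics. A synthetic-data generator
    with trait-conditioned Gaussian niches and multinomial read sampling makes
    the whole pipeline testable against known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    mgcv,
    nnet,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    withr
Suggests:
    jsonlite,
    knitr,
    readr,
    rmarkdown,
    testthat (>= 3.0.0),
    vegan
VignetteBuilder: knitr
Config/testthat/edition: 3
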
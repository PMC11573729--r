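Package: camtrapMSOM
Title: Multi-Species Occupancy Models and Species Richness from Camera-Trap Surveys
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds species detection histories from camera-trap image records
    (independence filtering, taxon grouping, occasion binning), derives per-site
    habitat covariates (terrain ruggedness index, buffered raster means, human
    disturbance counts), and fits a Bayesian hierarchical multi-species occupancy
    model with data augmentation for never-detected species using a purpose-built
    Metropolis-within-Gibbs sampler. Posterior summaries include community and
    site-level species richness, covariate effects on richness, species
    accumulation curves, and circular activity-overlap coefficients.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tools,
    S4Vectors,
    SummarizedExperiment,
    yaml,
    jsonlite
Suggests: testthat (>= 3.0.0), knitr, rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
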
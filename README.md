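# camtrapMSOM

Bayesian multi-species occupancy modeling for camera-trap surveys: from raw
image records to posterior species richness, covariate effects, and diel
activity overlap.

Camera-trap surveys detect elusive species imperfectly — a species absent
from every photo may still be present, and a community's true richness
exceeds the observed species list. **camtrapMSOM** addresses this with the
Dorazio–Royle data-augmented multi-species occupancy model (MSOM): the
observed detection histories are embedded in a supercommunity padded with
never-detected pseudo-species, and a hierarchical Bayesian model estimates,
jointly for all species, occupancy probabilities (optionally
covariate-driven on the logit scale), detection probabilities, and the
posterior distribution of true community and site-level richness. The
sampler is a purpose-built Metropolis-within-Gibbs implementation whose
exact full conditionals (for the latent presence and community-membership
indicators) are verified against brute-force enumeration in the test suite.

The package covers the full workflow:

* **Ingest** — read image records and deployment tables, group taxa, apply
  a 1-hour (configurable) greedy independence filter, and bin detections
  into sampling occasions (`readCameraRecords()`, `filterIndependent()`,
  `buildDetectionHistory()`). Detection histories are S4 objects extending
  `SummarizedExperiment`.
* **Covariates** — terrain ruggedness index from elevation rasters
  (plain-text ESRI ASCII grids), circular buffer means, human-disturbance
  counts, and a standardized design matrix with a quadratic elevation term
  (`terrainRuggedness()`, `bufferMean()`, `buildDesignMatrix()`).
* **Model** — the data-augmented MSOM sampler (`fitMsom()`,
  `msomControl()`), with adaptive burn-in, multi-chain Gelman–Rubin
  diagnostics, and bit-reproducible seeding.
* **Post-processing** — community and site richness summaries
  (`deriveRichness()`, `siteRichness()`), OLS regression of site richness
  on covariates (`richnessRegression()`), species accumulation curves
  (`accumulationCurve()`), and the circular activity-overlap coefficient
  Δ̂₁ with von Mises kernels (`activityOverlap()`).
* **Simulation** — a calibrated synthetic survey generator
  (`simulateCommunity()`, `simulateCameraRecords()`) whose records
  round-trip *exactly* through the ingest pipeline, enabling honest
  recovery experiments.
* **Orchestration** — config validation and a one-call pipeline with a
  hashed output manifest (`validateConfig()`, `runPipeline()`).

See the methods vignette (`vignettes/msom-methods.Rmd`) for the model,
sampler details, and numerical conventions.

## Worked example

Simulate a 45-site survey from a 26-species community at a sparse-detection
operating regime (mean occupancy ≈ 0.28, per-occasion detection ≈ 0.02),
expand it to timestamped image records, and run the full pipeline:

```r
library(camtrapMSOM)
sim <- simulateCommunity(I = 45, nTrue = 26, seed = 42)
rec <- simulateCameraRecords(sim, seed = 43)
head(rec$records, 4)
#>   site  kind species           timestamp
#> 1  S05 blank    <NA> 2017-01-01 03:22:53
#> 2  S05 blank    <NA> 2017-01-01 03:27:15
#> 3  S05 blank    <NA> 2017-01-01 03:31:36
#> 4  S25 human    <NA> 2017-01-01 13:16:39

indep <- filterIndependent(rec$records, windowMinutes = 60)
dh <- buildDetectionHistory(indep, rec$deployments)
dh
#> DetectionHistory: 24 species x 45 sites
#>   effort: 74-107 occasions of 1 day(s) per site, total 4063
#>   detections: 536 occasion-level events, naive richness 24
```

Two of the 26 species were never photographed. Fit the MSOM (a short
exploratory run; production defaults in `msomControl()` are longer):

```r
fit <- fitMsom(dh, control = msomControl(nChains = 2, nIter = 8000,
                                         burnIn = 2000, thin = 6), seed = 7)
deriveRichness(fit)
#>   parameter   mean        sd q2.5 median q97.5
#> 1         N 24.397 0.7659532   24     24    26

subset(msomSummary(fit), parameter %in% c("N", "meanPsi", "meanP", "omega"))
#>   parameter        mean          sd        q2.5      median       q97.5      rhat
#> 1     omega  0.50844082 0.071673633  0.36955801  0.50858025  0.65322486 0.9997213
#> 6         N 24.39700000 0.765953225 24.00000000 24.00000000 26.00000000 0.9995016
#> 7   meanPsi  0.32130499 0.026052093  0.27606946  0.32040029  0.37562283 0.9997446
#> 8     meanP  0.01622835 0.001133294  0.01415643  0.01620871  0.01850648 0.9997175
```

The 95% credible interval for richness covers the true community size of
26, and the community occupancy and detection means recover the generating
regime. Diel activity overlap between humans and wildlife (the generator
gives humans a midday peak and wildlife crepuscular/nocturnal peaks):

```r
wl <- indep[indep$kind == "wildlife", ]
hu <- indep[indep$kind == "human", ]
hrs <- function(t) { lt <- as.POSIXlt(t, tz = "UTC"); lt$hour + lt$min / 60 }
activityOverlap(hrs(hu$timestamp), hrs(wl$timestamp))
#> [1] 0.1826166
```

For real data, replace the simulation step with `readCameraRecords()` /
`readDeployments()`, derive covariates with `siteCovariates()` and
`buildDesignMatrix()`, and pass the design matrix to
`fitMsom(dh, design = X, ...)`. `runPipeline()` executes the same sequence
from a YAML config and writes CSV outputs plus a hashed manifest.

## Testing

The test suite (testthat, edition 3) includes exhaustive-enumeration checks
of the sampler's full conditionals, distributional checks of every
Metropolis and Gibbs update against grid-integration oracles, closed-form
and property-based tests of each pipeline stage, exact round-trip tests of
the record generator, and a 50-replicate richness-recovery experiment at
the reference operating regime:

```sh
Rscript -e 'testthat::test_dir("tests/testthat", package = "camtrapMSOM", load_package = "installed")'
```

## License

MIT (see `LICENSE`).
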
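#' Write / read a detection history as plain CSV
#'
#' The wide layout (rows = species, columns = sites) plus a per-site effort
#' table; the pair round-trips losslessly through
#' \code{readDetectionHistoryCsv()}.
#'
#' @param history a \linkS4class{DetectionHistory}.
#' @param historyPath,effortPath output / input CSV paths.
#' @return \code{writeDetectionHistoryCsv}: the paths, invisibly;
#'   \code{readDetectionHistoryCsv}: a \linkS4class{DetectionHistory}.
#' @export
writeDetectionHistoryCsv <- function(history, historyPath, effortPath) {
  y <- detections(history)
  write.csv(data.frame(species = rownames(y), y, check.names = FALSE),
            historyPath, row.names = FALSE)
  write.csv(data.frame(site = colnames(y), effort = unname(effort(history)),
                       occasionDays = history@occasionDays),
            effortPath, row.names = FALSE)
  invisible(c(historyPath, effortPath))
}

#' @rdname writeDetectionHistoryCsv
#' @export
readDetectionHistoryCsv <- function(historyPath, effortPath) {
  h <- read.csv(historyPath, check.names = FALSE, stringsAsFactors = FALSE)
  e <- read.csv(effortPath, stringsAsFactors = FALSE)
  y <- as.matrix(h[, -1, drop = FALSE])
  storage.mode(y) <- "integer"
  rownames(y) <- h$species
  y <- y[, e$site, drop = FALSE]
  newDetectionHistory(y, setNames(as.integer(e$effort), e$site),
                      occasionDays = e$occasionDays[1])
}

pipelineDefaults <- list(
  records = NULL, deployments = NULL, covariates = NULL, out = NULL,
  taxonMap = NULL, windowMinutes = 60, occasionDays = 1, radius = 100,
  covariateColumns = c("elev", "elev2", "tri", "canopy", "disturbance"),
  nChains = 3, nIter = 100000, burnIn = 5000, thin = 60, nAug = NULL,
  seed = 1)

#' Validate a pipeline run configuration
#'
#' Reads a YAML configuration (or takes a list), fills defaults (independence
#' window 60 min, daily occasions, 100 m buffer radius, 3 chains of 100,000
#' iterations, 5,000 burn-in, thinning 60, augmentation equal to the observed
#' species count), rejects unknown keys and contradictory settings, and
#' checks that referenced input paths exist.
#'
#' @param config path to a YAML file, or a named list.
#' @return The completed configuration list.
#' @export
validateConfig <- function(config = list()) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  stopifnot(is.list(config))
  unknown <- setdiff(names(config), names(pipelineDefaults))
  if (length(unknown))
    stop("unknown configuration key(s): ", paste(unknown, collapse = ", "))
  cfg <- utils::modifyList(pipelineDefaults, config)
  ## contradiction / range checks (msomControl re-validates MCMC settings)
  msomControl(cfg$nChains, cfg$nIter, cfg$burnIn, cfg$thin, cfg$nAug)
  if (cfg$windowMinutes < 0) stop("windowMinutes must be non-negative")
  if (cfg$occasionDays < 1) stop("occasionDays must be >= 1")
  if (cfg$radius <= 0) stop("radius must be positive")
  bad <- setdiff(cfg$covariateColumns, designColumns)
  if (length(bad))
    stop("unknown covariate column(s): ", paste(bad, collapse = ", "))
  for (key in c("records", "deployments", "covariates")) {
    p <- cfg[[key]]
    if (!is.null(p) && !file.exists(p))
      stop("configured ", key, " path does not exist: ", p)
  }
  if (!is.null(cfg$taxonMap)) cfg$taxonMap <- unlist(cfg$taxonMap)
  cfg
}

#' Run the full camera-trap occupancy pipeline
#'
#' Executes ingest (read, taxon grouping, independence filter, detection
#' histories), covariate assembly, the occupancy-model fit and the posterior
#' summaries, writing all artifacts plus a reproducibility manifest (input
#' MD5 hashes, seed, package version, outputs) to the configured output
#' directory. Re-running with identical inputs and seed reproduces every
#' output byte for byte.
#'
#' @param config a YAML path or configuration list (see
#'   \code{\link{validateConfig}}); must name \code{records},
#'   \code{deployments}, \code{covariates} (site-covariate CSV) and
#'   \code{out}.
#' @return The manifest list, invisibly.
#' @export
runPipeline <- function(config) {
  cfg <- validateConfig(config)
  for (key in c("records", "deployments", "covariates", "out"))
    if (is.null(cfg[[key]])) stop("configuration must set '", key, "'")
  dir.create(cfg$out, showWarnings = FALSE, recursive = TRUE)

  records <- readCameraRecords(cfg$records)
  deployments <- readDeployments(cfg$deployments)
  if (!is.null(cfg$taxonMap)) records <- aggregateTaxa(records, cfg$taxonMap)
  indep <- filterIndependent(records, cfg$windowMinutes)
  history <- buildDetectionHistory(indep, deployments, cfg$occasionDays)

  covTab <- read.csv(cfg$covariates, stringsAsFactors = FALSE)
  X <- buildDesignMatrix(covTab)
  X <- X[match(colnames(history), rownames(X)),
         cfg$covariateColumns, drop = FALSE]
  if (anyNA(X)) stop("covariate table is missing site(s) present in records")

  control <- msomControl(cfg$nChains, cfg$nIter, cfg$burnIn, cfg$thin, cfg$nAug)
  fit <- fitMsom(history, X, control, seed = cfg$seed)

  paths <- file.path(cfg$out, c(
    history = "detection_history.csv", effort = "effort.csv",
    summary = "model_summary.csv", species = "species_summary.csv",
    regression = "richness_regression.csv", accumulation = "accumulation.csv",
    siteRichness = "site_richness.csv"))
  names(paths) <- c("history", "effort", "summary", "species", "regression",
                    "accumulation", "siteRichness")
  writeDetectionHistoryCsv(history, paths["history"], paths["effort"])
  write.csv(msomSummary(fit), paths["summary"], row.names = FALSE)
  write.csv(speciesSummary(fit, X), paths["species"], row.names = FALSE)
  sr <- siteRichness(fit)
  write.csv(sr$summary, paths["siteRichness"], row.names = FALSE)
  reg <- richnessRegression(sr$mean, X)
  write.csv(reg, paths["regression"], row.names = FALSE)
  write.csv(accumulationCurve(records), paths["accumulation"],
            row.names = FALSE)

  manifest <- list(
    seed = cfg$seed,
    packageVersion = as.character(utils::packageVersion("camtrapMSOM")),
    inputs = as.list(tools::md5sum(c(cfg$records, cfg$deployments,
                                     cfg$covariates))),
    settings = cfg[c("windowMinutes", "occasionDays", "radius",
                     "covariateColumns", "nChains", "nIter", "burnIn",
                     "thin")],
    outputs = as.list(tools::md5sum(unname(paths))))
  jsonlite::write_json(manifest, file.path(cfg$out, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(manifest)
}
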
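#' @import methods
#' @importFrom stats rnorm runif rbinom rbeta rnbinom rpois dbinom dnorm plogis
#'   qlogis quantile sd var lm qt setNames median complete.cases
#' @importFrom utils read.csv write.csv modifyList packageVersion
#' @importFrom tools md5sum
#' @importFrom yaml read_yaml
#' @importFrom jsonlite write_json
NULL

#' Species detection histories from a camera-trap survey
#'
#' A \code{DetectionHistory} holds, for each observed species (rows) and camera
#' site (columns), the number of survey occasions with at least one independent
#' detection, together with the per-site number of active occasions (effort).
#' It extends \linkS4class{SummarizedExperiment}: the count matrix lives in the
#' \code{"detections"} assay and effort in \code{colData()$effort}, so the
#' usual subsetting, \code{rownames()} (species) and \code{colnames()} (sites)
#' work as expected.
#'
#' @slot occasionDays length of one survey occasion in days.
#'
#' @seealso \code{\link{buildDetectionHistory}}, \code{\link{detections}},
#'   \code{\link{effort}}
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#' @exportClass DetectionHistory
setClass("DetectionHistory",
  contains = "SummarizedExperiment",
  representation(occasionDays = "numeric"))

setValidity("DetectionHistory", function(object) {
  msg <- character()
  if (!"detections" %in% SummarizedExperiment::assayNames(object))
    msg <- c(msg, "assay 'detections' is required")
  if (!"effort" %in% colnames(SummarizedExperiment::colData(object)))
    msg <- c(msg, "colData column 'effort' is required")
  if (length(msg)) return(msg)
  y <- SummarizedExperiment::assay(object, "detections")
  n <- object$effort
  if (any(n < 1)) msg <- c(msg, "all sites must have effort >= 1 occasion")
  if (any(y < 0)) msg <- c(msg, "detection counts must be non-negative")
  if (any(sweep(y, 2, n) > 0)) msg <- c(msg, "y_ik must not exceed n_i")
  if (nrow(y) > 0 && any(rowSums(y) < 1))
    msg <- c(msg, "every species row must have at least one detection")
  if (length(object@occasionDays) != 1 || object@occasionDays < 1)
    msg <- c(msg, "occasionDays must be a single value >= 1")
  if (length(msg)) msg else TRUE
})

#' In-memory single-band raster on a regular grid
#'
#' Minimal planar raster: a numeric matrix with an origin and square cell size,
#' using \code{NA} as the missing-data sentinel. Row 1 is the northernmost row
#' (map orientation); the center of cell \code{[r, c]} is at
#' \code{x = xmin + (c - 0.5) * cellSize},
#' \code{y = ymin + (nrow - r + 0.5) * cellSize}. Coordinates are planar with
#' metre units; geographic rasters must be projected before use.
#'
#' @slot values numeric matrix of cell values (NA = missing).
#' @slot xmin,ymin coordinates of the lower-left corner of the grid.
#' @slot cellSize cell edge length (metres).
#'
#' @seealso \code{\link{rasterGrid}}, \code{\link{terrainRuggedness}},
#'   \code{\link{bufferMean}}, \code{\link{readAsciiGrid}}
#' @exportClass RasterGrid
setClass("RasterGrid",
  representation(values = "matrix", xmin = "numeric", ymin = "numeric",
                 cellSize = "numeric"))

setValidity("RasterGrid", function(object) {
  msg <- character()
  if (!is.numeric(object@values) || length(object@values) == 0)
    msg <- c(msg, "values must be a non-empty numeric matrix")
  if (length(object@cellSize) != 1 || object@cellSize <= 0)
    msg <- c(msg, "cellSize must be a single positive number")
  if (length(object@xmin) != 1 || length(object@ymin) != 1)
    msg <- c(msg, "xmin and ymin must be single numbers")
  if (length(msg)) msg else TRUE
})

#' Construct a RasterGrid
#'
#' @param values numeric matrix, row 1 = northernmost row.
#' @param xmin,ymin lower-left corner coordinates.
#' @param cellSize cell edge length in the same (planar, metre) units.
#' @return A \linkS4class{RasterGrid}.
#' @examples
#' g <- rasterGrid(matrix(1:12, 3, 4), xmin = 0, ymin = 0, cellSize = 30)
#' @export
rasterGrid <- function(values, xmin = 0, ymin = 0, cellSize = 1) {
  new("RasterGrid", values = as.matrix(values), xmin = xmin, ymin = ymin,
      cellSize = cellSize)
}

setMethod("show", "RasterGrid", function(object) {
  v <- object@values
  cat(sprintf("RasterGrid: %d x %d cells, cell size %g\n", nrow(v), ncol(v),
              object@cellSize))
  cat(sprintf("  extent: x [%g, %g], y [%g, %g]\n",
              object@xmin, object@xmin + ncol(v) * object@cellSize,
              object@ymin, object@ymin + nrow(v) * object@cellSize))
  cat(sprintf("  values: range [%g, %g], %d missing\n",
              suppressWarnings(min(v, na.rm = TRUE)),
              suppressWarnings(max(v, na.rm = TRUE)), sum(is.na(v))))
})

#' Posterior samples from the multi-species occupancy model
#'
#' Container for the MCMC output of \code{\link{fitMsom}}. Scalar traces
#' (community hyperparameters, the augmentation parameter Omega, derived
#' richness N and community mean occupancy/detection) are stored as a
#' draws x chain x parameter array; species-level coefficients, detection
#' probabilities and inclusion indicators, and per-site richness, keep their
#' own arrays with a trailing draws x chain index.
#'
#' @slot scalars numeric array [draw, chain, parameter] of scalar traces.
#' @slot beta numeric array [species, coefficient, draw, chain].
#' @slot logitP numeric array [species, draw, chain].
#' @slot w integer array [species, draw, chain] of inclusion indicators.
#' @slot siteN integer array [site, draw, chain]: per-draw site richness.
#' @slot species character vector of row labels (observed then augmented).
#' @slot sites character vector of site labels.
#' @slot nObserved number of observed species K (the remaining rows are
#'   all-zero augmented pseudo-species).
#' @slot coefNames design-matrix coefficient labels (intercept first).
#' @slot acceptance named list of mean Metropolis acceptance rates.
#' @slot config the \code{\link{msomControl}} list used for the run.
#'
#' @seealso \code{\link{fitMsom}}, \code{\link{deriveRichness}},
#'   \code{\link{siteRichness}}, \code{\link{gelmanRubin}}
#' @exportClass MsomSamples
setClass("MsomSamples",
  representation(scalars = "array", beta = "array", logitP = "array",
                 w = "array", siteN = "array", species = "character",
                 sites = "character", nObserved = "integer",
                 coefNames = "character", acceptance = "list",
                 config = "list"))

setValidity("MsomSamples", function(object) {
  msg <- character()
  M <- length(object@species)
  if (dim(object@w)[1] != M) msg <- c(msg, "w must have one row per species")
  if (object@nObserved < 0 || object@nObserved > M)
    msg <- c(msg, "nObserved must be in [0, number of species]")
  Ndr <- apply(object@w, c(2, 3), sum)
  if (length(Ndr) && (min(Ndr) < object@nObserved || max(Ndr) > M))
    msg <- c(msg, "richness draws must lie in [K, M]")
  if (length(msg)) msg else TRUE
})

setMethod("show", "MsomSamples", function(object) {
  d <- dim(object@scalars)
  cat(sprintf("MsomSamples: %d species (%d observed + %d augmented), %d sites\n",
              length(object@species), object@nObserved,
              length(object@species) - object@nObserved, length(object@sites)))
  cat(sprintf("  %d stored draws x %d chains\n", d[1], d[2]))
  N <- richnessDraws(object)
  cat(sprintf("  species richness N: mean %.2f, 95%% CRI [%g, %g]\n",
              mean(N), quantile(N, 0.025), quantile(N, 0.975)))
})
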
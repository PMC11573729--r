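#' Read an ESRI ASCII grid raster
#'
#' Parses the plain-text ASCII grid interchange format (header lines
#' \code{ncols}, \code{nrows}, \code{xllcorner}, \code{yllcorner},
#' \code{cellsize}, optional \code{NODATA_value}, then rows north to south)
#' into a \linkS4class{RasterGrid}.
#'
#' @param path path to an .asc file.
#' @return A \linkS4class{RasterGrid}.
#' @export
readAsciiGrid <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  hdr <- list()
  i <- 1
  while (grepl("^[A-Za-z]", lines[i])) {
    parts <- strsplit(trimws(lines[i]), "[[:space:]]+")[[1]]
    hdr[[tolower(parts[1])]] <- as.numeric(parts[2])
    i <- i + 1
  }
  need <- c("ncols", "nrows", "xllcorner", "yllcorner", "cellsize")
  missing <- setdiff(need, names(hdr))
  if (length(missing))
    stop("ASCII grid header missing: ", paste(missing, collapse = ", "))
  vals <- scan(text = paste(lines[i:length(lines)], collapse = "\n"),
               quiet = TRUE)
  if (length(vals) != hdr$ncols * hdr$nrows)
    stop("ASCII grid body has ", length(vals), " values, expected ",
         hdr$ncols * hdr$nrows)
  m <- matrix(vals, nrow = hdr$nrows, ncol = hdr$ncols, byrow = TRUE)
  if (!is.null(hdr$nodata_value)) m[m == hdr$nodata_value] <- NA
  rasterGrid(m, xmin = hdr$xllcorner, ymin = hdr$yllcorner,
             cellSize = hdr$cellsize)
}

#' Write an ESRI ASCII grid raster
#'
#' @param grid a \linkS4class{RasterGrid}.
#' @param path output path.
#' @param nodata sentinel written for missing cells (default -9999).
#' @return \code{path}, invisibly.
#' @export
writeAsciiGrid <- function(grid, path, nodata = -9999) {
  m <- grid@values
  m[is.na(m)] <- nodata
  hdr <- c(paste("ncols", ncol(m)), paste("nrows", nrow(m)),
           paste("xllcorner", grid@xmin), paste("yllcorner", grid@ymin),
           paste("cellsize", grid@cellSize), paste("NODATA_value", nodata))
  body <- apply(m, 1, paste, collapse = " ")
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Terrain ruggedness index
#'
#' Converts an elevation raster to the terrain ruggedness index of Riley,
#' DeGloria and Elliot: for each cell, the square root of the sum of squared
#' elevation differences to its eight neighbours. Border cells use the
#' neighbours that exist; missing (\code{NA}) neighbours are excluded from the
#' sum. A cell with a missing elevation gets a missing TRI.
#'
#' @param elev a \linkS4class{RasterGrid} of elevations (>= 3 x 3).
#' @return A \linkS4class{RasterGrid} of TRI values on the same grid.
#' @examples
#' g <- rasterGrid(matrix(5, 5, 5))
#' terrainRuggedness(g)@values[3, 3]  # flat terrain -> 0
#' @export
terrainRuggedness <- function(elev) {
  e <- elev@values
  if (nrow(e) < 3 || ncol(e) < 3) stop("elevation grid must be at least 3 x 3")
  nr <- nrow(e); nc <- ncol(e)
  pad <- matrix(NA_real_, nr + 2, nc + 2)
  pad[2:(nr + 1), 2:(nc + 1)] <- e
  ss <- matrix(0, nr, nc)
  for (dr in -1:1) for (dc in -1:1) {
    if (dr == 0 && dc == 0) next
    nbr <- pad[(2 + dr):(nr + 1 + dr), (2 + dc):(nc + 1 + dc)]
    d2 <- (nbr - e)^2
    d2[is.na(d2)] <- 0
    ss <- ss + d2
  }
  tri <- sqrt(ss)
  tri[is.na(e)] <- NA
  rasterGrid(tri, xmin = elev@xmin, ymin = elev@ymin, cellSize = elev@cellSize)
}

rasterCellCenters <- function(grid) {
  nr <- nrow(grid@values); nc <- ncol(grid@values); cs <- grid@cellSize
  list(x = grid@xmin + (seq_len(nc) - 0.5) * cs,
       y = grid@ymin + (nr - seq_len(nr) + 0.5) * cs)
}

#' Mean raster value within a circular buffer
#'
#' Arithmetic mean of all non-missing cells whose center lies within
#' \code{radius} of the point (cell membership by center-in-circle, boundary
#' inclusive). Used to summarise elevation / TRI / canopy around a camera
#' station.
#'
#' @param grid a \linkS4class{RasterGrid}.
#' @param x,y point coordinates (same planar units as the grid, metres).
#' @param radius buffer radius in metres, default 100.
#' @return The buffered mean, or \code{NA} if no cell center qualifies.
#' @export
bufferMean <- function(grid, x, y, radius = 100) {
  nr <- nrow(grid@values); nc <- ncol(grid@values); cs <- grid@cellSize
  if (x < grid@xmin || x > grid@xmin + nc * cs ||
      y < grid@ymin || y > grid@ymin + nr * cs)
    stop("point (", x, ", ", y, ") lies outside the raster extent")
  cc <- rasterCellCenters(grid)
  d2 <- outer((cc$y - y)^2, (cc$x - x)^2, `+`)
  sel <- d2 <= radius^2 & !is.na(grid@values)
  if (!any(sel)) return(NA_real_)
  mean(grid@values[sel])
}

#' Per-site human-disturbance counts
#'
#' Number of independent human plus livestock images per camera site — the
#' anthropogenic disturbance covariate. Sites without such images get 0.
#'
#' @param records an independence-filtered record table.
#' @param sites site identifiers defining output order (and zero-count sites).
#' @return Named integer vector of counts.
#' @export
disturbanceCount <- function(records, sites = sort(unique(records$site))) {
  hl <- records[records$kind %in% c("human", "livestock"), , drop = FALSE]
  cnt <- table(factor(hl$site, levels = sites))
  setNames(as.integer(cnt), sites)
}

#' Standardize covariate columns
#'
#' Centers and scales each column to mean 0 and sample standard deviation 1
#' (n - 1 denominator), returning the constants for reuse on new sites.
#'
#' @param x numeric matrix (sites x covariates).
#' @return list with \code{x} (standardized matrix), \code{center}, \code{scale}.
#' @export
standardizeColumns <- function(x) {
  x <- as.matrix(x)
  ctr <- colMeans(x)
  scl <- apply(x, 2, sd)
  zero <- which(!is.finite(scl) | scl == 0)
  if (length(zero))
    stop("zero-variance covariate column(s): ",
         paste(colnames(x)[zero], collapse = ", "))
  list(x = sweep(sweep(x, 2, ctr), 2, scl, "/"), center = ctr, scale = scl)
}

designColumns <- c("elev", "elev2", "tri", "canopy", "disturbance")

#' Build the standardized occupancy design matrix
#'
#' Standardizes elevation, terrain ruggedness, canopy cover and disturbance,
#' then appends a quadratic elevation column computed as the square of the
#' already-standardized elevation (not re-standardized, so a site at the mean
#' elevation gets 0 in both columns). Column order is fixed:
#' \code{elev, elev2, tri, canopy, disturbance}.
#'
#' @param covariates data.frame with columns \code{site}, \code{elevation},
#'   \code{tri}, \code{canopy}, \code{disturbance}.
#' @return A numeric matrix (sites x 5) with attributes \code{center} and
#'   \code{scale} holding the standardization constants of the four base
#'   columns, and rownames = site IDs.
#' @export
buildDesignMatrix <- function(covariates) {
  need <- c("site", "elevation", "tri", "canopy", "disturbance")
  missing <- setdiff(need, names(covariates))
  if (length(missing))
    stop("covariate table is missing column(s): ",
         paste(missing, collapse = ", "))
  if (nrow(covariates) < 2) stop("need at least 2 sites")
  if (any(!complete.cases(covariates[need])))
    stop("covariate table contains missing values")
  base <- as.matrix(covariates[c("elevation", "tri", "canopy", "disturbance")])
  std <- standardizeColumns(base)
  X <- cbind(elev = std$x[, "elevation"],
             elev2 = std$x[, "elevation"]^2,
             tri = std$x[, "tri"],
             canopy = std$x[, "canopy"],
             disturbance = std$x[, "disturbance"])
  rownames(X) <- as.character(covariates$site)
  attr(X, "center") <- std$center
  attr(X, "scale") <- std$scale
  X
}

#' Derive per-site covariates from rasters and records
#'
#' Convenience wrapper: buffered means of elevation, TRI (derived from the
#' elevation raster) and canopy around each deployment, plus independent
#' human/livestock counts.
#'
#' @param deployments deployment table with \code{site}, \code{x}, \code{y}.
#' @param dem elevation \linkS4class{RasterGrid}.
#' @param canopy canopy-cover \linkS4class{RasterGrid} (percent).
#' @param records independence-filtered record table (for disturbance).
#' @param radius buffer radius in metres, default 100.
#' @return Covariate data.frame suitable for \code{\link{buildDesignMatrix}}.
#' @export
siteCovariates <- function(deployments, dem, canopy, records, radius = 100) {
  tri <- terrainRuggedness(dem)
  data.frame(
    site = deployments$site,
    elevation = mapply(function(x, y) bufferMean(dem, x, y, radius),
                       deployments$x, deployments$y),
    tri = mapply(function(x, y) bufferMean(tri, x, y, radius),
                 deployments$x, deployments$y),
    canopy = mapply(function(x, y) bufferMean(canopy, x, y, radius),
                    deployments$x, deployments$y),
    disturbance = unname(disturbanceCount(records, as.character(deployments$site))),
    row.names = NULL)
}
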
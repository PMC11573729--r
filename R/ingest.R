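#' Read camera-trap image records
#'
#' Reads a delimited table of classified camera-trap images into the record
#' table used by the rest of the pipeline. Each row is one image with its
#' camera site, classification kind (wildlife, human, livestock, blank,
#' unidentified), species label (wildlife rows) and a timestamp to the second.
#'
#' @param path path to a CSV file with columns \code{site}, \code{timestamp}
#'   and at least one of \code{species} / \code{kind}. When \code{kind} is
#'   absent every row is taken as wildlife.
#' @return A data.frame with columns \code{site}, \code{kind}, \code{species}
#'   and \code{timestamp} (POSIXct, camera-local clock stored as UTC), one row
#'   per image in file order.
#' @details Timestamps are treated as local camera time; no time-zone
#'   arithmetic is applied. Accepted formats are \code{"YYYY-mm-dd HH:MM:SS"}
#'   (optionally with a \code{T} separator, and seconds optional).
#' @examples
#' f <- tempfile(fileext = ".csv")
#' write.csv(data.frame(site = "S1", kind = "wildlife", species = "muntjac",
#'                      timestamp = "2017-01-05 06:30:00"), f, row.names = FALSE)
#' readCameraRecords(f)
#' @export
readCameraRecords <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("site", "timestamp")
  missing <- setdiff(need, names(raw))
  if (length(missing))
    stop("records file is missing required column(s): ",
         paste(missing, collapse = ", "))
  if (!any(c("species", "kind") %in% names(raw)))
    stop("records file is missing required column(s): species or kind")
  if (is.null(raw$kind)) raw$kind <- "wildlife"
  if (is.null(raw$species)) raw$species <- NA_character_
  makeRecordTable(site = raw$site, kind = raw$kind, species = raw$species,
                  timestamp = raw$timestamp)
}

recordKinds <- c("wildlife", "human", "livestock", "blank", "unidentified")

#' Assemble a record table in memory
#'
#' @param site,kind,species,timestamp equal-length vectors; \code{timestamp}
#'   may be character (parsed) or POSIXct.
#' @return A record-table data.frame (see \code{\link{readCameraRecords}}).
#' @export
makeRecordTable <- function(site, kind = "wildlife", species = NA_character_,
                            timestamp) {
  n <- max(length(site), length(kind), length(species), length(timestamp))
  site <- rep_len(as.character(site), n)
  kind <- rep_len(as.character(kind), n)
  species <- rep_len(as.character(species), n)
  timestamp <- rep(timestamp, length.out = n)
  bad <- !kind %in% recordKinds
  if (any(bad))
    stop("unknown record kind(s): ", paste(unique(kind[bad]), collapse = ", "))
  ts <- parseTimestamps(timestamp)
  if (any(kind == "wildlife" & (is.na(species) | !nzchar(species))))
    stop("wildlife records must carry a non-empty species label")
  data.frame(site = as.character(site), kind = kind, species = species,
             timestamp = ts, stringsAsFactors = FALSE)
}

parseTimestamps <- function(x) {
  if (inherits(x, "POSIXct")) return(x)
  x <- as.character(x)
  fmts <- c("%Y-%m-%d %H:%M:%S", "%Y-%m-%dT%H:%M:%S", "%Y-%m-%d %H:%M")
  ts <- .POSIXct(rep(NA_real_, length(x)), tz = "UTC")
  for (f in fmts) {
    miss <- which(is.na(ts))
    if (!length(miss)) break
    ts[miss] <- as.POSIXct(strptime(x[miss], f, tz = "UTC"))
  }
  ok <- !is.na(ts)
  if (any(!ok))
    stop("unparseable timestamp(s) at row(s): ",
         paste(which(!ok), collapse = ", "),
         " (first offending value: '", x[which(!ok)[1]], "')")
  ts
}

#' Read camera deployments
#'
#' @param path CSV with columns \code{site}, \code{x}, \code{y},
#'   \code{start}, \code{end} (dates, inclusive).
#' @return A data.frame with \code{start}/\code{end} as \code{Date} and an
#'   \code{activeDays} column (\code{end - start + 1}).
#' @export
readDeployments <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  d <- read.csv(path, stringsAsFactors = FALSE)
  missing <- setdiff(c("site", "start", "end"), names(d))
  if (length(missing))
    stop("deployments file is missing required column(s): ",
         paste(missing, collapse = ", "))
  d$start <- as.Date(d$start)
  d$end <- as.Date(d$end)
  validateDeployments(d)
}

validateDeployments <- function(d) {
  if (anyNA(d$start) || anyNA(d$end)) stop("unparseable deployment dates")
  if (any(d$end < d$start)) stop("deployment end date before start date")
  if (anyDuplicated(d$site)) stop("duplicated site in deployments")
  d$activeDays <- as.integer(d$end - d$start) + 1L
  d
}

#' Group hard-to-identify taxa under one label
#'
#' Relabels species that cannot reliably be told apart on images (e.g. mice of
#' several genera) so they enter the model as one pseudo-species. Labels not
#' present in the mapping pass through unchanged; the number of records never
#' changes.
#'
#' @param records a record table.
#' @param mapping named character vector: \code{c("species label" = "group label")}.
#' @return The record table with taxa relabelled.
#' @examples
#' r <- makeRecordTable(site = "S1", species = c("Apodemus gorkha", "Mus cervicolor"),
#'                      timestamp = c("2017-01-01 08:00:00", "2017-01-02 08:00:00"))
#' table(aggregateTaxa(r, c("Apodemus gorkha" = "Mouse spp.",
#'                          "Mus cervicolor" = "Mouse spp."))$species)
#' @export
aggregateTaxa <- function(records, mapping) {
  if (length(mapping) == 0) return(records)
  stopifnot(is.character(mapping), !is.null(names(mapping)))
  hit <- records$species %in% names(mapping)
  records$species[hit] <- unname(mapping[records$species[hit]])
  records
}

#' Keep only temporally independent records
#'
#' Consecutive images of the same species at the same camera are counted as a
#' single detection event unless separated by at least \code{windowMinutes}.
#' Within each (site, species) stream, processed in time order, a record is
#' retained iff at least \code{windowMinutes} have elapsed since the previously
#' retained record of that stream (greedy from the first image; a gap of
#' exactly \code{windowMinutes} counts as independent). Human and livestock
#' images are filtered the same way per (site, kind); blank and unidentified
#' rows pass through untouched.
#'
#' @param records a record table.
#' @param windowMinutes independence window, default 60.
#' @return The retained subset of \code{records}, in the original row order.
#' @examples
#' r <- makeRecordTable(site = "S1", species = "muntjac",
#'   timestamp = sprintf("2017-01-01 %02d:%02d:00", c(8, 8, 9, 9, 10), c(0, 30, 0, 30, 0)))
#' nrow(filterIndependent(r))  # images at 0/30/60/90/120 min -> 3 independent
#' @export
filterIndependent <- function(records, windowMinutes = 60) {
  if (length(windowMinutes) != 1 || !is.finite(windowMinutes) || windowMinutes < 0)
    stop("windowMinutes must be a single non-negative number")
  stream <- ifelse(records$kind == "wildlife",
                   paste(records$site, "w", records$species, sep = "\r"),
            ifelse(records$kind %in% c("human", "livestock"),
                   paste(records$site, "k", records$kind, sep = "\r"),
                   NA_character_))
  keep <- rep(TRUE, nrow(records))
  for (s in unique(stream[!is.na(stream)])) {
    idx <- which(!is.na(stream) & stream == s)
    idx <- idx[order(records$timestamp[idx])]
    lastKept <- -Inf
    for (i in idx) {
      t <- as.numeric(records$timestamp[i])
      if (t - lastKept >= windowMinutes * 60) lastKept <- t
      else keep[i] <- FALSE
    }
  }
  records[keep, , drop = FALSE]
}

#' Build species detection histories
#'
#' Bins independence-filtered wildlife records into survey occasions and counts,
#' per species and site, the occasions with at least one detection (y_ik), along
#' with the per-site number of active occasions (n_i). Occasions are aligned to
#' each deployment's start date; with \code{occasionDays > 1} a trailing partial
#' occasion is dropped from both effort and counts.
#'
#' @param records an independence-filtered record table.
#' @param deployments deployment table (see \code{\link{readDeployments}}).
#' @param occasionDays occasion length in days, default 1 (1 occasion = 1 trap
#'   night).
#' @return A \linkS4class{DetectionHistory}.
#' @examples
#' dh <- exampleDetectionHistory()
#' effort(dh)
#' @export
buildDetectionHistory <- function(records, deployments, occasionDays = 1) {
  stopifnot(occasionDays >= 1, occasionDays == round(occasionDays))
  deployments <- validateDeployments(deployments)
  unknown <- setdiff(unique(records$site), deployments$site)
  if (length(unknown))
    stop("record site(s) not present in deployments: ",
         paste(unknown, collapse = ", "))
  n <- deployments$activeDays %/% occasionDays
  names(n) <- deployments$site

  wl <- records[records$kind == "wildlife", , drop = FALSE]
  dep <- deployments[match(wl$site, deployments$site), ]
  day <- as.integer(as.Date(wl$timestamp, tz = "UTC") - dep$start)
  outside <- day < 0 | day > (dep$activeDays - 1L)
  if (any(outside))
    stop("record(s) outside the deployment window at row(s): ",
         paste(which(records$kind == "wildlife")[outside], collapse = ", "))
  occ <- day %/% occasionDays
  inWindow <- occ < n[wl$site]           # drop trailing partial occasion
  wl <- wl[inWindow, , drop = FALSE]
  occ <- occ[inWindow]

  species <- sort(unique(wl$species))
  y <- matrix(0L, length(species), length(n),
              dimnames = list(species, deployments$site))
  if (nrow(wl)) {
    key <- unique(data.frame(species = wl$species, site = wl$site, occ = occ))
    tab <- table(factor(key$species, species), factor(key$site, deployments$site))
    y[] <- as.integer(tab)
  }
  newDetectionHistory(y, n, occasionDays)
}

newDetectionHistory <- function(y, n, occasionDays = 1) {
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(detections = y),
    colData = S4Vectors::DataFrame(effort = as.integer(unname(n)),
                                   row.names = colnames(y)))
  new("DetectionHistory", se, occasionDays = occasionDays)
}

#' Detection-frequency categories
#'
#' Bins species by their survey-wide number of independent detection occasions:
#' Abundant (> 100), Common (11-100), Uncommon (2-10), Rare (1), plus the count
#' of species the richness model estimates were present but never detected.
#'
#' @param history a \linkS4class{DetectionHistory}.
#' @param estRichness estimated community richness (>= number of observed
#'   species); the Undetected row is \code{estRichness - nrow(history)}.
#' @return data.frame with columns \code{category} and \code{speciesCount}.
#' @export
detectionCategories <- function(history, estRichness) {
  y <- detections(history)
  K <- nrow(y)
  if (estRichness < K) stop("estRichness must be >= number of observed species")
  d <- rowSums(y)
  data.frame(
    category = factor(c("Abundant", "Common", "Uncommon", "Rare", "Undetected"),
                      levels = c("Abundant", "Common", "Uncommon", "Rare",
                                 "Undetected")),
    speciesCount = c(sum(d > 100), sum(d >= 11 & d <= 100),
                     sum(d >= 2 & d <= 10), sum(d == 1),
                     as.integer(round(estRichness)) - K))
}

#' Naive occupancy and detection estimates
#'
#' Model-free summaries uncorrected for imperfect detection: naive occupancy is
#' the fraction of sites with at least one detection; naive detection is total
#' detections divided by total effort (trap nights for daily occasions).
#'
#' @param history a \linkS4class{DetectionHistory}.
#' @return data.frame with columns \code{species}, \code{naivePsi}, \code{naiveP}.
#' @export
naiveEstimates <- function(history) {
  y <- detections(history)
  n <- effort(history)
  data.frame(species = rownames(y),
             naivePsi = rowMeans(y >= 1),
             naiveP = rowSums(y) / sum(n),
             row.names = NULL)
}

#' Image-classification percentage table
#'
#' Recomputes category percentages from raw image counts (percent of
#' \code{total}, rounded to 2 decimal places) — the arithmetic behind survey
#' summary sentences such as "wildlife (16.58%, n = 2541)".
#'
#' @param counts named integer vector of image counts per category.
#' @param total denominator; defaults to \code{sum(counts)}.
#' @return data.frame with \code{category}, \code{n}, \code{percent}.
#' @export
classificationPercentages <- function(counts, total = sum(counts)) {
  data.frame(category = names(counts), n = as.integer(counts),
             percent = round(100 * as.numeric(counts) / total, 2),
             row.names = NULL)
}

#' Small built-in example detection history
#'
#' A deterministic toy survey (4 species, 5 sites) used in documentation
#' examples.
#' @return A \linkS4class{DetectionHistory}.
#' @export
exampleDetectionHistory <- function() {
  y <- matrix(c(3L, 0L, 1L, 2L, 5L,
                0L, 1L, 0L, 0L, 2L,
                1L, 1L, 1L, 1L, 1L,
                0L, 0L, 0L, 4L, 0L), 4, 5, byrow = TRUE,
              dimnames = list(c("barking deer", "leopard cat", "mouse spp.",
                                "serow"), paste0("S", 1:5)))
  newDetectionHistory(y, setNames(c(80L, 74L, 90L, 107L, 85L), paste0("S", 1:5)))
}
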
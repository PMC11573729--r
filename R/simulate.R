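#' Community hyperparameters for the synthetic survey generator
#'
#' Defaults place the community at the study's operating regime: mean
#' occupancy about 0.28 and mean per-occasion detection about 0.02. Because
#' species effects are drawn on the logit scale, the logit-scale community
#' means are found by numerically inverting the logistic-normal mean
#' E[plogis(Normal(mu, sd^2))] so the realized probability-scale means hit
#' those targets exactly in expectation.
#'
#' @param meanPsi target community mean occupancy probability.
#' @param meanP target community mean per-occasion detection probability.
#' @param sdBeta0 community sd of occupancy intercepts (logit scale).
#' @param sdP community sd of logit detection.
#' @param muSlopes named community mean covariate effects (logit scale) for
#'   columns of the design matrix; \code{NULL} for an intercept-only
#'   community.
#' @param sdSlopes community sd of covariate effects.
#' @return Named list of hyperparameters.
#' @export
msomHyper <- function(meanPsi = 0.28, meanP = 0.02, sdBeta0 = 1, sdP = 0.7,
                      muSlopes = NULL, sdSlopes = 0.5) {
  list(mu0 = logisticNormalMu(meanPsi, sdBeta0), sd0 = sdBeta0,
       muP = logisticNormalMu(meanP, sdP), sdP = sdP,
       muSlopes = muSlopes, sdSlopes = sdSlopes)
}

## mean of plogis(Normal(mu, sd^2)) by quadrature, and its inverse in mu
logisticNormalMean <- function(mu, sd) {
  stats::integrate(function(x) plogis(x) * dnorm(x, mu, sd),
                   mu - 10 * sd, mu + 10 * sd, rel.tol = 1e-10)$value
}

logisticNormalMu <- function(target, sd) {
  stopifnot(target > 0, target < 1)
  stats::uniroot(function(m) logisticNormalMean(m, sd) - target,
                 c(qlogis(target) - 5 * sd, qlogis(target) + 5 * sd),
                 tol = 1e-9)$root
}

#' Simulate per-site habitat covariates
#'
#' Draws a covariate table shaped like a mid-elevation Himalayan survey:
#' elevation Uniform(1400, 3000) m, terrain ruggedness |Normal| (TRI units),
#' canopy cover Beta-scaled to [0, 100] percent, and overdispersed
#' negative-binomial human-disturbance counts.
#'
#' @param I number of camera sites, default 45.
#' @param seed optional RNG seed (reproducible output).
#' @return data.frame with columns \code{site}, \code{elevation}, \code{tri},
#'   \code{canopy}, \code{disturbance}.
#' @export
simulateCovariates <- function(I = 45, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  data.frame(site = sprintf("S%02d", seq_len(I)),
             elevation = runif(I, 1400, 3000),
             tri = abs(rnorm(I, 8, 5)),
             canopy = 100 * rbeta(I, 2, 1.2),
             disturbance = rnbinom(I, size = 1.2, mu = 8))
}

#' Simulate a community camera-trap survey with known truth
#'
#' Runs the occupancy and detection model forward: species occupancy
#' intercepts (and optional covariate effects) and logit detection
#' probabilities are drawn from community normal distributions, presence
#' z_ik ~ Bernoulli(psi_ik), detections y_ik ~ Binomial(n_i, p_k z_ik).
#' Species with no detections anywhere are dropped from the returned
#' detection history — exactly as a real survey would miss them — while the
#' truth object retains the full community, so richness-recovery experiments
#' know how many species were missed.
#'
#' @param I number of sites, default 45.
#' @param nTrue true community richness, default 26.
#' @param hyper hyperparameters from \code{\link{msomHyper}}.
#' @param effort per-site active occasions; default samples 74-107 trap
#'   nights per site.
#' @param X optional standardized covariate matrix (I x M) acting on
#'   occupancy through \code{hyper$muSlopes}/\code{sdSlopes}.
#' @param seed optional RNG seed.
#' @return list with \code{history} (a \linkS4class{DetectionHistory} of the
#'   observed species) and \code{truth} (list: \code{beta}, \code{p},
#'   \code{z}, \code{psi}, \code{effort}, \code{observed} flags, realized
#'   \code{meanPsi} and \code{meanP}, and the generating hyperparameters).
#' @examples
#' sim <- simulateCommunity(I = 10, nTrue = 8, seed = 1)
#' nrow(sim$history) <= 8
#' @export
simulateCommunity <- function(I = 45, nTrue = 26, hyper = msomHyper(),
                              effort = NULL, X = NULL, seed = NULL) {
  stopifnot(I >= 2, nTrue >= 1)
  if (!is.null(seed)) set.seed(seed)
  if (is.null(effort)) effort <- sample(74:107, I, replace = TRUE)
  stopifnot(length(effort) == I, all(effort >= 1))
  if (!is.null(X)) {
    X <- as.matrix(X)
    stopifnot(nrow(X) == I)
    P <- ncol(X)
    muS <- rep_len(if (is.null(hyper$muSlopes)) 0 else hyper$muSlopes, P)
    slopes <- matrix(rnorm(nTrue * P, rep(muS, each = nTrue),
                           hyper$sdSlopes), nTrue, P)
  } else {
    P <- 0
    slopes <- matrix(numeric(0), nTrue, 0)
  }
  beta <- cbind(rnorm(nTrue, hyper$mu0, hyper$sd0), slopes)
  lp <- rnorm(nTrue, hyper$muP, hyper$sdP)
  p <- plogis(lp)
  X1 <- cbind(rep(1, I), X)
  psi <- plogis(beta %*% t(X1))             # nTrue x I
  z <- matrix(rbinom(nTrue * I, 1L, psi), nTrue, I)
  y <- matrix(rbinom(nTrue * I, rep(effort, each = nTrue),
                     rep(p, I) * z), nTrue, I)
  species <- sprintf("sp%02d", seq_len(nTrue))
  sites <- sprintf("S%02d", seq_len(I))
  dimnames(y) <- list(species, sites)
  observed <- rowSums(y) > 0
  history <- newDetectionHistory(y[observed, , drop = FALSE],
                                 setNames(as.integer(effort), sites))
  truth <- list(beta = beta, p = p, z = z, psi = psi,
                effort = as.integer(effort), species = species,
                observed = observed, y = y,
                meanPsi = mean(psi), meanP = mean(p), hyper = hyper, X = X)
  list(history = history, truth = truth)
}

#' Expand a simulated survey into timestamped camera records
#'
#' Turns each detection day of a simulated survey into a short within-hour
#' image burst (all burst images fall inside the one-hour independence
#' window, so filtering recovers exactly one independent record per detection
#' day), and adds human/livestock and blank trigger rows. Running the result
#' through \code{\link{filterIndependent}} and
#' \code{\link{buildDetectionHistory}} reproduces the generating detection
#' matrix exactly.
#'
#' Trigger times follow simple diel patterns: wildlife bursts start at
#' crepuscular/nocturnal hours (a mixture of peaks near 05:00 and 19:00),
#' human and livestock activity peaks near midday, and blanks fire uniformly.
#' All burst start hours are truncated to [01:00, 22:00] so bursts never span
#' midnight and detections on consecutive days stay independent.
#'
#' @param sim output of \code{\link{simulateCommunity}}.
#' @param burstMax maximum images per detection event; 1 means a single image
#'   per detection day.
#' @param humanRate,livestockRate expected human / livestock image bursts per
#'   site over the whole deployment.
#' @param blankRate expected blank triggers per site.
#' @param startDate first possible deployment start date.
#' @param seed optional RNG seed.
#' @return list with \code{records} (a record table) and \code{deployments}
#'   (site, x, y, start, end).
#' @export
simulateCameraRecords <- function(sim, burstMax = 3, humanRate = 6,
                                  livestockRate = 3, blankRate = 10,
                                  startDate = as.Date("2016-12-31"),
                                  seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  y <- detections(sim$history)
  n <- effort(sim$history)
  sites <- colnames(y)
  I <- length(sites)
  start <- startDate + sample(0:21, I, replace = TRUE)
  deployments <- data.frame(site = sites,
                            x = runif(I, 0, 12000), y = runif(I, 0, 12000),
                            start = start, end = start + n - 1)
  rows <- list()
  dielHour <- function(kind) {
    ## burst start hour, truncated to [1, 22] so that consecutive days are
    ## always > 1 h apart and a burst never crosses midnight
    repeat {
      h <- switch(kind,
                  wildlife = rnorm(1, sample(c(5, 19), 1), 1.5),
                  human = rnorm(1, 13, 2.5),
                  livestock = rnorm(1, 13, 2.5),
                  runif(1, 1, 22))
      if (h >= 1 && h <= 22) return(h)
    }
  }
  burstTimes <- function(day0, nEvents, kind) {
    ## one burst per event day
    lapply(seq_len(nEvents), function(e) {
      nImg <- sample.int(max(burstMax, 1), 1)
      base <- day0[e] * 86400 + dielHour(kind) * 3600
      base + c(0, cumsum(60 * (1 + runif(max(nImg - 1, 0)) * 10)))
    })
  }
  for (i in seq_len(I)) {
    origin <- as.POSIXct(paste(deployments$start[i], "00:00:00"), tz = "UTC")
    for (k in seq_len(nrow(y))) {
      if (y[k, i] == 0) next
      days <- sort(sample.int(n[i], y[k, i]) - 1L)
      for (ts in burstTimes(days, y[k, i], "wildlife"))
        rows[[length(rows) + 1]] <- data.frame(
          site = sites[i], kind = "wildlife", species = rownames(y)[k],
          timestamp = origin + ts, stringsAsFactors = FALSE)
    }
    for (kind in c("human", "livestock", "blank")) {
      rate <- switch(kind, human = humanRate, livestock = livestockRate,
                     blank = blankRate)
      nEv <- rpois(1, rate)
      if (nEv == 0) next
      days <- sample.int(n[i], nEv, replace = TRUE) - 1L
      for (ts in burstTimes(days, nEv, kind))
        rows[[length(rows) + 1]] <- data.frame(
          site = sites[i], kind = kind, species = NA_character_,
          timestamp = origin + ts, stringsAsFactors = FALSE)
    }
  }
  records <- do.call(rbind, rows)
  records <- records[order(records$timestamp, records$site), ]
  rownames(records) <- NULL
  list(records = records, deployments = deployments)
}
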
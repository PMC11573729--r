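#' Posterior site-level species richness
#'
#' Per posterior draw, the number of species present at each site,
#' N_i = sum_k w_k z_ik, computed during sampling and stored in the fit.
#'
#' @param samples a \linkS4class{MsomSamples}.
#' @return list with \code{draws} (sites x pooled draws matrix), \code{mean}
#'   (named per-site posterior means) and \code{summary} (per-site data.frame
#'   with mean, sd and credible interval).
#' @export
siteRichness <- function(samples) {
  d <- samples@siteN
  draws <- matrix(d, nrow = dim(d)[1])
  rownames(draws) <- samples@sites
  summ <- do.call(rbind, lapply(seq_len(nrow(draws)), function(i)
    summariseDraws(draws[i, ], samples@sites[i])))
  names(summ)[1] <- "site"
  list(draws = draws, mean = setNames(rowMeans(draws), samples@sites),
       summary = summ)
}

#' Regression of modeled species richness on site covariates
#'
#' Ordinary least squares of the per-site posterior mean richness on the
#' standardized covariate columns, with classical t-based standard errors,
#' 95 percent confidence intervals and two-sided p-values on
#' I - M - 1 degrees of freedom (I sites, M covariates).
#'
#' @param meanN length-I response (posterior mean site richness).
#' @param X standardized covariate matrix (I x M), e.g. from
#'   \code{\link{buildDesignMatrix}}.
#' @return data.frame with one row per term (intercept first): \code{beta},
#'   \code{se}, \code{ciLow}, \code{ciHigh}, \code{t}, \code{p}, plus a
#'   \code{df} attribute.
#' @examples
#' X <- cbind(x = 0:3)
#' richnessRegression(c(1, 2, 3, 5), X)  # slope 1.3, intercept 0.8
#' @export
richnessRegression <- function(meanN, X) {
  X <- as.matrix(X)
  if (length(meanN) != nrow(X)) stop("meanN and X disagree on site count")
  if (length(meanN) <= ncol(X) + 1)
    stop("need more sites than regression parameters")
  Xf <- cbind(`(Intercept)` = 1, X)
  qrX <- qr(Xf)
  if (qrX$rank < ncol(Xf)) {
    dropped <- colnames(Xf)[qrX$pivot[(qrX$rank + 1):ncol(Xf)]]
    stop("design matrix is rank deficient; collinear column(s): ",
         paste(dropped, collapse = ", "))
  }
  fit <- lm(meanN ~ X)
  cf <- summary(fit)$coefficients
  df <- fit$df.residual
  tcrit <- qt(0.975, df)
  out <- data.frame(term = c("(Intercept)", colnames(X)),
                    beta = cf[, 1], se = cf[, 2],
                    ciLow = cf[, 1] - tcrit * cf[, 2],
                    ciHigh = cf[, 1] + tcrit * cf[, 2],
                    t = cf[, 3], p = cf[, 4], row.names = NULL)
  attr(out, "df") <- df
  out
}

#' Species accumulation curve
#'
#' For each survey day (pooled over all sites), the cumulative number of
#' distinct species detected on or before that day. The curve is
#' non-decreasing and ends at the observed species count; plotted against the
#' model's posterior richness it shows how far the survey was from complete.
#'
#' @param records a record table (independence filtering is irrelevant here —
#'   only first detections matter).
#' @return data.frame with \code{occasion} (1-based survey day), \code{date},
#'   and \code{cumulative} species count.
#' @export
accumulationCurve <- function(records) {
  wl <- records[records$kind == "wildlife", , drop = FALSE]
  if (nrow(wl) == 0) stop("no wildlife records")
  day <- as.Date(wl$timestamp, tz = "UTC")
  days <- seq(min(day), max(day), by = "day")
  firstDay <- vapply(split(as.numeric(day), wl$species), min, numeric(1))
  cum <- vapply(as.numeric(days), function(d) sum(firstDay <= d), integer(1))
  data.frame(occasion = seq_along(days), date = days, cumulative = cum)
}

## von Mises ML concentration from the mean resultant length (Fisher 1993)
a1inv <- function(R) {
  if (R < 0.53) 2 * R + R^3 + 5 * R^5 / 6
  else if (R < 0.85) -0.4 + 1.39 * R + 0.43 / (1 - R)
  else 1 / (R^3 - 4 * R^2 + 3 * R)
}

## plug-in smoothing concentration for circular KDE (Taylor 2008 rule)
vonMisesBandwidth <- function(theta) {
  n <- length(theta)
  R <- sqrt(mean(cos(theta))^2 + mean(sin(theta))^2)
  k <- a1inv(R)
  ((3 * n * k^2 * besselI(2 * k, 2)) /
     (4 * sqrt(pi) * besselI(k, 1)^2))^(2 / 5)
}

vonMisesKde <- function(theta, grid, kappa) {
  dens <- vapply(grid, function(g)
    mean(exp(kappa * cos(g - theta))), numeric(1)) /
    (2 * pi * besselI(kappa, 0, expon.scaled = TRUE) * exp(kappa))
  dens
}

#' Coefficient of overlap between two daily activity patterns
#'
#' Estimates the overlap Dhat1 = integral of min(f, g) between the circular
#' kernel density estimates of two samples of detection times-of-day (von
#' Mises kernel, plug-in concentration, trapezoid integration on a periodic
#' grid). 0 means fully disjoint activity, 1 identical activity.
#'
#' @param timesA,timesB numeric vectors of clock times in hours [0, 24)
#'   (values outside are wrapped), each with at least 2 observations.
#' @param nGrid number of grid points on the circle, default 512.
#' @return Overlap coefficient in [0, 1].
#' @examples
#' day <- c(11, 12, 12.5, 13, 11.5, 12.2)
#' night <- (day + 12) %% 24
#' activityOverlap(day, night) # near 0: activity 12 h apart
#' @export
activityOverlap <- function(timesA, timesB, nGrid = 512) {
  if (length(timesA) < 2 || length(timesB) < 2)
    stop("each sample needs at least 2 observations")
  a <- (timesA %% 24) * 2 * pi / 24
  b <- (timesB %% 24) * 2 * pi / 24
  grid <- seq(0, 2 * pi, length.out = nGrid + 1)
  fa <- vonMisesKde(a, grid, vonMisesBandwidth(a))
  fb <- vonMisesKde(b, grid, vonMisesBandwidth(b))
  m <- pmin(fa, fb)
  h <- 2 * pi / nGrid
  dhat <- sum((m[-1] + m[-length(m)]) / 2) * h
  min(max(dhat, 0), 1)
}
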
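#' Occupancy probability under the logit link
#'
#' psi = logit^-1(beta0 + sum_m beta_m x_m): the probability a species with
#' coefficient vector \code{beta} occupies a site with covariate row \code{x}.
#'
#' @param beta coefficient vector, intercept first.
#' @param x covariate values (length \code{length(beta) - 1}; the intercept is
#'   prepended internally).
#' @return Occupancy probability in (0, 1).
#' @examples
#' occupancyProb(c(1, 2), 0.5)  # 1 / (1 + exp(-2))
#' @export
occupancyProb <- function(beta, x = numeric(0)) {
  if (length(beta) != length(x) + 1)
    stop("beta must have one more element than x (the intercept)")
  plogis(sum(beta * c(1, x)))
}

#' Observation log-likelihood for one species-site cell
#'
#' The detection model: given presence (z = 1) the number of detection
#' occasions is Binomial(n, p); given absence, detections are impossible.
#'
#' @param y detections (0 <= y <= n).
#' @param n occasions.
#' @param p per-occasion detection probability.
#' @param z latent presence indicator (0/1).
#' @return log-probability (\code{-Inf} when z = 0 but y > 0).
#' @export
obsLoglik <- function(y, n, p, z) {
  if (any(y > n) || any(y < 0)) stop("y must lie in [0, n]")
  ifelse(z == 1, dbinom(y, n, p, log = TRUE), ifelse(y == 0, 0, -Inf))
}

#' Full-conditional presence probability
#'
#' P(z_ik = 1 | y, psi, p, w): 1 whenever a detection occurred; for included
#' species (w = 1) with y = 0 the two-hypothesis Bayes weight
#' psi (1-p)^n / (psi (1-p)^n + 1 - psi); for excluded species (w = 0) the
#' prior psi (the observation likelihood is flat since y must be 0).
#'
#' @param psi,p,n,y,w vectors (recycled) of occupancy probability, detection
#'   probability, occasions, detections and inclusion indicator.
#' @return Vector of conditional probabilities.
#' @export
zConditionalProb <- function(psi, p, n, y, w = 1) {
  if (any(w == 0 & y > 0))
    stop("invalid state: detections recorded for a species with w = 0")
  len <- max(length(psi), length(p), length(n), length(y), length(w))
  psi <- rep_len(psi, len); p <- rep_len(p, len); n <- rep_len(n, len)
  y <- rep_len(y, len); w <- rep_len(w, len)
  q <- psi * (1 - p)^n
  ifelse(w == 1, ifelse(y > 0, 1, q / (q + 1 - psi)), psi)
}

#' Collapsed full-conditional inclusion probability
#'
#' For an all-zero augmented species, the latent z row is marginalized out:
#' P(w_k = 1 | y = 0, .) = Omega L1 / (Omega L1 + 1 - Omega) with
#' L1 = prod_i [psi_ik (1-p_k)^{n_i} + 1 - psi_ik].
#'
#' @param psi length-I occupancy probabilities of the species.
#' @param p its detection probability.
#' @param n per-site occasions.
#' @param omega community inclusion probability.
#' @return P(w = 1 | all-zero detection row).
#' @export
wConditionalProb <- function(psi, p, n, omega) {
  L1 <- exp(sum(log(psi * (1 - p)^n + 1 - psi)))
  omega * L1 / (omega * L1 + 1 - omega)
}

log1pexp <- function(x) ifelse(x > 30, x, log1p(exp(x)))

## ---- internal sampler machinery ------------------------------------------
## data: list(y, n, X1, K, M, I, P1, lchoose)
## state: list(beta, lp, w, z, omega, mu, sigma, muP, sigmaP)

msomData <- function(y, n, X = NULL, nAug) {
  K <- nrow(y); I <- ncol(y)
  if (is.null(X)) X <- matrix(numeric(0), I, 0)
  X1 <- cbind(`(Intercept)` = 1, X)
  yAug <- rbind(y, matrix(0L, nAug, I))
  rownames(yAug) <- c(rownames(y), if (nAug) sprintf("aug%02d", seq_len(nAug)))
  lc <- matrix(lchoose(rep(n, each = nrow(yAug)), yAug), nrow(yAug), I)
  list(y = yAug, n = n, X1 = X1, K = K, M = K + nAug, I = I,
       P1 = ncol(X1), lchoose = lc)
}

psiMatrix <- function(beta, X1) plogis(beta %*% t(X1))

etaMatrix <- function(beta, X1) beta %*% t(X1)

## per-species log posterior (z-likelihood + obs likelihood + priors)
speciesLogPost <- function(beta, lp, z, state, data) {
  eta <- etaMatrix(beta, data$X1)
  zll <- rowSums(z * eta - log1pexp(eta))
  p <- plogis(lp)
  obs <- data$lchoose + data$y * log(p) +
    sweep(-data$y, 2, data$n, "+") * log1p(-p)
  oll <- rowSums(z * obs)
  prior <- rowSums(dnorm(sweep(beta, 2, state$mu), 0,
                         rep(state$sigma, each = data$M), log = TRUE)) +
    dnorm(lp, state$muP, state$sigmaP, log = TRUE)
  zll + oll + prior
}

updateZ <- function(state, data) {
  psi <- psiMatrix(state$beta, data$X1)
  p <- plogis(state$lp)
  q <- psi * exp(outer(log1p(-p), data$n))
  pz <- ifelse(rep(state$w, data$I) == 1,
               ifelse(data$y > 0, 1, q / (q + 1 - psi)),
               psi)
  state$z <- matrix(rbinom(length(pz), 1L, pz), data$M, data$I)
  state
}

updateW <- function(state, data) {
  if (data$M == data$K) return(state)
  aug <- (data$K + 1):data$M
  psi <- psiMatrix(state$beta[aug, , drop = FALSE], data$X1)
  p <- plogis(state$lp[aug])
  q <- psi * exp(outer(log1p(-p), data$n))
  L1 <- exp(rowSums(log(q + 1 - psi)))
  pw <- state$omega * L1 / (state$omega * L1 + 1 - state$omega)
  state$w[aug] <- rbinom(length(aug), 1L, pw)
  ## redraw z for augmented rows conditional on the refreshed w
  pz <- ifelse(rep(state$w[aug], data$I) == 1, q / (q + 1 - psi), psi)
  state$z[aug, ] <- rbinom(length(pz), 1L, pz)
  state
}

updateOmega <- function(state, data) {
  state$omega <- rbeta(1, 1 + sum(state$w), 1 + data$M - sum(state$w))
  state
}

updateSpeciesParams <- function(state, data, scales) {
  cur <- speciesLogPost(state$beta, state$lp, state$z, state, data)
  act <- state$w == 1
  if (any(!is.finite(cur[act])))
    stop("invalid state: non-finite species log posterior")
  accepted <- rep(NA, data$M)
  if (any(act)) {
    nact <- sum(act)
    betaProp <- state$beta
    betaProp[act, ] <- state$beta[act, , drop = FALSE] +
      matrix(rnorm(nact * data$P1), nact) * scales[act]
    lpProp <- state$lp
    lpProp[act] <- state$lp[act] + rnorm(nact) * scales[act]
    prop <- speciesLogPost(betaProp, lpProp, state$z, state, data)
    acc <- act & log(runif(data$M)) < (prop - cur)
    state$beta[acc, ] <- betaProp[acc, , drop = FALSE]
    state$lp[acc] <- lpProp[acc]
    accepted[act] <- acc[act]
  }
  if (any(!act)) {
    nid <- sum(!act)
    state$beta[!act, ] <- rep(state$mu, each = nid) +
      matrix(rnorm(nid * data$P1), nid) * rep(state$sigma, each = nid)
    state$lp[!act] <- rnorm(nid, state$muP, state$sigmaP)
  }
  list(state = state, accepted = accepted)
}

## conjugate normal mean given values, sd and N(0, priorSd^2) prior
conjNormalMean <- function(values, sigma, priorSd = 10) {
  prec <- length(values) / sigma^2 + 1 / priorSd^2
  rnorm(1, sum(values) / sigma^2 / prec, sqrt(1 / prec))
}

## random-walk on log sigma with Uniform(0, upper) prior on sigma
updateSigma <- function(values, mu, sigma, scale, upper = 5) {
  ls <- log(sigma)
  lsProp <- ls + rnorm(1) * scale
  sigProp <- exp(lsProp)
  if (sigProp >= upper) return(list(sigma = sigma, accepted = FALSE))
  lr <- sum(dnorm(values, mu, sigProp, log = TRUE)) -
    sum(dnorm(values, mu, sigma, log = TRUE)) + (lsProp - ls)
  if (log(runif(1)) < lr) list(sigma = sigProp, accepted = TRUE)
  else list(sigma = sigma, accepted = FALSE)
}

updateHyperparams <- function(state, data, scales) {
  accepted <- logical(data$P1 + 1)
  for (j in seq_len(data$P1)) {
    state$mu[j] <- conjNormalMean(state$beta[, j], state$sigma[j])
    up <- updateSigma(state$beta[, j], state$mu[j], state$sigma[j], scales[j])
    state$sigma[j] <- up$sigma
    accepted[j] <- up$accepted
  }
  state$muP <- conjNormalMean(state$lp, state$sigmaP)
  up <- updateSigma(state$lp, state$muP, state$sigmaP, scales[data$P1 + 1])
  state$sigmaP <- up$sigma
  accepted[data$P1 + 1] <- up$accepted
  list(state = state, accepted = accepted)
}

initState <- function(data, chain) {
  ## overdispersed starts: chain-specific jitter around neutral values
  jit <- 0.25 * chain
  beta <- matrix(rnorm(data$M * data$P1, 0, jit + 0.1), data$M, data$P1)
  naiveP <- pmin(pmax(rowSums(data$y) / sum(data$n), 1e-3), 0.5)
  lp <- qlogis(naiveP) + rnorm(data$M, 0, jit + 0.1)
  z <- matrix(rbinom(data$M * data$I, 1L, 0.5), data$M, data$I)
  z[data$y > 0] <- 1L
  list(beta = beta, lp = lp, w = rep(1L, data$M), z = z, omega = 0.5,
       mu = rep(0, data$P1), sigma = rep(1, data$P1), muP = mean(qlogis(naiveP)),
       sigmaP = 1)
}

#' MCMC settings for the multi-species occupancy sampler
#'
#' Defaults mirror a long production run: 3 chains of 100,000 iterations,
#' 5,000 burn-in, thinning by 60. Reduced runs (e.g. \code{nIter = 20000},
#' \code{thin = 10}) reproduce posterior means within Monte-Carlo error and
#' are used throughout the package tests.
#'
#' @param nChains number of independent chains.
#' @param nIter iterations per chain.
#' @param burnIn initial iterations discarded (proposal scales adapt only
#'   here, then freeze to preserve detailed balance).
#' @param thin store every \code{thin}-th post-burn-in draw.
#' @param nAug number of all-zero augmented pseudo-species; \code{NULL} means
#'   "as many as there are observed species".
#' @param proposalScale initial random-walk scale for species parameters.
#' @param sigmaScale initial random-walk scale on log community sds.
#' @param adaptBatch adaptation batch length (iterations) during burn-in.
#' @return A named list of validated settings.
#' @export
msomControl <- function(nChains = 3, nIter = 100000, burnIn = 5000, thin = 60,
                        nAug = NULL, proposalScale = 0.3, sigmaScale = 0.3,
                        adaptBatch = 50) {
  if (nIter <= burnIn) stop("nIter must exceed burnIn")
  if (thin < 1) stop("thin must be >= 1")
  if (!is.null(nAug) && nAug < 0) stop("nAug must be >= 0")
  list(nChains = as.integer(nChains), nIter = as.integer(nIter),
       burnIn = as.integer(burnIn), thin = as.integer(thin), nAug = nAug,
       proposalScale = proposalScale, sigmaScale = sigmaScale,
       adaptBatch = as.integer(adaptBatch))
}

runChain <- function(data, cfg, chainSeed, chain) {
  set.seed(chainSeed)
  state <- initState(data, chain)
  nStore <- (cfg$nIter - cfg$burnIn) %/% cfg$thin
  P1 <- data$P1
  scalarNames <- c("omega", paste0("mu_", colnames(data$X1)),
                   paste0("sigma_", colnames(data$X1)), "mu_p", "sigma_p",
                   "N", "meanPsi", "meanP")
  out <- list(
    scalars = matrix(NA_real_, nStore, length(scalarNames),
                     dimnames = list(NULL, scalarNames)),
    beta = array(NA_real_, c(data$M, P1, nStore)),
    logitP = matrix(NA_real_, data$M, nStore),
    w = matrix(NA_integer_, data$M, nStore),
    siteN = matrix(NA_integer_, data$I, nStore))
  spScale <- rep(cfg$proposalScale, data$M)
  hyScale <- rep(cfg$sigmaScale, P1 + 1)
  spAcc <- rep(0, data$M); spTry <- rep(0, data$M)
  hyAcc <- rep(0, P1 + 1)
  spAccTot <- rep(0, data$M); spTryTot <- rep(0, data$M)
  s <- 0
  for (iter in seq_len(cfg$nIter)) {
    state <- updateZ(state, data)
    state <- updateW(state, data)
    state <- updateOmega(state, data)
    up <- updateSpeciesParams(state, data, spScale)
    state <- up$state
    tried <- !is.na(up$accepted)
    spAcc <- spAcc + ifelse(tried, up$accepted, 0)
    spTry <- spTry + tried
    hy <- updateHyperparams(state, data, hyScale)
    state <- hy$state
    hyAcc <- hyAcc + hy$accepted
    if (iter <= cfg$burnIn && iter %% cfg$adaptBatch == 0) {
      rate <- ifelse(spTry > 0, spAcc / spTry, 0.375)
      spScale <- spScale * exp(pmin(pmax(rate - 0.375, -0.25), 0.25))
      hrate <- hyAcc / cfg$adaptBatch
      hyScale <- hyScale * exp(pmin(pmax(hrate - 0.375, -0.25), 0.25))
      spAcc[] <- 0; spTry[] <- 0; hyAcc[] <- 0
    }
    if (iter > cfg$burnIn) {
      spAccTot <- spAccTot + ifelse(tried, up$accepted, 0)
      spTryTot <- spTryTot + tried
      if ((iter - cfg$burnIn) %% cfg$thin == 0) {
        s <- s + 1
        psi <- psiMatrix(state$beta, data$X1)
        inc <- state$w == 1
        out$scalars[s, ] <- c(state$omega, state$mu, state$sigma, state$muP,
                              state$sigmaP, sum(state$w),
                              mean(rowMeans(psi)[inc]),
                              mean(plogis(state$lp)[inc]))
        out$beta[, , s] <- state$beta
        out$logitP[, s] <- state$lp
        out$w[, s] <- state$w
        out$siteN[, s] <- colSums(state$z * state$w)
      }
    }
  }
  tr <- spTryTot > 0
  out$acceptance <- if (any(tr)) mean(spAccTot[tr] / spTryTot[tr]) else NA_real_
  out
}

#' Fit the data-augmented multi-species occupancy model
#'
#' Fits the Bayesian hierarchical community occupancy model by
#' Metropolis-within-Gibbs sampling. The ecological process is
#' z_ik ~ Bernoulli(psi_ik) with logit(psi_ik) = beta_0k + sum_m beta_mk X_mi;
#' the observation process is y_ik ~ Binomial(n_i, p_k z_ik w_k) with a
#' species-constant detection probability p_k; never-detected species are
#' accommodated by augmenting the detection matrix with all-zero rows whose
#' inclusion indicators w_k ~ Bernoulli(Omega) drive the richness estimate
#' N = sum_k w_k. Species coefficients and logit(p_k) are pooled through
#' community normal distributions with Normal(0, 10^2) hyperpriors on the
#' means and Uniform(0, 5) on the sds; Omega ~ Beta(1, 1).
#'
#' Latent z and (for augmented species) w have exact full-conditional draws
#' (w is updated with z collapsed out to avoid absorbing states); Omega is
#' conjugate; species and sd parameters move by adaptive random-walk
#' Metropolis (adaptation during burn-in only).
#'
#' @param history a \linkS4class{DetectionHistory} of observed species.
#' @param design optional standardized site covariate matrix (sites x
#'   covariates, e.g. from \code{\link{buildDesignMatrix}}); \code{NULL} fits
#'   an intercept-only occupancy model.
#' @param control sampler settings from \code{\link{msomControl}}.
#' @param seed single integer; all chain sub-seeds derive from it, so runs are
#'   bit-reproducible.
#' @return A \linkS4class{MsomSamples} object.
#' @examples
#' dh <- exampleDetectionHistory()
#' fit <- fitMsom(dh, control = msomControl(nChains = 2, nIter = 400,
#'                                          burnIn = 100, thin = 2), seed = 1)
#' deriveRichness(fit)
#' @export
fitMsom <- function(history, design = NULL, control = msomControl(), seed = 1) {
  y <- detections(history)
  n <- effort(history)
  if (!is.null(design)) {
    design <- as.matrix(design)
    if (nrow(design) != ncol(y))
      stop("design must have one row per site")
  }
  nAug <- if (is.null(control$nAug)) nrow(y) else as.integer(control$nAug)
  data <- msomData(y, unname(n), design, nAug)
  set.seed(seed)
  chainSeeds <- sample.int(.Machine$integer.max - 1L, control$nChains)
  chains <- lapply(seq_len(control$nChains), function(ch)
    runChain(data, control, chainSeeds[ch], ch))
  nStore <- nrow(chains[[1]]$scalars)
  scalarNames <- colnames(chains[[1]]$scalars)
  scalars <- array(NA_real_, c(nStore, control$nChains, length(scalarNames)),
                   dimnames = list(NULL, NULL, scalarNames))
  beta <- array(NA_real_, c(data$M, data$P1, nStore, control$nChains))
  logitP <- array(NA_real_, c(data$M, nStore, control$nChains))
  w <- array(NA_integer_, c(data$M, nStore, control$nChains))
  siteN <- array(NA_integer_, c(data$I, nStore, control$nChains))
  for (ch in seq_len(control$nChains)) {
    scalars[, ch, ] <- chains[[ch]]$scalars
    beta[, , , ch] <- chains[[ch]]$beta
    logitP[, , ch] <- chains[[ch]]$logitP
    w[, , ch] <- chains[[ch]]$w
    siteN[, , ch] <- chains[[ch]]$siteN
  }
  new("MsomSamples", scalars = scalars, beta = beta, logitP = logitP, w = w,
      siteN = siteN, species = rownames(data$y), sites = colnames(y),
      nObserved = data$K, coefNames = colnames(data$X1),
      acceptance = list(species = vapply(chains, `[[`, numeric(1),
                                         "acceptance")),
      config = control)
}

#' Pooled species-richness draws
#'
#' @param samples a \linkS4class{MsomSamples}.
#' @return Integer vector of per-draw N = sum_k w_k, pooled over chains.
#' @export
richnessDraws <- function(samples) as.vector(samples@scalars[, , "N"])

#' Posterior summary of community species richness
#'
#' @param samples a \linkS4class{MsomSamples}.
#' @return data.frame with the posterior mean, sd and 2.5/50/97.5 percentiles
#'   of N.
#' @examples
#' # deriveRichness(fitMsom(exampleDetectionHistory()))
#' @export
deriveRichness <- function(samples) {
  summariseDraws(richnessDraws(samples), "N")
}

summariseDraws <- function(x, name) {
  q <- quantile(x, c(0.025, 0.5, 0.975), names = FALSE, type = 7)
  data.frame(parameter = name, mean = mean(x), sd = sd(x),
             q2.5 = q[1], median = q[2], q97.5 = q[3], row.names = NULL)
}

#' Gelman-Rubin potential scale reduction factor
#'
#' Classic (unsplit) diagnostic: with W the mean within-chain variance and
#' B/n the variance of chain means, Vhat = (n-1)/n W + B/n and
#' Rhat = sqrt(Vhat / W). Values near 1 indicate between-chain agreement;
#' the conventional warning threshold is 1.1.
#'
#' @param draws numeric matrix, iterations x chains (>= 2 chains, >= 2
#'   iterations).
#' @return Rhat, or \code{NA} when the within-chain variance is zero.
#' @examples
#' gelmanRubin(cbind(c(1, 2, 3), c(1, 2, 3)))  # sqrt(2/3)
#' @export
gelmanRubin <- function(draws) {
  draws <- as.matrix(draws)
  if (ncol(draws) < 2 || nrow(draws) < 2)
    stop("need at least 2 chains of at least 2 draws")
  n <- nrow(draws)
  W <- mean(apply(draws, 2, var))
  Bn <- var(colMeans(draws))
  if (W == 0) return(NA_real_)
  sqrt(((n - 1) / n * W + Bn) / W)
}

#' Posterior summary table of scalar model parameters
#'
#' Mean, sd, percentile credible interval and Gelman-Rubin Rhat for Omega, the
#' community hyperparameters, derived richness N and the community mean
#' occupancy and detection probabilities.
#'
#' @param samples a \linkS4class{MsomSamples}.
#' @return data.frame, one row per scalar parameter.
#' @export
msomSummary <- function(samples) {
  nm <- dimnames(samples@scalars)[[3]]
  out <- do.call(rbind, lapply(nm, function(p)
    summariseDraws(as.vector(samples@scalars[, , p]), p)))
  out$rhat <- vapply(nm, function(p)
    if (dim(samples@scalars)[2] >= 2) gelmanRubin(samples@scalars[, , p])
    else NA_real_, numeric(1))
  out
}

#' Species-level posterior summaries
#'
#' Per-species posterior means and credible intervals for the detection
#' probability p_k and (averaged over sites) occupancy probability, alongside
#' the naive estimates — the model-based analogue of a survey's
#' species-by-species occupancy table.
#'
#' @param samples a \linkS4class{MsomSamples}.
#' @param design the covariate matrix used in the fit (or \code{NULL}).
#' @param observedOnly drop augmented pseudo-species rows (default TRUE).
#' @return data.frame with species, p and psi summaries.
#' @export
speciesSummary <- function(samples, design = NULL, observedOnly = TRUE) {
  M <- length(samples@species)
  keep <- if (observedOnly) seq_len(samples@nObserved) else seq_len(M)
  X1 <- cbind(1, if (is.null(design)) matrix(numeric(0), 1, 0) else design)
  pDraws <- plogis(samples@logitP)
  rows <- lapply(keep, function(k) {
    p <- as.vector(pDraws[k, , ])
    nd <- dim(samples@beta)[3] * dim(samples@beta)[4]
    bk <- matrix(samples@beta[k, , , ], nrow = dim(samples@beta)[2])
    psi <- colMeans(plogis(X1 %*% bk))
    data.frame(species = samples@species[k],
               p = mean(p), pLow = quantile(p, 0.025, names = FALSE),
               pHigh = quantile(p, 0.975, names = FALSE),
               psi = mean(psi), psiLow = quantile(psi, 0.025, names = FALSE),
               psiHigh = quantile(psi, 0.975, names = FALSE))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
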
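test_that("logit-link occupancy probability evaluates correctly", {
  expect_equal(occupancyProb(0), 0.5)
  expect_equal(occupancyProb(c(1, 2), 0.5), 1 / (1 + exp(-2)))
  expect_equal(occupancyProb(50), 1, tolerance = 1e-12)  # saturation
  expect_error(occupancyProb(c(1, 2), c(0.5, 0.2)), "intercept")
})

test_that("observation log-likelihood handles presence and absence", {
  expect_equal(obsLoglik(0, 5, 0.3, z = 0), 0)
  expect_equal(obsLoglik(3, 5, 0.3, z = 0), -Inf)
  expect_equal(obsLoglik(1, 2, 0.5, z = 1), log(0.5))
  expect_error(obsLoglik(6, 5, 0.3, 1), "\\[0, n\\]")
})

test_that("presence conditional reproduces the two-hypothesis Bayes weight", {
  # psi = 0.5, p = 0.5, n = 2, y = 0: 0.125 / 0.625 = 0.2
  expect_equal(zConditionalProb(0.5, 0.5, 2, 0, w = 1), 0.2)
  expect_equal(zConditionalProb(0.7, 0.1, 3, 2, w = 1), 1)  # detection forces z
  expect_equal(zConditionalProb(0, 0.5, 2, 0, w = 1), 0)
  expect_equal(zConditionalProb(0.37, 0.5, 2, 0, w = 0), 0.37)  # prior draw
  expect_error(zConditionalProb(0.5, 0.5, 2, 3, w = 0), "invalid state")
  # p fixed at 1: posterior presence equals observed presence exactly
  expect_equal(zConditionalProb(c(0.9, 0.9), 1, c(3, 3), c(0, 2)), c(0, 1))
})

test_that("collapsed inclusion conditional matches the plug-in formula", {
  # one site, psi = 1, p = 0.5, n = 1: L1 = 0.5, P(w=1) = 0.25/0.75 = 1/3
  expect_equal(wConditionalProb(1, 0.5, 1, omega = 0.5), 1 / 3)
  # undetectable species carries no data: P(w=1) = omega
  expect_equal(wConditionalProb(c(0.3, 0.8), 0, c(5, 7), omega = 0.41), 0.41)
})

test_that("full conditionals match exhaustive joint-posterior enumeration", {
  set.seed(101)
  for (rep in 1:40) {
    M <- sample(1:3, 1); I <- sample(1:3, 1)
    n <- sample(1:2, I, replace = TRUE)
    psi <- matrix(runif(M * I, 0.05, 0.95), M, I)
    p <- runif(M, 0.05, 0.95)
    omega <- runif(1, 0.1, 0.9)
    w <- rbinom(M, 1, 0.6)
    z <- matrix(rbinom(M * I, 1, 0.5), M, I)
    y <- matrix(0L, M, I)
    det <- w == 1
    y[det, ] <- rbinom(sum(det) * I, rep(n, each = sum(det)),
                       (p[det] * z[det, , drop = FALSE]))
    z[y > 0] <- 1L   # consistency
    for (k in seq_len(M)) for (i in seq_len(I)) {
      expect_equal(zConditionalProb(psi[k, i], p[k], n[i], y[k, i], w[k]),
                   oracleZProb(k, i, z, w, y, n, psi, p, omega),
                   tolerance = 1e-10)
    }
    for (k in which(rowSums(y) == 0)) {
      expect_equal(wConditionalProb(psi[k, ], p[k], n, omega),
                   oracleWProb(k, z, w, y, n, psi, p, omega),
                   tolerance = 1e-10)
    }
    # omega conditional: Beta(1 + sum w, 1 + M - sum w) density ratios match
    # the unnormalized prior x Bernoulli likelihood exactly
    a <- 1 + sum(w); b <- 1 + M - sum(w)
    pts <- c(0.2, 0.4, 0.6, 0.8)
    lhs <- dbeta(pts, a, b, log = TRUE) - dbeta(0.5, a, b, log = TRUE)
    rhs <- (sum(w) * log(pts) + (M - sum(w)) * log(1 - pts)) -
      (sum(w) * log(0.5) + (M - sum(w)) * log(0.5))
    expect_equal(lhs, rhs, tolerance = 1e-10)
  }
})

test_that("omega Gibbs draw has the conjugate Beta moments", {
  set.seed(7)
  state <- list(w = c(rep(1L, 26), rep(0L, 16)), omega = 0.5)
  data <- list(M = 42L)
  draws <- replicate(20000, camtrapMSOM:::updateOmega(state, data)$omega)
  m <- (1 + 26) / (2 + 42)
  v <- (27 * 17) / (44^2 * 45)
  expect_lt(abs(mean(draws) - m), 3 * sqrt(v / 20000))
})

test_that("Metropolis species update targets its grid-integration posterior", {
  # 1 species, 2 sites, fixed z and hyperparameters: sampled beta0 must match
  # the numerically integrated conditional (KS distance < 0.05 at 20k draws)
  y <- matrix(c(1L, 0L), 1, 2)
  n <- c(2L, 2L)
  data <- camtrapMSOM:::msomData(
    structure(y, dimnames = list("sp1", c("S1", "S2"))), n, NULL, nAug = 0)
  z <- matrix(c(1L, 0L), 1, 2)
  state <- list(beta = matrix(0, 1, 1), lp = -1, w = 1L, z = z, omega = 0.5,
                mu = 0, sigma = 1.5, muP = -1, sigmaP = 1)
  set.seed(55)
  draws <- numeric(20000)
  for (s in seq_len(20000)) {
    up <- camtrapMSOM:::updateSpeciesParams(state, data, scales = 1.2)
    state <- up$state
    draws[s] <- state$beta[1, 1]
  }
  grid <- expand.grid(b = seq(-8, 8, by = 0.02), l = seq(-9, 5, by = 0.02))
  lp <- with(grid, {
    psi1 <- plogis(b); p <- plogis(l)
    (log(psi1) + dbinom(1, 2, p, log = TRUE)) +    # site 1, z=1, y=1
      log(1 - psi1) +                              # site 2, z=0, y=0
      dnorm(b, 0, 1.5, log = TRUE) + dnorm(l, -1, 1, log = TRUE)
  })
  wgt <- exp(lp - max(lp))
  bGrid <- sort(unique(grid$b))
  marg <- tapply(wgt, grid$b, sum)
  cdf <- cumsum(marg) / sum(marg)
  ks <- max(abs(ecdf(draws)(bGrid) - cdf))
  expect_lt(ks, 0.05)
})

test_that("hyperparameter updates follow normal-normal conjugacy and the sigma prior", {
  # prior N(0, 10^2), 4 values with mean 1, sigma = 1:
  # posterior mean 400/401, variance 100/401
  set.seed(12)
  draws <- replicate(20000, camtrapMSOM:::conjNormalMean(rep(1, 4), 1))
  expect_lt(abs(mean(draws) - 400 / 401), 3 * sqrt(100 / 401 / 20000))
  expect_lt(abs(var(draws) - 100 / 401), 3 * (100 / 401) * sqrt(2 / 20000))
  # sigma proposals outside (0, 5) are always rejected
  set.seed(13)
  for (i in 1:50) {
    up <- camtrapMSOM:::updateSigma(rnorm(5), 0, sigma = 4.99, scale = 3)
    expect_true(up$sigma <= 4.99 || !up$accepted)
    expect_lt(up$sigma, 5)
  }
})

test_that("degenerate community concentrates the mean at the shared value", {
  set.seed(14)
  draws <- replicate(2000, camtrapMSOM:::conjNormalMean(rep(2.5, 30), 0.01))
  expect_equal(mean(draws), 2.5, tolerance = 1e-3)
})
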
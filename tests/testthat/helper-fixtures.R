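# shared fixtures and independent oracles for the test suite

ts_ <- function(...) as.POSIXct(c(...), tz = "UTC")

toyRecords <- function() {
  makeRecordTable(
    site = c("S1", "S1", "S1", "S2", "S1", "S1"),
    kind = c("wildlife", "wildlife", "wildlife", "wildlife", "human", "blank"),
    species = c("deer", "deer", "civet", "deer", NA, NA),
    timestamp = ts_("2017-01-02 08:00:00", "2017-01-02 08:30:00",
                    "2017-01-02 09:00:00", "2017-01-03 10:00:00",
                    "2017-01-04 12:00:00", "2017-01-05 12:00:00"))
}

toyDeployments <- function() {
  data.frame(site = c("S1", "S2"), x = c(0, 1000), y = c(0, 1000),
             start = as.Date(c("2017-01-01", "2017-01-01")),
             end = as.Date(c("2017-03-15", "2017-03-20")))
}

# joint log-probability of the augmented community model at fixed parameters:
# w_k ~ Bern(omega), z_ik ~ Bern(psi_ik), y_ik ~ Binomial(n_i, p_k z_ik w_k)
jointLogProb <- function(z, w, y, n, psi, p, omega) {
  M <- nrow(y); I <- ncol(y)
  lw <- sum(w * log(omega) + (1 - w) * log(1 - omega))
  lz <- sum(z * log(psi) + (1 - z) * log(1 - psi))
  pr <- (p * w)[row(y)] * z
  ly <- sum(dbinom(y, rep(n, each = M), pr, log = TRUE))
  lw + lz + ly
}

# brute-force conditional P(z_ik = 1 | everything else) from the joint
oracleZProb <- function(k, i, z, w, y, n, psi, p, omega) {
  z1 <- z; z1[k, i] <- 1
  z0 <- z; z0[k, i] <- 0
  l1 <- jointLogProb(z1, w, y, n, psi, p, omega)
  l0 <- jointLogProb(z0, w, y, n, psi, p, omega)
  1 / (1 + exp(l0 - l1))
}

# brute-force collapsed conditional P(w_k = 1 | y, z_{-k}, params): the k-th
# z row is summed out over all 2^I configurations
oracleWProb <- function(k, z, w, y, n, psi, p, omega) {
  I <- ncol(y)
  configs <- as.matrix(expand.grid(rep(list(0:1), I)))
  mass <- function(wk) {
    wTry <- w; wTry[k] <- wk
    sum(apply(configs, 1, function(zk) {
      zTry <- z; zTry[k, ] <- zk
      exp(jointLogProb(zTry, wTry, y, n, psi, p, omega))
    }))
  }
  m1 <- mass(1)
  m1 / (m1 + mass(0))
}

# small deterministic simulated survey shared by several tests
smallSim <- function(seed = 11, I = 12, nTrue = 10) {
  simulateCommunity(I = I, nTrue = nTrue,
                    hyper = msomHyper(meanPsi = 0.4, meanP = 0.15),
                    effort = rep(20L, I), seed = seed)
}

quickControl <- function(nChains = 2, nIter = 1200, burnIn = 400, thin = 4,
                         nAug = NULL)
  msomControl(nChains, nIter, burnIn, thin, nAug)
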
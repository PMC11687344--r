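# Independent oracles and fixture builders shared across the suite.

# Marginal likelihood by exhaustive enumeration over all 2^K latent
# occupancy sequences (the forward recursion must reproduce this exactly).
bruteLoglik <- function(v, obs, psi1, gamma, phi, p) {
  K <- nrow(v)
  tot <- 0
  for (zint in 0:(2^K - 1)) {
    z <- as.integer(intToBits(zint)[1:K])
    pr <- if (z[1] == 1) psi1 else 1 - psi1
    if (K > 1) for (k in 2:K) {
      pr <- pr * if (z[k - 1] == 1) {
        if (z[k] == 1) phi[k] else 1 - phi[k]
      } else {
        if (z[k] == 1) gamma[k] else 1 - gamma[k]
      }
    }
    for (k in 1:K) for (l in which(obs[k, ])) {
      pr <- pr * if (z[k] == 1) {
        if (v[k, l] == 1) p[k, l] else 1 - p[k, l]
      } else {
        if (v[k, l] == 1) 0 else 1
      }
    }
    tot <- tot + pr
  }
  log(tot)
}

# Minimum Kullback-Leibler d over all integer allocations of ai units to
# the genera of q, by exhaustive enumeration (compositions of ai).
bruteDMin <- function(ai, q) {
  G <- length(q)
  best <- Inf
  recurse <- function(alloc, left, g) {
    if (g == G) {
      alloc[G] <- left
      use <- alloc > 0
      p <- alloc[use] / ai
      best <<- min(best, sum(p * log(p / q[use])))
      return(invisible())
    }
    for (a in 0:left) recurse(`[<-`(alloc, g, a), left - a, g + 1)
  }
  recurse(integer(G), ai, 1)
  best
}

# Interaction network straight from a labelled count matrix.
netFromMatrix <- function(A) {
  if (is.null(rownames(A))) rownames(A) <- paste0("s", seq_len(nrow(A)))
  if (is.null(colnames(A))) colnames(A) <- paste0("g", seq_len(ncol(A)))
  interactionNetwork(data.frame(
    pollinator_species = rownames(A)[row(A)[A > 0]],
    plant_genus = colnames(A)[col(A)[A > 0]],
    count = A[A > 0]))
}

# Random small interaction network (counts guaranteed non-degenerate).
randomNetwork <- function(nSpecies = 6, nGenera = 4, maxCount = 8) {
  repeat {
    A <- matrix(rpois(nSpecies * nGenera, 1.2), nSpecies, nGenera)
    A[sample(length(A), 2)] <- sample(maxCount, 2)
    if (all(rowSums(A) > 0) && all(colSums(A) > 0)) break
  }
  rownames(A) <- paste0("s", seq_len(nSpecies))
  colnames(A) <- paste0("g", seq_len(nGenera))
  netFromMatrix(A)
}

# Random detection-history fixture: probabilities plus a history.
randomHistory <- function(K, L) {
  list(v = matrix(rbinom(K * L, 1, 0.4), K, L),
       obs = matrix(runif(K * L) < 0.85, K, L),
       psi1 = runif(1, 0.05, 0.95),
       gamma = runif(K, 0.05, 0.95),
       phi = runif(K, 0.05, 0.95),
       p = matrix(runif(K * L, 0.05, 0.95), K, L))
}

# Tiny synthetic study used by several fit tests.
smallSim <- function(seed = 7, nSpecies = 8, nSites = 6, nYears = 2,
                     nSurveys = 3, ...) {
  cfg <- simConfig(seed = seed, nSpecies = nSpecies, nSites = nSites,
                   nRestored = floor(nSites / 2), nYears = nYears,
                   nSurveys = nSurveys, ...)
  truth <- generateTruth(cfg)
  det <- generateDetections(truth, cfg)
  list(cfg = cfg, truth = truth, det = det)
}

# Build an OccupancyFit holding a single known parameter set, so the
# projection machinery can be exercised against analytic oracles.
fitFromParams <- function(params, covs, dims, nDraws = 1) {
  dims <- stats::setNames(as.integer(dims), names(dims))
  nms <- metaoccu:::.paramNames(names(covs@dPrime), dims[["K"]], "community")
  row <- stats::setNames(numeric(length(nms)), nms)
  sp <- names(covs@dPrime)
  K <- dims[["K"]]
  # the fitted parameterisation pins transition offsets at year 2, so the
  # year-2 offset of the truth is absorbed into the intercepts
  gOff <- if (K > 1) params$gamma_year[2] else 0
  fOff <- if (K > 1) params$phi_year[2] else 0
  row[paste0("psi1_0[", sp, "]")] <- params$psi1_0
  row[paste0("gamma_0[", sp, "]")] <- params$gamma_0 + gOff
  row[paste0("phi_0[", sp, "]")] <- params$phi_0 + fOff
  row[paste0("p_0[", sp, "]")] <- params$p_0
  row[paste0("p_2[", sp, "]")] <- params$p_2
  row[paste0("p_3[", sp, "]")] <- params$p_3
  row[paste0("psi1_", 1:5)] <- params$psi1
  row[paste0("gamma_", 1:5)] <- params$gamma
  row[paste0("phi_", 1:5)] <- params$phi
  row["p_1"] <- params$p_1; row["p_4"] <- params$p_4
  if (K > 2) {
    row[paste0("gamma_6[", 3:K, "]")] <- params$gamma_year[3:K] - gOff
    row[paste0("phi_6[", 3:K, "]")] <- params$phi_year[3:K] - fOff
  }
  if (K > 1) row[paste0("p_5[", 2:K, "]")] <- params$p_5[2:K]
  draws <- matrix(rep(row, each = nDraws), nDraws, length(nms),
                  dimnames = list(NULL, nms))
  new("OccupancyFit", draws = draws, chain = rep(1L, nDraws),
      report = fitReport(1, 1, 0L), covariates = covs, dims = dims,
      variant = "community", config = list())
}

# Covariate bundle with prescribed (standardised) values, bypassing
# re-standardisation: species/site covariates exactly as given.
directCovs <- function(dPrime, degree, restored, woody) {
  S <- length(dPrime); J <- length(restored)
  sp <- sprintf("sp%02d", seq_len(S)); st <- sprintf("site%02d", seq_len(J))
  new("CovariateBundle",
      dPrime = stats::setNames(dPrime, sp),
      degree = stats::setNames(degree, sp),
      restored = stats::setNames(restored, st),
      woody = matrix(woody, J, length(woody) / J,
                     dimnames = list(st, NULL)),
      standardizers = list())
}
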
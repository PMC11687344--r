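#' Weakly-informative prior settings for the occupancy model
#'
#' All parameters live on the logit scale, where values beyond a few units
#' already correspond to near-0/near-1 probabilities, so unit-scale normal
#' priors are weakly informative and mainly discourage unrealistic values:
#' community slopes and hypermeans Normal(0, 2); hierarchical (species)
#' standard deviations half-Normal(0, 1.5); year offsets Normal(0, 2).
#'
#' @param slope_sd,hypermean_sd,hypersd_scale,year_sd positive scalars.
#' @return named list of prior scales.
#' @export
occuPriors <- function(slope_sd = 2, hypermean_sd = 2, hypersd_scale = 1.5,
                       year_sd = 2) {
  stopifnot(slope_sd > 0, hypermean_sd > 0, hypersd_scale > 0, year_sd > 0)
  list(slope_sd = slope_sd, hypermean_sd = hypermean_sd,
       hypersd_scale = hypersd_scale, year_sd = year_sd)
}

#' Build a convergence report
#'
#' Applies the convergence gates: `converged` is `TRUE` exactly when
#' `maxRhat < 1.05`, `minEssRatio > 0.1` and `nDivergent == 0`.
#'
#' @param maxRhat largest split R-hat over monitored parameters.
#' @param minEssRatio smallest effective sample size divided by stored
#'   steps.
#' @param nDivergent number of divergent transitions (0 for the
#'   random-walk sampler used here).
#' @return a [FitReport-class].
#' @export
fitReport <- function(maxRhat, minEssRatio, nDivergent = 0L) {
  conv <- maxRhat < 1.05 && minEssRatio > 0.1 && nDivergent == 0L
  new("FitReport", converged = conv, maxRhat = as.numeric(maxRhat),
      minEssRatio = as.numeric(minEssRatio),
      nDivergent = as.integer(nDivergent))
}

# split R-hat and ESS ratio via coda, pooling chains
.mcmcDiagnostics <- function(chainList) {
  nkept <- nrow(chainList[[1]])
  half <- floor(nkept / 2)
  splits <- list()
  for (ch in chainList) {
    splits <- c(splits, list(ch[seq_len(half), , drop = FALSE],
                             ch[(half + 1):(2 * half), , drop = FALSE]))
  }
  pooled <- do.call(rbind, chainList)
  sds <- apply(pooled, 2, stats::sd)
  varying <- which(sds > 1e-10)
  rhat <- rep(1, ncol(pooled))
  if (length(varying)) {
    ml <- coda::mcmc.list(lapply(splits, function(m)
      coda::mcmc(m[, varying, drop = FALSE])))
    gd <- coda::gelman.diag(ml, autoburnin = FALSE, multivariate = FALSE)
    rhat[varying] <- gd$psrf[, 1]
  }
  ess <- rep(nkept * length(chainList), ncol(pooled))
  if (length(varying)) {
    essV <- Reduce(`+`, lapply(chainList, function(m)
      as.numeric(coda::effectiveSize(m[, varying, drop = FALSE]))))
    ess[varying] <- essV
  }
  list(maxRhat = max(rhat, na.rm = TRUE),
       minEssRatio = min(ess, na.rm = TRUE) / (nkept * length(chainList)),
       rhat = rhat, ess = ess)
}

# parameter names in the canonical storage order of the compiled sampler
.paramNames <- function(species, K, variant) {
  spBlocks <- c("psi1_0", "gamma_0", "phi_0", "p_0", "p_2", "p_3")
  slBlocks <- c("b_psi1_r", "b_psi1_w", "b_gamma_r", "b_gamma_w",
                "b_phi_r", "b_phi_w")
  commAll <- c(paste0("psi1_", 1:5), paste0("gamma_", 1:5),
               paste0("phi_", 1:5), "p_1", "p_4")
  hyp <- c(paste0("mu_", spBlocks), paste0("sigma_", spBlocks))
  # transition-year offsets are pinned at the first transition (year 2);
  # the detection offset at year 1
  yrT <- function(nm) if (K > 2) paste0(nm, "[", 3:K, "]") else character()
  yrD <- function(nm) if (K > 1) paste0(nm, "[", 2:K, "]") else character()
  blk <- function(nms) as.vector(t(outer(nms, species,
                                         function(a, b) paste0(a, "[", b, "]"))))
  if (variant == "community") {
    c(blk(spBlocks), commAll, yrT("gamma_6"), yrT("phi_6"), yrD("p_5"), hyp)
  } else {
    c(blk(spBlocks), blk(slBlocks), "p_1", "p_4",
      yrT("gamma_6"), yrT("phi_6"), yrD("p_5"), hyp,
      paste0("mu_", slBlocks), paste0("sigma_", slBlocks))
  }
}

.randomInit <- function(S, K, rs) {
  yrT <- numeric(K)  # offsets pinned through the first transition year
  if (K > 2) yrT[3:K] <- stats::rnorm(K - 2, 0, 0.1)
  yrD <- numeric(K)
  if (K > 1) yrD[2:K] <- stats::rnorm(K - 1, 0, 0.1)
  init <- list(
    sp = matrix(stats::rnorm(6 * S, 0, 0.5), S, 6),
    comm = stats::rnorm(17, 0, 0.25),
    gamma_year = yrT,
    phi_year = if (K > 2) replace(numeric(K), 3:K, stats::rnorm(K - 2, 0, 0.1)) else numeric(K),
    p_year = yrD,
    hyper_mu = stats::rnorm(6, 0, 0.5),
    hyper_sigma = stats::runif(6, 0.5, 1.5))
  if (rs) {
    init$slope <- matrix(stats::rnorm(6 * S, 0, 0.25), S, 6)
    init$slope_mu <- stats::rnorm(6, 0, 0.25)
    init$slope_sigma <- stats::runif(6, 0.25, 1)
  }
  init
}

#' Fit the multi-species dynamic occupancy model
#'
#' Samples the posterior of the hierarchical dynamic occupancy model by
#' adaptive Markov chain Monte Carlo on the marginalised likelihood (latent
#' occurrence states are summed out by a forward recursion, never sampled).
#' Species-level parameters are updated with scalar random-walk Metropolis
#' steps touching only that species' likelihood slice; community slopes and
#' year offsets with full-likelihood steps; hypermeans by conjugate Gibbs
#' draws; hierarchical standard deviations on the log scale. Proposal
#' scales adapt toward a 0.44 acceptance rate during warmup and are then
#' frozen.
#'
#' The default run length follows the convention of 4000 iterations with
#' the first half discarded. Convergence is gated on split R-hat < 1.05,
#' ESS ratio > 0.1 and zero divergences; a non-converged fit is still
#' returned, flagged, with a warning.
#'
#' @param darr a [DetectionArray-class].
#' @param covs a [CovariateBundle-class] (aligned to `darr` by id).
#' @param priors prior scales from [occuPriors()].
#' @param iterations,warmup,chains sampler configuration.
#' @param seed integer; every chain derives its RNG stream from it.
#' @param variant `"community"` for the d'-based core model or
#'   `"randomSlopes"` for species-specific ecological slopes (the
#'   a-posteriori variant; see [slopeCorrelations()]).
#' @return an [OccupancyFit-class].
#' @export
fitOccupancy <- function(darr, covs, priors = occuPriors(),
                         iterations = 4000, warmup = floor(iterations / 2),
                         chains = 3, seed = 1,
                         variant = c("community", "randomSlopes")) {
  variant <- match.arg(variant)
  stopifnot(iterations > warmup, warmup >= 0, chains >= 1)
  covs <- .alignCovariates(covs, darr)
  rs <- variant == "randomSlopes"
  S <- nSpecies(darr); K <- nYears(darr)
  maskInt <- array(as.integer(darr@mask), dim(darr@mask))
  woody <- covs@woody[, seq_len(K), drop = FALSE]

  chainDraws <- vector("list", chains)
  for (ch in seq_len(chains)) {
    set.seed((seed + 7919L * (ch - 1L)) %% .Machine$integer.max)
    init <- .randomInit(S, K, rs)
    res <- runOccuChainCpp(darr@V, maskInt, covs@restored, woody,
                           as.numeric(darr@date), as.numeric(darr@flowers),
                           covs@dPrime, covs@degree,
                           as.integer(dim(darr@V)), init, priors,
                           as.integer(iterations), as.integer(warmup), rs)
    chainDraws[[ch]] <- res$draws
  }
  nms <- .paramNames(speciesIds(darr), K, variant)
  for (ch in seq_len(chains)) colnames(chainDraws[[ch]]) <- nms

  diag <- .mcmcDiagnostics(chainDraws)
  report <- fitReport(diag$maxRhat, diag$minEssRatio, 0L)
  if (!report@converged)
    warning(sprintf("fit did not pass convergence gates (max R-hat %.3f, min ESS ratio %.3f)",
                    diag$maxRhat, diag$minEssRatio))

  new("OccupancyFit",
      draws = do.call(rbind, chainDraws),
      chain = rep(seq_len(chains), each = iterations - warmup),
      report = report, covariates = covs,
      dims = c(S = S, J = nSites(darr), K = K, L = nSurveys(darr)),
      variant = variant,
      config = list(iterations = iterations, warmup = warmup,
                    chains = chains, seed = seed, priors = priors))
}

#' Summarise a vector or matrix of posterior draws
#'
#' Computes the posterior mean, central 50% and 95% credible intervals and
#' the certainty label used throughout: `"strong"` when the 95% BCI
#' excludes zero, `"marginal"` when only the 50% BCI does, `"none"`
#' otherwise.
#'
#' @param draws numeric matrix of draws (columns = parameters) or a vector.
#' @param pars optional character vector selecting columns.
#' @return data.frame with one row per parameter.
#' @export
summarizeDraws <- function(draws, pars = NULL) {
  if (is.null(dim(draws))) draws <- matrix(draws, ncol = 1,
                                           dimnames = list(NULL, "par"))
  if (!is.null(pars)) {
    bad <- setdiff(pars, colnames(draws))
    if (length(bad))
      stop("unknown parameter(s): ", paste(bad, collapse = ", "),
           "; available: ", paste(utils::head(colnames(draws), 30), collapse = ", "),
           if (ncol(draws) > 30) ", ..." else "")
    draws <- draws[, pars, drop = FALSE]
  }
  qs <- t(apply(draws, 2, stats::quantile, probs = c(0.025, 0.25, 0.75, 0.975)))
  lab <- function(l50, u50, l95, u95) {
    if (l95 > 0 || u95 < 0) "strong"
    else if (l50 > 0 || u50 < 0) "marginal"
    else "none"
  }
  data.frame(name = colnames(draws),
             mean = colMeans(draws),
             l50 = qs[, 2], u50 = qs[, 3], l95 = qs[, 1], u95 = qs[, 4],
             label = mapply(lab, qs[, 2], qs[, 3], qs[, 1], qs[, 4]),
             row.names = NULL)
}

#' @rdname summarizeFit
#' @export
setMethod("summarizeFit", "OccupancyFit", function(x, pars = NULL) {
  if (is.null(pars)) pars <- grep("\\[", colnames(x@draws), invert = TRUE,
                                  value = TRUE)
  summarizeDraws(x@draws, pars)
})

#' @rdname summarizeFit
#' @export
setMethod("summarizeFit", "PollenFit", function(x, pars = NULL) {
  if (is.null(pars)) pars <- c("mu_beta0", "sigma_beta0", "beta_1")
  summarizeDraws(x@draws, pars)
})

#' Correlation between specialisation and species-specific slopes
#'
#' For a `"randomSlopes"` fit, computes per posterior draw the Pearson
#' correlation between standardised d' and each vector of species-specific
#' ecological slopes (restoration and woody effects on initial occurrence,
#' colonisation and persistence), and summarises the resulting posterior
#' correlation distributions.
#'
#' @param fit an [OccupancyFit-class] fitted with `variant =
#'   "randomSlopes"`.
#' @return data.frame (one row per slope family) in the format of
#'   [summarizeDraws()].
#' @export
slopeCorrelations <- function(fit) {
  if (fit@variant != "randomSlopes")
    stop("slopeCorrelations requires a randomSlopes fit")
  dp <- fit@covariates@dPrime
  fams <- c("b_psi1_r", "b_psi1_w", "b_gamma_r", "b_gamma_w",
            "b_phi_r", "b_phi_w")
  cors <- sapply(fams, function(f) {
    cols <- paste0(f, "[", names(dp), "]")
    apply(fit@draws[, cols, drop = FALSE], 1,
          function(b) stats::cor(dp, b))
  })
  colnames(cors) <- paste0("cor_dprime_", fams)
  summarizeDraws(cors)
}
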
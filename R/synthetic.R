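#' Configuration for the synthetic-data generator
#'
#' Defaults reproduce the design shape of the field study the model is
#' built for — 18 urban parks (9 restored, 9 mowed controls), 3 years, 6
#' surveys per site-year, 108 pollinator species — and true community
#' effects with the direction and rough magnitude of that study's
#' estimates (strong positive restoration effect on initial occurrence,
#' positive woody and d' x woody effects on colonisation, mildly negative
#' woody effect on persistence), so the synthetic metacommunity re-tells
#' the same ecological story with known ground truth. The specialisation
#' distribution targets mean d' 0.29 (SD 0.13).
#'
#' Slot-by-slot, `effects` are the five community slopes per ecological
#' predictor (order d', restoration, woody, d' x restoration, d' x woody),
#' `hypers` the (mean, sd) of each species-intercept distribution on the
#' logit scale. Species phenology peaks are spread uniformly across the
#' standardised season with quadratic decay curvature drawn from
#' `hypers$p_3`, leaving a typical species detectable in roughly 2-4 of
#' the 6 surveys.
#'
#' Determinism: each sub-generator (site covariates, species parameters,
#' detections, network, pollen) derives its own fixed offset from `seed`
#' and uses R's default Mersenne-Twister stream, so e.g. changing the
#' species count does not shift the site covariates.
#'
#' @param seed integer master seed.
#' @param nSpecies,nSites,nRestored,nYears,nSurveys study dimensions.
#' @param effects list of length-5 slope vectors `psi1`, `gamma`, `phi`
#'   plus scalars `p_1`, `p_4`.
#' @param hypers list of `c(mean, sd)` for `psi1_0`, `gamma_0`, `phi_0`,
#'   `p_0`, `p_3` (the `p_2` values are induced by the uniform peaks).
#' @param yearSd sd of the yearly offsets on colonisation, persistence and
#'   detection (first year pinned at 0).
#' @param dPrimeMean,dPrimeSd target moments of the Beta-distributed
#'   specialisation scores.
#' @param missingRate fraction of site-year-surveys not conducted.
#' @param network list: `nGenera`, `meanLogInteractions`,
#'   `sdLogInteractions`, `availabilitySd` (log-normal spread of genus
#'   attractiveness).
#' @param pollen list: `thetaControl`, `thetaRestored`, `nRestoredSites`,
#'   `nControlSites`, `pairsPerSite`, `siteSd`, `exclusionRate`.
#' @return a validated config list.
#' @export
simConfig <- function(seed = 1,
                      nSpecies = 108, nSites = 18, nRestored = 9,
                      nYears = 3, nSurveys = 6,
                      effects = list(
                        psi1 = c(0.07, 2.26, -0.48, -0.21, -0.04),
                        gamma = c(-1.32, 1.02, 1.60, -0.11, 1.36),
                        phi = c(0.57, -0.30, -0.61, -0.42, -0.32),
                        p_1 = 0.98, p_4 = 0.41),
                      hypers = list(
                        psi1_0 = c(-1.5, 1.25), gamma_0 = c(-2, 1),
                        phi_0 = c(0.5, 1), p_0 = c(-1, 0.75),
                        p_3 = c(-1.25, 0.4)),
                      yearSd = 0.3,
                      dPrimeMean = 0.29, dPrimeSd = 0.13,
                      missingRate = 0,
                      network = list(nGenera = 25,
                                     meanLogInteractions = log(60),
                                     sdLogInteractions = 0.9,
                                     availabilitySd = 1),
                      pollen = list(thetaControl = 0.3, thetaRestored = 0.3,
                                    nRestoredSites = 6, nControlSites = 5,
                                    pairsPerSite = 16, siteSd = 0.5,
                                    exclusionRate = 0.1)) {
  stopifnot(nRestored <= nSites, nYears >= 1, nSurveys >= 1,
            missingRate >= 0, missingRate < 1,
            vapply(effects[c("psi1", "gamma", "phi")], length, 1L) == 5)
  .betaShapes(dPrimeMean, dPrimeSd)  # errors when infeasible
  list(seed = seed, nSpecies = nSpecies, nSites = nSites,
       nRestored = nRestored, nYears = nYears, nSurveys = nSurveys,
       effects = effects, hypers = hypers, yearSd = yearSd,
       dPrimeMean = dPrimeMean, dPrimeSd = dPrimeSd,
       missingRate = missingRate, network = network, pollen = pollen)
}

# method-of-moments Beta shapes; requires var < mean*(1-mean)
.betaShapes <- function(mean, sd) {
  v <- sd^2
  if (mean <= 0 || mean >= 1 || v <= 0 || v >= mean * (1 - mean))
    stop("infeasible Beta moments: need 0 < mean < 1 and sd^2 < mean*(1-mean)")
  nu <- mean * (1 - mean) / v - 1
  c(shape1 = mean * nu, shape2 = (1 - mean) * nu)
}

.padId <- function(prefix, i, n) sprintf("%s%0*d", prefix, nchar(n), i)

#' Draw the true parameters and covariates of a synthetic study
#'
#' Generates site covariates (restoration flags, survey dates, woody and
#' herbaceous floral counts), species traits (d' from the moment-matched
#' Beta distribution, log-normal degree) and a full set of true occupancy
#' parameters: species intercepts from the configured hyper-distributions,
#' community slopes as configured, uniform phenology peaks, and yearly
#' offsets. Covariates are standardised exactly as the ingest path would
#' standardise them, so the truth lives on the same scale the model is
#' fitted on.
#'
#' @param config a [simConfig()].
#' @return list with `params` ([occupancyParams()]), `covs`
#'   ([CovariateBundle-class]), `sites`, `scores`, `woody` data.frames,
#'   and `surveyFrame` (one row per site-year-survey with date and floral
#'   counts).
#' @export
generateTruth <- function(config) {
  S <- config$nSpecies; J <- config$nSites
  K <- config$nYears; L <- config$nSurveys

  set.seed(config$seed + 1L)  # covariate stream
  sites <- data.frame(site_id = .padId("site", seq_len(J), J),
                      restored = as.numeric(seq_len(J) <= config$nRestored))
  surveyFrame <- expand.grid(site_id = sites$site_id,
                             year_index = seq_len(K),
                             survey_index = seq_len(L),
                             stringsAsFactors = FALSE)
  surveyFrame <- surveyFrame[order(surveyFrame$site_id,
                                   surveyFrame$year_index,
                                   surveyFrame$survey_index), ]
  # six roughly even surveys across the May-mid-August activity window
  slots <- 121 + (surveyFrame$survey_index - 0.5) * (106 / L)
  surveyFrame$survey_date <- pmin(366, pmax(1, round(
    slots + stats::runif(nrow(surveyFrame), -5, 5))))
  # woody floral resources: site-level log-normal abundance, a fifth of
  # sites essentially without woody plants; negative-binomial survey counts
  lambda <- stats::rlnorm(J, meanlog = 4.5, sdlog = 1.2) *
    stats::rbinom(J, 1, 0.8)
  lamRow <- lambda[match(surveyFrame$site_id, sites$site_id)]
  surveyFrame$woody_floral_count <- ifelse(
    lamRow > 0, stats::rnbinom(nrow(surveyFrame), mu = lamRow, size = 2), 0L)
  # herbaceous flowers: restorations carry far more forbs than mowed lawns
  restRow <- sites$restored[match(surveyFrame$site_id, sites$site_id)]
  herbMu <- ifelse(restRow == 1, 250, 15)
  surveyFrame$herbaceous_floral_count <-
    stats::rnbinom(nrow(surveyFrame), mu = herbMu, size = 1.5)

  woody <- stats::aggregate(
    log1p(surveyFrame$woody_floral_count),
    by = list(site_id = surveyFrame$site_id,
              year_index = surveyFrame$year_index), FUN = mean)
  names(woody)[3] <- "woody"

  scores <- data.frame(
    species_id = .padId("sp", seq_len(S), S),
    d_prime = {
      sh <- .betaShapes(config$dPrimeMean, config$dPrimeSd)
      stats::rbeta(S, sh[1], sh[2])
    },
    degree = pmax(1, round(stats::rlnorm(S, log(5), 0.8))))
  covs <- covariateBundle(scores, sites, woody)

  set.seed(config$seed + 2L)  # species-parameter stream
  h <- config$hypers
  dateStd <- standardizeCovariate(surveyFrame$survey_date)$values
  peaks <- stats::runif(S, stats::quantile(dateStd, 0.1),
                        stats::quantile(dateStd, 0.9))
  p_3 <- -abs(stats::rnorm(S, -h$p_3[1], h$p_3[2]))
  params <- occupancyParams(
    psi1_0 = stats::rnorm(S, h$psi1_0[1], h$psi1_0[2]),
    psi1 = config$effects$psi1,
    gamma_0 = stats::rnorm(S, h$gamma_0[1], h$gamma_0[2]),
    gamma = config$effects$gamma,
    gamma_year = c(0, stats::rnorm(K - 1, 0, config$yearSd)),
    phi_0 = stats::rnorm(S, h$phi_0[1], h$phi_0[2]),
    phi = config$effects$phi,
    phi_year = c(0, stats::rnorm(K - 1, 0, config$yearSd)),
    p_0 = stats::rnorm(S, h$p_0[1], h$p_0[2]),
    p_1 = config$effects$p_1,
    p_2 = -2 * p_3 * peaks,  # vertex of the quadratic sits at the peak
    p_3 = p_3,
    p_4 = config$effects$p_4,
    p_5 = c(0, stats::rnorm(K - 1, 0, config$yearSd)))
  list(params = params, covs = covs, sites = sites, scores = scores,
       woody = woody, surveyFrame = surveyFrame)
}

#' Simulate detection histories from a synthetic truth
#'
#' Forward-simulates latent occurrence `Z` by the occupancy recursion and
#' survey detections `V` by the detection submodel, then passes the
#' resulting long-format records through [buildDetectionArray()] so the
#' output is exactly what ingest would produce (masked surveys, dropped
#' never-detected species and all). Capture counts for detected cells are
#' `1 + Poisson(0.7)`.
#'
#' @param truth output of [generateTruth()].
#' @param config the same [simConfig()].
#' @return list with `darr` (a [DetectionArray-class]), `records` (the
#'   long-format survey table), and — for tests only — the latent `Z`
#'   (species x site x year) and detection probabilities `p`.
#' @export
generateDetections <- function(truth, config) {
  S <- config$nSpecies; J <- config$nSites
  K <- config$nYears; L <- config$nSurveys
  params <- truth$params; covs <- truth$covs
  sf <- truth$surveyFrame

  set.seed(config$seed + 3L)  # detection stream
  keepSurvey <- stats::runif(nrow(sf)) >= config$missingRate
  sf <- sf[keepSurvey, , drop = FALSE]

  # standardised survey covariates over conducted surveys, as ingest does
  cell <- cbind(match(sf$site_id, truth$sites$site_id),
                sf$year_index, sf$survey_index)
  dateArr <- array(0, c(J, K, L))
  flowersArr <- array(0, c(J, K, L))
  dateArr[cell] <- standardizeCovariate(sf$survey_date)$values
  flowersArr[cell] <- standardizeCovariate(
    log1p(sf$woody_floral_count + sf$herbaceous_floral_count))$values

  psi1 <- initialOccupancyProb(params, covs)
  Z <- array(0L, c(S, J, K))
  Z[, , 1] <- matrix(stats::rbinom(S * J, 1, psi1), S, J)
  if (K > 1) for (k in 2:K) {
    gam <- colonizationProb(params, covs, k)
    phi <- persistenceProb(params, covs, k)
    pk <- ifelse(Z[, , k - 1] == 1L, phi, gam)
    Z[, , k] <- matrix(stats::rbinom(S * J, 1, pk), S, J)
  }

  p <- .detProbArray(params, covs@degree, dateArr, flowersArr)
  V <- array(0L, c(S, J, K, L))
  spCell <- cbind(rep(seq_len(S), nrow(sf)),
                  cell[rep(seq_len(nrow(sf)), each = S), , drop = FALSE])
  zHere <- Z[spCell[, 1:3, drop = FALSE]]
  pHere <- p[spCell]
  V[spCell] <- stats::rbinom(nrow(spCell), 1, zHere * pHere)

  records <- data.frame(
    species_id = truth$scores$species_id[spCell[, 1]],
    site_id = truth$sites$site_id[spCell[, 2]],
    year_index = spCell[, 3],
    survey_index = spCell[, 4],
    capture_count = V[spCell] *
      (1L + stats::rpois(nrow(spCell), 0.7)),
    survey_date = sf$survey_date[rep(seq_len(nrow(sf)), each = S)],
    herbaceous_floral_count = sf$herbaceous_floral_count[
      rep(seq_len(nrow(sf)), each = S)],
    woody_floral_count = sf$woody_floral_count[
      rep(seq_len(nrow(sf)), each = S)])
  records <- records[order(records$species_id, records$site_id,
                           records$year_index, records$survey_index), ]
  rownames(records) <- NULL
  darr <- buildDetectionArray(records)
  list(darr = darr, records = records, Z = Z, p = p)
}

#' Generate an interaction network with a specialisation gradient
#'
#' Each species draws its interactions from a mixture of the community
#' availability profile (generalist limit) and a point mass on a focal
#' genus (specialist limit). The species' specialisation weight `w` in
#' `[0, 1]` — drawn from the Beta distribution with the configured d'
#' moments — is its *target standardised specialisation*: the mixture
#' coefficient is calibrated by bisection so the expected interaction
#' profile has Kullback-Leibler divergence `w` times the species'
#' attainable maximum. Specialists are steered toward genera rare enough
#' to support their target (a common genus cannot carry a high d').
#' Counts are multinomial around the calibrated profile, so realised
#' scores scatter around the targets but track them in rank.
#'
#' @param config a [simConfig()].
#' @return list with `network` ([InteractionNetwork-class]), the target
#'   `weights`, and the `edges` data.frame.
#' @export
generateNetwork <- function(config) {
  set.seed(config$seed + 4L)  # network stream
  S <- config$nSpecies
  G <- config$network$nGenera
  genera <- .padId("genus", seq_len(G), G)
  base <- stats::rlnorm(G, 0, config$network$availabilitySd)
  q0 <- base / sum(base)
  sh <- .betaShapes(config$dPrimeMean, config$dPrimeSd)
  w <- stats::rbeta(S, sh[1], sh[2])
  total <- pmax(1, round(stats::rlnorm(S, config$network$meanLogInteractions,
                                       config$network$sdLogInteractions)))
  M <- sum(total)

  klAt <- function(m, g) {
    p <- (1 - m) * q0
    p[g] <- p[g] + m
    use <- p > 0
    sum(p[use] * log(p[use] / q0[use]))
  }
  rows <- lapply(seq_len(S), function(i) {
    dMax <- log(M / total[i])
    target <- w[i] * dMax
    # focal genus must be rare enough that exclusive use reaches the target
    ok <- which(log(1 / q0) >= target)
    g <- if (length(ok)) ok[sample.int(length(ok), 1, prob = q0[ok])]
         else which.min(q0)
    lo <- 0; hi <- 1
    for (it in 1:40) {
      mid <- (lo + hi) / 2
      if (klAt(mid, g) < min(target, klAt(1, g))) lo <- mid else hi <- mid
    }
    pr <- (1 - lo) * q0
    pr[g] <- pr[g] + lo
    cnt <- stats::rmultinom(1, total[i], pr)[, 1]
    use <- cnt > 0
    data.frame(pollinator_species = .padId("sp", i, S),
               plant_genus = genera[use], count = cnt[use],
               source = "synthetic")
  })
  edges <- do.call(rbind, rows)
  list(network = interactionNetwork(edges), weights = w, edges = edges)
}

#' Generate a paired pollen-supplementation dataset
#'
#' Site intercepts are normal around the logit of the per-arm limitation
#' probability; each retained pair's limitation state is Bernoulli in its
#' site's probability, and seed counts are constructed to realise the
#' intended ratio class (limited: ratio in (0.05, 0.45); not limited:
#' (0.55, 1.4)). A configurable fraction of pairs is planted as exclusion
#' cases, split between supplemented flowers that did not fruit and
#' controls with more than twice the supplemented seeds.
#'
#' @param config a [simConfig()].
#' @return list with `pairs` (raw table for [scorePollenPairs()]), `sites`,
#'   and the true site probabilities `theta`.
#' @export
generatePollen <- function(config) {
  set.seed(config$seed + 5L)  # pollen stream
  pc <- config$pollen
  nSite <- pc$nRestoredSites + pc$nControlSites
  sites <- data.frame(
    site_id = .padId("psite", seq_len(nSite), nSite),
    restored = as.numeric(seq_len(nSite) <= pc$nRestoredSites))
  thetaArm <- ifelse(sites$restored == 1, pc$thetaRestored, pc$thetaControl)
  b0 <- stats::rnorm(nSite, stats::qlogis(thetaArm), pc$siteSd)
  theta <- stats::plogis(b0)

  n <- nSite * pc$pairsPerSite
  siteIx <- rep(seq_len(nSite), each = pc$pairsPerSite)
  planted <- stats::runif(n) < pc$exclusionRate
  noFruit <- planted & stats::runif(n) < 0.5
  limited <- stats::rbinom(n, 1, theta[siteIx])
  supp <- 20L + stats::rpois(n, 60)
  ratio <- ifelse(limited == 1, stats::runif(n, 0.05, 0.45),
                  stats::runif(n, 0.55, 1.4))
  ratio[planted & !noFruit] <- stats::runif(sum(planted & !noFruit), 2.2, 4)
  control <- round(ratio * supp)
  suppOut <- ifelse(noFruit, NA_integer_, supp)
  pairs <- data.frame(site_id = sites$site_id[siteIx],
                      plant_id = paste0("plant", seq_len(n)),
                      control_seeds = as.integer(control),
                      supplemented_seeds = as.integer(suppOut))
  list(pairs = pairs, sites = sites, theta = theta)
}

#' Generate a complete synthetic study
#'
#' Convenience wrapper running all sub-generators under one config.
#'
#' @param config a [simConfig()].
#' @return list with elements `truth`, `detections`, `network`, `pollen`.
#' @export
generateSimulation <- function(config = simConfig()) {
  truth <- generateTruth(config)
  list(truth = truth,
       detections = generateDetections(truth, config),
       network = generateNetwork(config),
       pollen = generatePollen(config))
}

#' Write a synthetic study to CSV files
#'
#' Writes `surveys.csv`, `sites.csv`, `interactions.csv` and
#' `pollen_pairs.csv` into `dir`. The latent truth (true parameters, Z,
#' network weights, site theta) is written separately to
#' `truth.json` when the jsonlite package is available, so pipeline code
#' cannot accidentally consume it alongside the data.
#'
#' @param sim output of [generateSimulation()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
writeSimulatedData <- function(sim, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  writeSurveyTable(sim$detections$records, file.path(dir, "surveys.csv"))
  writeSiteTable(sim$truth$sites, file.path(dir, "sites.csv"))
  utils::write.csv(sim$network$edges, file.path(dir, "interactions.csv"),
                   row.names = FALSE)
  utils::write.csv(sim$pollen$pairs, file.path(dir, "pollen_pairs.csv"),
                   row.names = FALSE)
  if (requireNamespace("jsonlite", quietly = TRUE)) {
    truth <- list(params = unclass(sim$truth$params), Z = sim$detections$Z,
                  network_weights = sim$network$weights,
                  pollen_theta = sim$pollen$theta)
    jsonlite::write_json(truth, file.path(dir, "truth.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  invisible(dir)
}
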
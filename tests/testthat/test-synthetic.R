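test_that("generation is bit-identical under a fixed seed", {
  cfg <- simConfig(seed = 12, nSpecies = 15, nSites = 8, nRestored = 4)
  a <- generateSimulation(cfg)
  b <- generateSimulation(cfg)
  expect_identical(a$detections$records, b$detections$records)
  expect_identical(a$network$edges, b$network$edges)
  expect_identical(a$pollen$pairs, b$pollen$pairs)
  expect_identical(a$truth$params, b$truth$params)
})

test_that("sub-generators use independent streams", {
  big <- generateTruth(simConfig(seed = 12, nSpecies = 30, nSites = 8,
                                 nRestored = 4))
  small <- generateTruth(simConfig(seed = 12, nSpecies = 10, nSites = 8,
                                   nRestored = 4))
  # adding species must not shift the site covariate stream
  expect_identical(big$surveyFrame$survey_date, small$surveyFrame$survey_date)
  expect_identical(big$woody, small$woody)
})

test_that("specialisation scores hit the configured moments", {
  cfg <- simConfig(seed = 1)
  truth <- generateTruth(cfg)
  expect_equal(length(truth$scores$d_prime), 108)
  expect_lt(abs(mean(truth$scores$d_prime) - 0.29), 0.02)
  expect_lt(abs(sd(truth$scores$d_prime) - 0.13), 0.02)
  expect_error(simConfig(dPrimeMean = 0.5, dPrimeSd = 0.6), "infeasible")
})

test_that("degenerate hyper-sds collapse the community", {
  cfg <- simConfig(seed = 9, nSpecies = 12, nSites = 6, nRestored = 3,
                   hypers = list(psi1_0 = c(-1, 0), gamma_0 = c(-2, 0),
                                 phi_0 = c(0.5, 0), p_0 = c(-1, 0),
                                 p_3 = c(-1.25, 0)))
  truth <- generateTruth(cfg)
  expect_true(all(truth$params$psi1_0 == -1))
  expect_true(all(truth$params$gamma_0 == -2))
  expect_true(all(truth$params$p_3 == -1.25))
})

test_that("perfect detection exposes the latent states", {
  cfg <- simConfig(seed = 33, nSpecies = 10, nSites = 6, nRestored = 3)
  truth <- generateTruth(cfg)
  S <- cfg$nSpecies
  truth$params$p_0 <- rep(40, S)
  truth$params$p_1 <- 0; truth$params$p_4 <- 0
  truth$params$p_2 <- rep(0, S); truth$params$p_3 <- rep(0, S)
  truth$params$p_5 <- rep(0, cfg$nYears)
  det <- generateDetections(truth, cfg)
  V <- detections(det$darr)
  sp <- match(speciesIds(det$darr), truth$scores$species_id)
  st <- match(siteIds(det$darr), truth$sites$site_id)
  for (l in seq_len(cfg$nSurveys))
    expect_equal(V[, , , l], det$Z[sp, st, , drop = FALSE],
                 ignore_attr = TRUE)
})

test_that("impossible occurrence yields an empty detection history", {
  cfg <- simConfig(seed = 34, nSpecies = 6, nSites = 4, nRestored = 2)
  truth <- generateTruth(cfg)
  truth$params$psi1_0 <- rep(-40, 6)
  truth$params$gamma_0 <- rep(-40, 6)
  truth$params$psi1 <- rep(0, 5)
  truth$params$gamma <- rep(0, 5)
  truth$params$gamma_year <- rep(0, cfg$nYears)
  det <- generateDetections(truth, cfg)
  expect_equal(sum(det$Z), 0)
  expect_equal(nSpecies(det$darr), 0)
})

test_that("first-year occupancy frequencies match psi1", {
  cfg <- simConfig(seed = 44, nSpecies = 125, nSites = 40, nRestored = 20,
                   nYears = 1, nSurveys = 2)
  truth <- generateTruth(cfg)
  det <- generateDetections(truth, cfg)
  psi1 <- initialOccupancyProb(truth$params, truth$covs)
  n <- length(psi1)  # 5000 species-site cells
  se <- sqrt(sum(psi1 * (1 - psi1))) / n
  expect_lt(abs(mean(det$Z[, , 1]) - mean(psi1)), 3 * se)
})

test_that("generated tables pass the ingest path unchanged", {
  sim <- generateSimulation(simConfig(seed = 3, nSpecies = 10, nSites = 6,
                                      nRestored = 3, missingRate = 0.1))
  dir <- withr::local_tempdir()
  writeSimulatedData(sim, dir)
  rec <- readSurveyTable(file.path(dir, "surveys.csv"))
  darr <- buildDetectionArray(rec)
  expect_identical(detections(darr), detections(sim$detections$darr))
  sites <- readSiteTable(file.path(dir, "sites.csv"))
  woody <- summarizeWoody(rec)
  sc <- specializationScores(interactionNetwork(file.path(dir, "interactions.csv")))
  expect_true(all(sim$truth$scores$species_id %in% sc$species_id))
  covs <- covariateBundle(sc, sites, woody)
  expect_s4_class(covs, "CovariateBundle")
  # masked surveys are genuinely absent from the written records
  expect_lt(sum(surveyMask(darr)), length(surveyMask(darr)))
})
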
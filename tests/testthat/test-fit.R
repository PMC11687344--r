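test_that("a small fit completes, is finite and seed-reproducible", {
  sim <- smallSim(seed = 7, nSpecies = 5, nSites = 4, nYears = 2,
                  nSurveys = 3)
  fit <- suppressWarnings(fitOccupancy(sim$det$darr, sim$truth$covs,
                                       iterations = 300, warmup = 150,
                                       chains = 2, seed = 11))
  expect_true(all(is.finite(posteriorDraws(fit))))
  expect_equal(nrow(posteriorDraws(fit)), 300)
  fit2 <- suppressWarnings(fitOccupancy(sim$det$darr, sim$truth$covs,
                                        iterations = 300, warmup = 150,
                                        chains = 2, seed = 11))
  expect_identical(posteriorDraws(fit), posteriorDraws(fit2))
  expect_s4_class(convergence(fit), "FitReport")
  expect_identical(convergence(fit)@nDivergent, 0L)
})

test_that("with no conducted surveys the posterior reproduces the priors", {
  sim <- smallSim(seed = 19, nSpecies = 6, nSites = 4, nYears = 2,
                  nSurveys = 2)
  darr <- sim$det$darr
  darr@mask[] <- FALSE
  darr@V[] <- 0L
  fit <- suppressWarnings(fitOccupancy(darr, sim$truth$covs,
                                       iterations = 3000, warmup = 1000,
                                       chains = 2, seed = 3))
  d <- posteriorDraws(fit)
  # community slopes should recover their Normal(0, 2) prior
  sl <- as.vector(d[, c("psi1_2", "gamma_3", "p_4")])
  expect_lt(abs(mean(sl)), 0.25)
  expect_lt(abs(sd(sl) - 2), 0.4)
  # hyper-sd keeps to its half-Normal(0, 1.5) prior (median ~ 1.01)
  expect_lt(abs(median(d[, "sigma_psi1_0"]) - 1.5 * qnorm(0.75)), 0.35)
})

test_that("posterior summaries follow the BCI labelling convention", {
  expect_equal(summarizeDraws(rep(2, 100))$label, "strong")
  expect_equal(summarizeDraws(rep(2, 100))$l95, 2)
  sym <- qnorm(seq(0.001, 0.999, length.out = 2001), 0, 1)
  expect_equal(summarizeDraws(sym)$label, "none")
  # mean 1.02 with sd 1: the 50% interval clears zero, the 95% does not
  marg <- qnorm(seq(0.001, 0.999, length.out = 2001), 1.02, 1)
  s <- summarizeDraws(marg)
  expect_equal(s$label, "marginal")
  expect_gt(s$l50, 0)
  expect_lt(s$l95, 0)
  m <- cbind(a = rnorm(10), b = rnorm(10))
  expect_error(summarizeDraws(m, "zzz"), "unknown parameter.*available.*a")
})

test_that("convergence gates flag exactly the reported conditions", {
  expect_true(fitReport(1.04, 0.2, 0L)@converged)
  expect_false(fitReport(1.06, 0.2, 0L)@converged)
  expect_false(fitReport(1.04, 0.05, 0L)@converged)
  expect_false(fitReport(1.04, 0.2, 1L)@converged)
  expect_false(fitReport(1.049999, 0.1, 0L)@converged)  # ratio must exceed 0.1
  expect_true(fitReport(1.0499, 0.100001, 0L)@converged)
})

test_that("the random-slopes variant recovers a d'-linked colonisation effect", {
  cfg <- simConfig(seed = 23, nSpecies = 30, nSites = 10, nRestored = 5,
                   effects = list(psi1 = c(0, 2.3, 0, 0, 0),
                                  gamma = c(0, 0.5, 1.6, 0, 1.8),
                                  phi = c(0, 0, 0, 0, 0),
                                  p_1 = 0.5, p_4 = 0.4))
  truth <- generateTruth(cfg)
  det <- generateDetections(truth, cfg)
  fit <- suppressWarnings(fitOccupancy(det$darr, truth$covs,
                                       iterations = 1500, warmup = 750,
                                       chains = 2, seed = 4,
                                       variant = "randomSlopes"))
  cors <- slopeCorrelations(fit)
  gw <- cors[cors$name == "cor_dprime_b_gamma_w", ]
  expect_gt(gw$mean, 0)
  expect_gt(gw$u50, 0)

  # null configuration: no d'-linked effects anywhere
  cfg0 <- simConfig(seed = 29, nSpecies = 30, nSites = 10, nRestored = 5,
                    effects = list(psi1 = c(0, 2.3, 0, 0, 0),
                                   gamma = c(0, 0.5, 1.6, 0, 0),
                                   phi = c(0, 0, 0, 0, 0),
                                   p_1 = 0.5, p_4 = 0.4))
  truth0 <- generateTruth(cfg0)
  det0 <- generateDetections(truth0, cfg0)
  fit0 <- suppressWarnings(fitOccupancy(det0$darr, truth0$covs,
                                        iterations = 1500, warmup = 750,
                                        chains = 2, seed = 4,
                                        variant = "randomSlopes"))
  gw0 <- slopeCorrelations(fit0)
  gw0 <- gw0[gw0$name == "cor_dprime_b_gamma_w", ]
  expect_lt(gw0$l95, 0)
  expect_gt(gw0$u95, 0)
})

test_that("species slopes shrink to the community mean as the hierarchy tightens", {
  sim <- smallSim(seed = 37, nSpecies = 10, nSites = 6, nYears = 2,
                  nSurveys = 3)
  tight <- occuPriors(hypersd_scale = 0.02)
  fit <- suppressWarnings(fitOccupancy(sim$det$darr, sim$truth$covs,
                                       iterations = 800, warmup = 400,
                                       chains = 1, seed = 2,
                                       priors = tight,
                                       variant = "randomSlopes"))
  d <- posteriorDraws(fit)
  cols <- grep("^b_gamma_w\\[", colnames(d))
  spread <- mean(apply(d[, cols], 1, sd))
  expect_lt(spread, 0.1)
})
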
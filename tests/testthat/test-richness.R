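# a minimal known-parameter fit used throughout: S species, K years
richnessFixture <- function(S = 20, K = 3, psi1_2 = 0, gamma_2 = 0,
                            seed = 5) {
  set.seed(seed)
  covs <- directCovs(dPrime = rnorm(S), degree = rnorm(S),
                     restored = c(0, 1), woody = rep(0, 2 * K))
  params <- occupancyParams(
    psi1_0 = rnorm(S, -0.5, 1), psi1 = c(0, psi1_2, 0, 0, 0),
    gamma_0 = rnorm(S, -1.5, 1), gamma = c(0, gamma_2, 0, 0, 0),
    gamma_year = rep(0, K),
    phi_0 = rnorm(S, 0.5, 1), phi = rep(0, 5), phi_year = rep(0, K),
    p_0 = rep(0, S), p_1 = 0, p_2 = rep(0, S), p_3 = rep(0, S), p_4 = 0,
    p_5 = rep(0, K))
  fitFromParams(params, covs, c(S = S, J = 2L, K = K, L = 1L))
}

test_that("occurrence simulation honours absorbing probabilities", {
  S <- 10; K <- 4
  ones <- matrix(1, S, K); zeros <- matrix(0, S, K)
  expect_true(all(simulateOccurrence(rep(1, S), zeros, ones) == 1))
  expect_true(all(simulateOccurrence(rep(0, S), zeros, ones) == 0))
})

test_that("second-year occurrence frequency matches the recursion", {
  set.seed(12)
  psi1 <- 0.35; phi <- 0.7; gamma <- 0.2
  n <- 10000
  z2 <- replicate(50, {
    Z <- simulateOccurrence(rep(psi1, n / 50),
                            matrix(gamma, n / 50, 2),
                            matrix(phi, n / 50, 2))
    sum(Z[, 2])
  })
  target <- occupancyRecursion(psi1, phi, gamma)
  se <- sqrt(target * (1 - target) / n)
  expect_lt(abs(sum(z2) / n - target), 3 * se)
})

test_that("richness is exact when occupancy is certain and bounded always", {
  S <- 15; K <- 3
  covs <- directCovs(dPrime = rep(0, S), degree = rep(0, S),
                     restored = c(0, 1), woody = rep(0, 2 * K))
  params <- occupancyParams(
    psi1_0 = rep(40, S), psi1 = rep(0, 5),
    gamma_0 = rep(40, S), gamma = rep(0, 5), gamma_year = rep(0, K),
    phi_0 = rep(40, S), phi = rep(0, 5), phi_year = rep(0, K),
    p_0 = rep(0, S), p_1 = 0, p_2 = rep(0, S), p_3 = rep(0, S), p_4 = 0,
    p_5 = rep(0, K))
  fit <- fitFromParams(params, covs, c(S = S, J = 2L, K = K, L = 1L),
                       nDraws = 20)
  r <- projectRichness(fit, scenario(1, 0, K), reps = 2, seed = 1)
  expect_true(all(r@richness == S))
  expect_equal(r@summary$mean, rep(S, K))

  rnd <- projectRichness(richnessFixture(), scenario(0, 0, 3), seed = 3)
  expect_true(all(rnd@richness >= 0 & rnd@richness <= 20))
})

test_that("simulated expected richness matches the analytic occupancy sum", {
  fit <- richnessFixture(S = 30, seed = 8)
  scn <- scenario(1, 0.5, 3)
  reps <- 400
  r <- projectRichness(fit, scn, reps = reps, seed = 21)
  analytic <- expectedRichness(fit, scn)[1, ]
  # per-year Monte-Carlo SE of a sum of independent Bernoullis
  idx <- metaoccu:::.paramIndices(fit)
  rates <- metaoccu:::.scenarioRates(fit@draws[1, ], idx,
                                     fit@covariates@dPrime, scn, 3)
  psi <- occupancyTrajectory(rates$psi1, rates$gamma, rates$phi)
  se <- sqrt(colSums(psi * (1 - psi)) / reps)
  expect_true(all(abs(colMeans(r@richness) - analytic) < 3 * se))
})

test_that("scenario contrasts are paired, antisymmetric and sign-correct", {
  fit <- richnessFixture(S = 25, psi1_2 = 2.26, gamma_2 = 1.02, seed = 9)
  a <- scenario(1, 0, 3); b <- scenario(0, 0, 3)
  same <- scenarioContrast(fit, a, a, reps = 5, seed = 2)
  expect_true(all(same@richness == 0))
  ab <- scenarioContrast(fit, a, b, reps = 5, seed = 2)
  ba <- scenarioContrast(fit, b, a, reps = 5, seed = 2)
  expect_identical(ab@richness, -ba@richness)
  expect_true(all(ab@summary$mean > 0))
})

test_that("the restored-control contrast matches the analytic difference", {
  # the reported-scale configuration: 108 species, strong restoration
  # effect on initial occurrence, marginal one on colonisation
  fit <- richnessFixture(S = 108, psi1_2 = 2.26, gamma_2 = 1.02, seed = 14)
  a <- scenario(1, 0, 3); b <- scenario(0, 0, 3)
  reps <- 300
  con <- scenarioContrast(fit, a, b, reps = reps, seed = 6)
  analytic <- expectedRichness(fit, a)[1, ] - expectedRichness(fit, b)[1, ]
  expect_true(all(analytic > 0))
  # each species' paired difference has variance at most 1
  expect_true(all(abs(colMeans(con@richness) - analytic) <
                    3 * sqrt(108 / (reps * nrow(fit@draws)))))
})
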
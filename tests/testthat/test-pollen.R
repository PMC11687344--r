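test_that("pair scoring applies both exclusion rules and the <50% rule", {
  pairs <- data.frame(
    site_id = "s1", plant_id = paste0("p", 1:6),
    control_seeds = c(30L, 210L, 40L, 50L, 90L, 10L),
    supplemented_seeds = c(100L, 100L, NA, 100L, 100L, 0L))
  sc <- scorePollenPairs(pairs)
  expect_equal(sc$ratio[1], 0.3)
  expect_false(sc$excluded[1])
  expect_equal(sc$limited[1], 1L)
  expect_true(sc$excluded[2])
  expect_equal(sc$reason[2], "control > 2x supplemented")
  expect_true(sc$excluded[3])
  expect_equal(sc$reason[3], "no fruit")
  # a ratio of exactly one half is not limited
  expect_equal(sc$limited[4], 0L)
  expect_equal(sc$limited[5], 0L)
  # fruit with zero seeds leaves the ratio undefined
  expect_equal(sc$reason[6], "no fruit")
  expect_true(is.na(sc$limited[6]))
  # conservation and exhaustive, mutually exclusive reasons
  expect_equal(sum(!sc$excluded), nrow(pairs) - sum(sc$excluded))
  expect_true(all(is.na(sc$reason) == !sc$excluded))
  expect_error(scorePollenPairs(transform(pairs, control_seeds = -1L)),
               "non-negative")
})

test_that("scoring is order-independent and idempotent", {
  set.seed(51)
  gen <- generatePollen(simConfig(seed = 51))
  sc <- scorePollenPairs(gen$pairs)
  perm <- sample(nrow(gen$pairs))
  scP <- scorePollenPairs(gen$pairs[perm, ])
  expect_equal(scP$limited, sc$limited[perm])
  expect_equal(scP$excluded, sc$excluded[perm])
  expect_equal(scorePollenPairs(sc)$limited, sc$limited)
})

test_that("the logit intercept maps to the reported limitation probability", {
  expect_equal(limitationProbability(-0.79), 0.312, tolerance = 1e-3)
  expect_equal(limitationProbability(0), 0.5)
  x <- 1.3
  expect_equal(limitationProbability(x) + limitationProbability(-x), 1)
})

test_that("the hierarchical logistic model recovers a common theta", {
  cfg <- simConfig(seed = 61,
                   pollen = list(thetaControl = 0.3, thetaRestored = 0.3,
                                 nRestoredSites = 6, nControlSites = 5,
                                 pairsPerSite = 16, siteSd = 0.3,
                                 exclusionRate = 0.1))
  gen <- generatePollen(cfg)
  fit <- suppressWarnings(
    fitPollenModel(scorePollenPairs(gen$pairs), gen$sites,
                   iterations = 3000, warmup = 1500, chains = 2, seed = 8))
  s <- summarizeFit(fit)
  mu <- s[s$name == "mu_beta0", ]
  expect_lt(abs(mu$mean - qlogis(0.3)), 0.4)
  b1 <- s[s$name == "beta_1", ]
  expect_lt(b1$l95, 0)
  expect_gt(b1$u95, 0)
})

test_that("beta_1 intervals are calibrated under the null", {
  hits <- 0
  for (r in 1:20) {
    cfg <- simConfig(seed = 700 + r,
                     pollen = list(thetaControl = 0.3, thetaRestored = 0.3,
                                   nRestoredSites = 6, nControlSites = 5,
                                   pairsPerSite = 16, siteSd = 0.3,
                                   exclusionRate = 0.1))
    gen <- generatePollen(cfg)
    fit <- suppressWarnings(
      fitPollenModel(scorePollenPairs(gen$pairs), gen$sites,
                     iterations = 1200, warmup = 600, chains = 2,
                     seed = r))
    s <- summarizeFit(fit, "beta_1")
    if (s$l95 < 0 && s$u95 > 0) hits <- hits + 1
  }
  expect_gte(hits, 18)
})

test_that("complete separation stays finite under the priors", {
  pairs <- data.frame(
    site_id = rep(c("a", "b", "c"), each = 8),
    plant_id = paste0("p", 1:24),
    control_seeds = c(rep(10L, 8), rep(c(10L, 90L), 8)),
    supplemented_seeds = 100L)
  sites <- data.frame(site_id = c("a", "b", "c"), restored = c(1, 0, 0))
  fit <- suppressWarnings(fitPollenModel(pairs, sites, iterations = 1500,
                                         warmup = 750, chains = 2, seed = 2))
  d <- posteriorDraws(fit)
  expect_true(all(is.finite(d)))
  expect_lt(max(abs(colMeans(d))), 10)
})

test_that("the pollen generator honours its arm and exclusion settings", {
  cfg <- simConfig(seed = 77,
                   pollen = list(thetaControl = 1e-9, thetaRestored = 1e-9,
                                 nRestoredSites = 6, nControlSites = 5,
                                 pairsPerSite = 16, siteSd = 0.01,
                                 exclusionRate = 0))
  gen <- generatePollen(cfg)
  sc <- scorePollenPairs(gen$pairs)
  expect_equal(sum(sc$limited, na.rm = TRUE), 0)

  cfg2 <- simConfig(seed = 78,
                    pollen = list(thetaControl = 0.3, thetaRestored = 0.3,
                                  nRestoredSites = 10, nControlSites = 10,
                                  pairsPerSite = 40, siteSd = 0.3,
                                  exclusionRate = 0.1))
  sc2 <- scorePollenPairs(generatePollen(cfg2)$pairs)
  n <- nrow(sc2)
  se <- sqrt(0.1 * 0.9 / n)
  expect_lt(abs(mean(sc2$excluded) - 0.1), 3 * se)
})
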
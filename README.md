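# metaoccu

Multi-species dynamic occupancy modelling of pollinator metacommunities
under urban habitat restoration.

`metaoccu` is for ecologists who survey pollinator communities repeatedly
(several surveys per year, several years) across treated and control sites
and want to know whether a treatment such as lawn restoration changes the
*processes* behind species richness — initial occurrence, colonisation and
persistence — rather than just the snapshot counts. Everything runs on
plain CSV tables, and a synthetic-data generator with known ground truth
stands in for field data everywhere in the tests.

## The model

For species *i*, site *j*, year *k* and survey *l*:

```
Z[i,j,1] ~ Bernoulli(psi1[i,j])
Z[i,j,k] ~ Bernoulli(phi[i,j,k] * Z[i,j,k-1] + gamma[i,j,k] * (1 - Z[i,j,k-1]))
V[i,j,k,l] ~ Bernoulli(Z[i,j,k] * p[i,j,k,l])
```

with logit-linear predictors on initial occurrence (`psi1`), colonisation
(`gamma`), persistence (`phi`) — species intercepts drawn from community
distributions plus community slopes for specialisation *d'*, restoration,
woody floral abundance and the *d'* interactions — and on detection (`p`):
degree, a species-specific quadratic date phenology, survey-level floral
abundance and year offsets. The latent `Z` are marginalised out of the
likelihood as a two-state hidden Markov chain (log-domain forward
recursion) and the posterior is sampled by adaptive MCMC with the usual
gates (split R-hat < 1.05, ESS ratio > 0.1, no divergences).

Around the core model the package provides Blüthgen's standardised
specialisation `d'` (Kullback–Leibler divergence from genus availability,
normalised by exact integer-allocation extremes), posterior species
richness projection under covariate scenarios, and the paired
pollen-supplementation stage (exclusion rules, <50% limitation rule, and a
site-random-intercept Bayesian logistic model).

## Worked example

Simulate a 30-species, 12-site, 3-year study whose true effects mirror a
typical urban-restoration outcome, fit the model, and project the
restoration effect on richness (shortened chains for a quick demo):

```r
library(metaoccu)
cfg   <- simConfig(seed = 42, nSpecies = 30, nSites = 12, nRestored = 6)
truth <- generateTruth(cfg)
det   <- generateDetections(truth, cfg)
fit   <- fitOccupancy(det$darr, truth$covs, iterations = 2000,
                      warmup = 1000, chains = 2, seed = 1)
summarizeFit(fit, c("psi1_2", "gamma_3", "gamma_5", "phi_3", "p_4"))
#>      name       mean        l50       u50        l95        u95  label
#> 1  psi1_2  3.0450497  2.6517411  3.413802  1.9771855  4.0336773 strong
#> 2 gamma_3  2.2004982  1.8815273  2.499388  1.4273197  3.1799748 strong
#> 3 gamma_5  2.2234380  1.8811977  2.570838  1.3234194  3.2140538 strong
#> 4   phi_3 -0.5142842 -0.6565126 -0.368178 -0.9360573 -0.1355854 strong
#> 5     p_4  0.4263937  0.3755096  0.478895  0.2816383  0.5739081 strong
```

The true slopes behind these data were `psi1_2 = 2.26` (restoration raises
initial occurrence), `gamma_3 = 1.60` and `gamma_5 = 1.36` (woody flowers
raise colonisation, more so for specialists), `phi_3 = -0.61` and
`p_4 = 0.41`; every sign and label is recovered. (At demo length the fit
warns that the conservative convergence gates are not all met — the
slowest-mixing hierarchical sds need the default 4000-iteration,
three-chain run.)

```r
gain <- scenarioContrast(fit, scenario(restored = 1), scenario(restored = 0),
                        seed = 2)
gain
#> RichnessDistribution over 2000 draws x 3 years
#>  year    mean l50 u50 l95    u95
#>     1 11.6475  10  14   6 17.000
#>     2  3.9250   2   6  -1  9.025
#>     3  3.8815   2   6  -1  9.000
```

Of the 30 modelled species, restoration gains about 12 species of richness
in year one (95% BCI [6, 17]) and the advantage persists in later years.
The specialisation and pollen stages run the same way:

```r
scores <- specializationScores(generateNetwork(cfg)$network)
round(c(mean = mean(scores$d_prime), sd = sd(scores$d_prime)), 2)
#> mean   sd
#> 0.29 0.13

pol  <- generatePollen(cfg)
pfit <- fitPollenModel(scorePollenPairs(pol$pairs), pol$sites, seed = 3)
summarizeFit(pfit, c("mu_beta0", "beta_1"))
#>       name         mean        l50        u50        l95        u95  label
#> 1 mu_beta0 -0.984412189 -1.2201988 -0.7436348 -1.7757231 -0.2782066 strong
#> 2   beta_1  0.008328728 -0.3074975  0.3207507 -0.9408613  1.0336061   none
round(limitationProbability(summarizeFit(pfit, "mu_beta0")$mean), 2)
#> [1] 0.27
```

About 27% of plant pairs are pollen limited at the baseline site (the
generating truth was 30%), with no restoration effect — as simulated.

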
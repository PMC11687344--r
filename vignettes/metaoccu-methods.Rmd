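---
title: "Models and methods behind metaoccu"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind metaoccu}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The scientific problem

Habitat restoration in cities — unmowed, wildflower-seeded patches replacing
turfgrass — is expected to benefit wild pollinators, but a snapshot of
abundance cannot tell whether restored patches merely concentrate insects
that were already around, or genuinely change the processes that sustain
regional diversity. Those processes are metacommunity dynamics: the yearly
balance between **colonisation** (an unoccupied site gains a species) and
**persistence** (an occupied site keeps it). `metaoccu` implements the full
analysis chain for a repeat-survey study design over restored and control
sites: specialisation scoring from plant–pollinator interaction networks, a
multi-species dynamic occupancy model that corrects for imperfect
detection, posterior projection of species richness under covariate
scenarios, and a paired pollen-supplementation assay of pollination
service.

# The dynamic occupancy model

Let $Z_{ijk} \in \{0,1\}$ be the occurrence of species $i$ at site $j$ in
year $k$, and $V_{ijkl}$ the detection on survey $l$. The process model is

$$Z_{ij1} \sim \mathrm{Bern}(\psi^{1}_{ij}), \qquad
  Z_{ijk} \sim \mathrm{Bern}\!\big(\phi_{ijk} Z_{ij,k-1} +
  \gamma_{ijk} (1 - Z_{ij,k-1})\big),$$

and detections are conditionally independent Bernoulli draws,
$V_{ijkl} \sim \mathrm{Bern}(Z_{ijk}\, p_{ijkl})$, over the surveys that
were actually conducted. Each of $\psi^1$, $\gamma$, $\phi$ carries a
logit-linear predictor with a species intercept (hierarchically drawn from
a community distribution) and five community slopes: specialisation $d'$,
the binary restoration flag, woody floral abundance, and the two $d'$
interactions. Persistence into year $k$ responds to woody resources in
year $k-1$ (the resources that fed the overwintering generation).
Detection has a species intercept, a degree effect, a species-specific
quadratic phenology in the standardised day of year, a survey-level floral
abundance effect, and year offsets.

## Marginalised likelihood

The latent states are never sampled. For one species at one site the
$K$-year occupancy sequence is a two-state Markov chain with Bernoulli
emissions, and the likelihood is computed by a log-domain forward
recursion; an unoccupied year emits an all-zero survey history with
probability one and anything else with probability zero. `marginalLoglik()`
is the readable R reference, `totalLoglik()` the compiled equivalent used
in fitting; the test suite pins both against exhaustive enumeration over
all $2^K$ latent sequences.

Marginalisation has two practical consequences. Missing surveys are simply
dropped from the emission product — they are *masked, never imputed as
non-detections*. And species never detected anywhere contribute a
constant factor to the likelihood while their parameters float on the
prior; they are excluded at ingest (and reported), so all richness
statements are conditional on the observed species pool.

## Sampling and convergence gates

The posterior is explored by adaptive Metropolis-within-Gibbs, written in
C++ against the marginalised likelihood:

* species-level parameters use scalar random-walk steps that touch only
  that species' likelihood slice;
* community slopes and year offsets use scalar full-likelihood steps;
* hypermeans are conjugate Gibbs draws; hierarchical sds are updated on
  the log scale against a half-Normal prior;
* one joint *translation* step per intercept family shifts all species
  intercepts and their hypermean together — the classic slow direction of
  a centred hierarchy — at the cost of one likelihood evaluation.

Proposal scales adapt toward 0.44 acceptance during warmup
(diminishing-adaptation schedule) and are frozen afterwards. The default
run is 4000 iterations per chain with the first half discarded, three
chains. Convergence is gated exactly on split R-hat $< 1.05$, effective
sample size per stored step $> 0.1$, and zero divergent transitions (a
random-walk sampler has none; the field is meaningful when diagnostics
come from elsewhere). A failed gate returns the fit flagged, with a
warning, rather than erroring.

The entire inference path is cross-validated in the test suite against an
independent engine: the same small dataset and priors fitted in JAGS,
which samples the latent $Z$ discretely instead of marginalising.
Posterior means and sds agree within Monte-Carlo error.

## Identifiability of year offsets

Colonisation and persistence act only on transitions (years $\ge 2$).
Pinning their year offsets at year 1 — a year their predictors never touch
— leaves a likelihood-flat ridge between the offsets and the intercept
level, which we found degrades mixing badly. The offsets are therefore
pinned at the *first transition year* (year 2) and free from year 3 on;
the detection offset is pinned at year 1 as usual. A generative truth with
a nonzero year-2 offset is still exactly representable: the offset is
absorbed into the intercepts.

## Priors

All parameters live on the logit scale, where $\pm 4$ already saturates
the probability scale, so unit-scale normals are weakly informative:
community slopes, hypermeans and year offsets $\mathcal N(0, 2)$;
hierarchical sds half-$\mathcal N(0, 1.5)$. The pollen model uses the same
scheme with half-$\mathcal N(0, 1)$ on the site-intercept sd. All scales
are overridable via `occuPriors()` / `pollenPriors()`.

# Specialisation: Blüthgen's d'

From the pooled interaction network (all sources are pooled; a `source`
column is provenance only), availability $q_g$ is each plant genus' share
of all interactions. The raw specialisation of species $i$ is the
Kullback–Leibler divergence of its interaction frequencies from $q$
(natural log), standardised to $d' = (d - d_{\min})/(d_{\max} - d_{\min})$.
Numerical choices:

* $d_{\max} = \ln(m/A_i)$ — exclusive use of a genus whose total is the
  species' own count; this is also a rigorous upper bound on $d$ because
  $q_g \ge A_{ig}/m$ for every used genus.
* $d_{\min}$ is found over integer allocations of the $A_i$ interactions
  by largest-remainder proportional allocation followed by single-unit
  local swaps (remainder ties break to the lower genus index, making the
  search deterministic); the observed allocation is itself feasible, so
  $d_{\min}$ is additionally capped at the observed $d$, keeping
  $d' \ge 0$ by construction. An exhaustive-enumeration oracle pins the
  greedy search on all small profiles in the tests.
* a one-genus network offers no choice: $d_{\max} = d_{\min}$ and $d'$ is
  defined as 0.

Degree (number of genera used) enters the detection model log-transformed
and z-scored, because it is strongly right-skewed.

# Richness projection

For each posterior draw, species trajectories are simulated at a
hypothetical site with fixed covariates (`scenario()`): first-year states
from $\psi^1$, later years from the colonisation/persistence recursion;
richness is the yearly species sum, and the posterior distribution pools
all draws (optionally several occurrence replicates per draw — the default
is one, since the posterior itself dominates the spread and the analytic
expectation is available as an oracle). Contrasts between scenarios use
common random numbers per draw, which makes them exactly antisymmetric and
sharpens the paired difference. `expectedRichness()` computes
$\sum_i \Psi_{ik}$ by the deterministic recursion and serves as the
no-simulation oracle in the tests. Scenario woody abundance applies to all
years, including the lagged persistence term.

# Pollen limitation

Each phytometer flower pair contributes the ratio of control to supplemented
seed counts. Pairs are excluded when the supplemented flower did not fruit
— including fruit with zero seeds, which leaves the ratio undefined — or
when the control out-produced the supplemented flower more than twofold.
Retained pairs are *limited* when the ratio is below one half; exactly one
half is classified not limited (strict reading of the `< 50%` rule). The
probability of limitation is modelled by logistic regression with a
site random intercept and a restoration effect, sampled by the same
adaptive scheme (site intercepts update in parallel against their
independent site likelihoods). The weakly informative priors keep
estimates finite under complete separation at a site.

# The synthetic-data generator

The generator is the package's test-bed and emulates the design of the
motivating study: 18 sites (half restored), 3 years, 6 surveys per
site-year, 108 species. Default true community slopes mirror the direction
and rough magnitude of that study's estimates (restoration strongly raises
initial occurrence; woody resources and their $d'$ interaction raise
colonisation; woody slightly lowers persistence), so the synthetic
metacommunity re-tells the same story with known truth. Other defaults we
chose once as field-realistic: community intercept distributions giving
modest baseline occupancy (mean initial occupancy around 0.2 at control
sites), detection around 0.25 at a species' phenological peak, phenology
peaks spread uniformly across the season with curvature leaving a species
detectable in roughly 2–4 of 6 surveys, log-normal woody abundance with a
fifth of sites woody-free, and far richer herbaceous bloom on restored
sites. Covariates are standardised by the very same code the ingest path
uses, so generated tables survive a write–read–rebuild round trip
bit-identically.

The network generator treats each species' Beta-distributed weight as its
*target* standardised specialisation and calibrates the mixture between
the availability profile and a focal-genus point mass by bisection, so the
community d' distribution matches the configured moments (default mean
0.29, sd 0.13) and realised scores track the targets in rank. Specialists
are steered to genera rare enough to support their target — a ubiquitous
genus cannot carry a high $d'$.

Determinism: every sub-generator (covariates, species parameters,
detections, network, pollen) seeds its own Mersenne–Twister stream from a
fixed offset of the master seed, so enlarging the species pool does not
shift the site covariates.

What the generator does *not* emulate — and hence what green tests do not
establish about real data: spatial structure and dispersal limitation
among sites, weather-driven survey heterogeneity beyond the quadratic
date curve, taxonomic detection biases, abundance dynamics underneath the
occupancy states, and any form of model misspecification beyond the mild
one it already contains (phenology peaks are uniform, not normal, while
the fitted model assumes normal hyperdistributions).

# Testing scales and what we learned at them

Parameter recovery is exercised at 40 species × 12 sites × 3 years × 6
surveys with ten simulated replicates and a short-chain configuration
(2000 iterations, half warmup, two chains) — sizes chosen so the whole
suite stays comfortably re-runnable; the likelihood itself is pinned
exactly at tiny sizes, and the sampler against JAGS, so the recovery runs
test calibration rather than correctness. At this reduced scale the
posterior for the transition-rate slopes is visibly right-skewed: with
only two year-to-year transitions, colonisation and persistence trade off
along a soft ridge and posterior *means* sit slightly outside the truth
(the same displacement appears in the independent JAGS fit). Interval
coverage is the more stable summary at this size.

# Known limitations

* A random-walk sampler needs many iterations relative to Hamiltonian
  schemes; the defaults are calibrated for the study's design scale, and
  much larger communities would warrant more.
* No data augmentation for never-detected species: richness is
  conditional on the observed pool, matching the analysis the package
  implements, and no asymptotic richness estimator is provided.
* One observation-level detection model (binary detection per survey);
  abundance-based (N-mixture) extensions are out of scope.
* The pollen stage models the binary limitation outcome, not seed counts.
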
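#' Define a covariate scenario for richness projection
#'
#' A scenario fixes the site-level covariates at which occupancy
#' trajectories are projected: the restoration flag and a standardised
#' woody floral abundance (constant across years, including the lag in the
#' persistence predictor).
#'
#' @param restored 0 or 1.
#' @param woodyZ woody floral abundance on the standardised scale (0 =
#'   study average, 1 = one SD above).
#' @param years number of years to project (must not exceed the fitted
#'   number of years, whose offsets are reused).
#' @return a scenario list.
#' @export
scenario <- function(restored, woodyZ = 0, years = 3) {
  stopifnot(restored %in% c(0, 1), years >= 1)
  list(restored = as.numeric(restored), woodyZ = as.numeric(woodyZ),
       years = as.integer(years))
}

# per-draw index map from parameter names to draw-matrix columns
.paramIndices <- function(fit) {
  cols <- colnames(fit@draws)
  sp <- names(fit@covariates@dPrime)
  K <- fit@dims[["K"]]
  one <- function(nms) {
    ix <- match(nms, cols)
    if (anyNA(ix)) stop("draws are missing parameters: ",
                        paste(nms[is.na(ix)], collapse = ", "))
    ix
  }
  yearIx <- function(nm) if (K > 2) one(paste0(nm, "[", 3:K, "]")) else integer()
  list(psi1_0 = one(paste0("psi1_0[", sp, "]")),
       gamma_0 = one(paste0("gamma_0[", sp, "]")),
       phi_0 = one(paste0("phi_0[", sp, "]")),
       psi1 = one(paste0("psi1_", 1:5)),
       gamma = one(paste0("gamma_", 1:5)),
       phi = one(paste0("phi_", 1:5)),
       gamma_6 = yearIx("gamma_6"), phi_6 = yearIx("phi_6"))
}

# species-level psi1 (S), gamma and phi (S x K) for one posterior draw
# under a scenario; transition entries for year 1 are NA
.scenarioRates <- function(x, idx, dp, scn, K) {
  r <- scn$restored; w <- scn$woodyZ
  lin <- function(b0, b, yearOff) {
    base <- b0 + b[1] * dp + b[2] * r + b[3] * w + b[4] * dp * r + b[5] * dp * w
    outer(base, c(NA, yearOff), `+`)
  }
  # year-2 transition offsets are the pinned reference level (0)
  yrG <- if (K > 1) c(0, x[idx$gamma_6]) else numeric()
  yrF <- if (K > 1) c(0, x[idx$phi_6]) else numeric()
  list(psi1 = stats::plogis(x[idx$psi1_0] + x[idx$psi1][1] * dp +
                            x[idx$psi1][2] * r + x[idx$psi1][3] * w +
                            x[idx$psi1][4] * dp * r + x[idx$psi1][5] * dp * w),
       gamma = stats::plogis(lin(x[idx$gamma_0], x[idx$gamma], yrG)),
       phi = stats::plogis(lin(x[idx$phi_0], x[idx$phi], yrF)))
}

#' Simulate yearly occurrence states
#'
#' Draws binary occupancy trajectories `Z[i, k]`: first-year states are
#' Bernoulli(`psi1`), later years persist with probability `phi[i, k]` when
#' occupied and colonise with probability `gamma[i, k]` otherwise.
#'
#' @param psi1 length-S vector of first-year occupancy probabilities.
#' @param gamma,phi S x K matrices (columns 2..K are used).
#' @param u optional S x K matrix of uniforms (for common-random-number
#'   pairing across scenarios); drawn internally when `NULL`.
#' @return S x K binary matrix.
#' @export
simulateOccurrence <- function(psi1, gamma, phi, u = NULL) {
  S <- length(psi1); K <- ncol(gamma)
  if (is.null(u)) u <- matrix(stats::runif(S * K), S, K)
  Z <- matrix(0L, S, K)
  Z[, 1] <- as.integer(u[, 1] < psi1)
  if (K > 1) for (k in 2:K) {
    pk <- ifelse(Z[, k - 1] == 1L, phi[, k], gamma[, k])
    Z[, k] <- as.integer(u[, k] < pk)
  }
  Z
}

#' Deterministic occupancy trajectory
#'
#' The expectation companion of [simulateOccurrence()]: applies the
#' occupancy recursion to probabilities instead of drawing states, giving
#' `Psi[i, k]` with expected richness `colSums(Psi)`. Used as the analytic
#' oracle for the simulation path.
#'
#' @inheritParams simulateOccurrence
#' @return S x K matrix of occupancy probabilities.
#' @export
occupancyTrajectory <- function(psi1, gamma, phi) {
  S <- length(psi1); K <- ncol(gamma)
  psi <- matrix(NA_real_, S, K)
  psi[, 1] <- psi1
  if (K > 1) for (k in 2:K)
    psi[, k] <- occupancyRecursion(psi[, k - 1], phi[, k], gamma[, k])
  psi
}

.richnessSummary <- function(mat) {
  qs <- t(apply(mat, 2, stats::quantile, probs = c(0.025, 0.25, 0.75, 0.975)))
  data.frame(year = seq_len(ncol(mat)), mean = colMeans(mat),
             l50 = qs[, 2], u50 = qs[, 3], l95 = qs[, 1], u95 = qs[, 4],
             row.names = NULL)
}

.selectDraws <- function(fit, draws) {
  if (is.null(draws)) seq_len(nrow(fit@draws)) else draws
}

#' Project species richness under a scenario
#'
#' The three-step posterior richness simulation: (1) for each posterior
#' draw, simulate every species' occurrence trajectory at a hypothetical
#' site with the scenario's covariates; (2) sum species present per year;
#' (3) repeat across all posterior draws (and `reps` occurrence replicates
#' per draw). Richness is conditional on the modelled (detected) species
#' pool and cannot exceed it.
#'
#' @param fit a `"community"`-variant [OccupancyFit-class].
#' @param scn a [scenario()].
#' @param reps occurrence replicates per posterior draw.
#' @param seed integer seed for the occurrence draws.
#' @param draws optional integer vector of posterior draw rows to use
#'   (default all).
#' @return a [RichnessDistribution-class].
#' @export
projectRichness <- function(fit, scn, reps = 1, seed = 1, draws = NULL) {
  idx <- .paramIndices(fit)
  dp <- fit@covariates@dPrime
  K <- scn$years
  if (K > fit@dims[["K"]])
    stop("scenario projects more years than the model was fitted to")
  rows <- .selectDraws(fit, draws)
  set.seed(seed)
  out <- matrix(0L, length(rows) * reps, K)
  S <- length(dp)
  for (a in seq_along(rows)) {
    rates <- .scenarioRates(fit@draws[rows[a], ], idx, dp, scn, fit@dims[["K"]])
    for (b in seq_len(reps)) {
      Z <- simulateOccurrence(rates$psi1,
                              rates$gamma[, seq_len(K), drop = FALSE],
                              rates$phi[, seq_len(K), drop = FALSE])
      out[(a - 1) * reps + b, ] <- colSums(Z)
    }
  }
  new("RichnessDistribution", richness = out, scenario = scn,
      summary = .richnessSummary(out))
}

#' Paired richness contrast between two scenarios
#'
#' Projects richness under both scenarios with common random numbers (the
#' same uniform stream per posterior draw drives the occurrence draws in
#' both), and returns the per-year distribution of differences
#' (`a` minus `b`). The pairing makes the contrast exactly antisymmetric
#' and sharpens the difference distribution.
#'
#' @inheritParams projectRichness
#' @param scnA,scnB two [scenario()]s with the same number of years.
#' @return a [RichnessDistribution-class] whose draws are differences.
#' @export
scenarioContrast <- function(fit, scnA, scnB, reps = 1, seed = 1,
                             draws = NULL) {
  if (scnA$years != scnB$years) stop("scenarios must share the same years")
  idx <- .paramIndices(fit)
  dp <- fit@covariates@dPrime
  K <- scnA$years
  if (K > fit@dims[["K"]])
    stop("scenario projects more years than the model was fitted to")
  rows <- .selectDraws(fit, draws)
  set.seed(seed)
  S <- length(dp)
  out <- matrix(0L, length(rows) * reps, K)
  for (a in seq_along(rows)) {
    x <- fit@draws[rows[a], ]
    ra <- .scenarioRates(x, idx, dp, scnA, fit@dims[["K"]])
    rb <- .scenarioRates(x, idx, dp, scnB, fit@dims[["K"]])
    for (b in seq_len(reps)) {
      u <- matrix(stats::runif(S * K), S, K)
      za <- simulateOccurrence(ra$psi1, ra$gamma[, seq_len(K), drop = FALSE],
                               ra$phi[, seq_len(K), drop = FALSE], u = u)
      zb <- simulateOccurrence(rb$psi1, rb$gamma[, seq_len(K), drop = FALSE],
                               rb$phi[, seq_len(K), drop = FALSE], u = u)
      out[(a - 1) * reps + b, ] <- colSums(za) - colSums(zb)
    }
  }
  new("RichnessDistribution", richness = out,
      scenario = list(a = scnA, b = scnB),
      summary = .richnessSummary(out))
}

#' Expected richness under a scenario, by analytic recursion
#'
#' For each posterior draw, computes `sum_i Psi[i, k]` without simulation.
#'
#' @inheritParams projectRichness
#' @return matrix draws x years of expected richness.
#' @export
expectedRichness <- function(fit, scn, draws = NULL) {
  idx <- .paramIndices(fit)
  dp <- fit@covariates@dPrime
  K <- scn$years
  if (K > fit@dims[["K"]])
    stop("scenario projects more years than the model was fitted to")
  rows <- .selectDraws(fit, draws)
  out <- matrix(NA_real_, length(rows), K)
  for (a in seq_along(rows)) {
    rates <- .scenarioRates(fit@draws[rows[a], ], idx, dp, scn, fit@dims[["K"]])
    psi <- occupancyTrajectory(rates$psi1,
                               rates$gamma[, seq_len(K), drop = FALSE],
                               rates$phi[, seq_len(K), drop = FALSE])
    out[a, ] <- colSums(psi)
  }
  out
}
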
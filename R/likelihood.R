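#' Parameter set for the dynamic occupancy model
#'
#' Bundles and validates every parameter of the model: species-specific
#' intercepts for initial occurrence (`psi1_0`), colonisation (`gamma_0`),
#' persistence (`phi_0`) and detection (`p_0`); the five community slopes of
#' each ecological linear predictor (order: d', restoration, woody,
#' d' x restoration, d' x woody); year offsets on colonisation, persistence
#' and detection with the first year pinned at 0 for identifiability; and
#' the detection parameters (degree slope `p_1`, species phenology `p_2`,
#' `p_3`, survey-flower slope `p_4`).
#'
#' @param psi1_0,gamma_0,phi_0,p_0,p_2,p_3 numeric vectors, one entry per
#'   species.
#' @param psi1,gamma,phi numeric length-5 community slope vectors.
#' @param gamma_year,phi_year,p_5 numeric length-K year offsets, first
#'   element 0.
#' @param p_1,p_4 scalars.
#' @return a validated list of class `occupancyParams`.
#' @export
occupancyParams <- function(psi1_0, psi1, gamma_0, gamma, gamma_year,
                            phi_0, phi, phi_year,
                            p_0, p_1, p_2, p_3, p_4, p_5) {
  S <- length(psi1_0)
  K <- length(gamma_year)
  stopifnot(length(gamma_0) == S, length(phi_0) == S, length(p_0) == S,
            length(p_2) == S, length(p_3) == S,
            length(psi1) == 5, length(gamma) == 5, length(phi) == 5,
            length(phi_year) == K, length(p_5) == K,
            length(p_1) == 1, length(p_4) == 1)
  if (gamma_year[1] != 0 || phi_year[1] != 0 || p_5[1] != 0)
    stop("year offsets must have the first year pinned at 0")
  structure(list(psi1_0 = psi1_0, psi1 = psi1, gamma_0 = gamma_0,
                 gamma = gamma, gamma_year = gamma_year, phi_0 = phi_0,
                 phi = phi, phi_year = phi_year, p_0 = p_0, p_1 = p_1,
                 p_2 = p_2, p_3 = p_3, p_4 = p_4, p_5 = p_5),
            class = "occupancyParams")
}

# canonical structures consumed by the C++ engine
.canonicalParams <- function(params) {
  list(sp = cbind(params$psi1_0, params$gamma_0, params$phi_0,
                  params$p_0, params$p_2, params$p_3),
       comm = c(params$psi1, params$gamma, params$phi, params$p_1, params$p_4),
       gamma_year = params$gamma_year, phi_year = params$phi_year,
       p_year = params$p_5,
       hyper_mu = rep(0, 6), hyper_sigma = rep(1, 6))
}

#' Initial occurrence probabilities
#'
#' Inverse-logit of the first-year linear predictor
#' `psi1_0[i] + psi1_1 d'_i + psi1_2 restored_j + psi1_3 woody_j1 +
#'  psi1_4 d'_i restored_j + psi1_5 d'_i woody_j1` for every species x site.
#'
#' @param params an [occupancyParams()] list.
#' @param covs a [CovariateBundle-class].
#' @return species x site probability matrix.
#' @export
initialOccupancyProb <- function(params, covs) {
  .ecoProb(params$psi1_0, params$psi1, 0, covs, covs@woody[, 1])
}

#' @rdname initialOccupancyProb
#' @param year year index `k >= 2` (colonisation/persistence act on the
#'   transition into year `k`).
#' @export
colonizationProb <- function(params, covs, year) {
  if (year < 2) stop("colonisation is defined for year >= 2")
  .ecoProb(params$gamma_0, params$gamma, params$gamma_year[year], covs,
           covs@woody[, year])
}

#' @rdname initialOccupancyProb
#' @export
persistenceProb <- function(params, covs, year) {
  if (year < 2) stop("persistence is defined for year >= 2")
  # woody is lagged: persistence into year k responds to resources in k-1
  .ecoProb(params$phi_0, params$phi, params$phi_year[year], covs,
           covs@woody[, year - 1])
}

.ecoProb <- function(intercepts, slopes, yearOffset, covs, w) {
  d <- covs@dPrime; r <- covs@restored
  lin <- outer(intercepts + slopes[1] * d, rep(1, length(r))) +
    rep(slopes[2] * r + slopes[3] * w + yearOffset, each = length(d)) +
    outer(slopes[4] * d, r) + outer(slopes[5] * d, w)
  stats::plogis(lin)
}

#' Survey detection probabilities
#'
#' Inverse-logit of
#' `p_0[i] + p_1 degree_i + p_2[i] date + p_3[i] date^2 + p_4 flowers +
#'  p_5[k]` for every cell of the detection array. Values at masked
#' (unconducted) surveys are returned but carry no meaning.
#'
#' @inheritParams initialOccupancyProb
#' @param darr a [DetectionArray-class] providing the standardised date and
#'   floral-abundance tensors.
#' @return species x site x year x survey probability array.
#' @export
detectionProbability <- function(params, covs, darr) {
  .detProbArray(params, covs@degree, darr@date, darr@flowers)
}

.detProbArray <- function(params, degree, dateArr, flowersArr) {
  S <- length(params$p_0)
  dims <- dim(dateArr)
  dt <- as.vector(dateArr)
  base <- params$p_4 * as.vector(flowersArr) +
    rep(params$p_5[rep(seq_len(dims[2]), each = dims[1])],
        times = dims[3])  # p_5[k] over the (j,k,l) grid
  lin <- outer(params$p_0 + params$p_1 * degree, rep(1, length(dt))) +
    outer(params$p_2, dt) + outer(params$p_3, dt^2) +
    rep(base, each = S)
  array(stats::plogis(lin), c(S, dims))
}

#' One step of the occupancy recursion
#'
#' `psi_next = phi * psi_prev + gamma * (1 - psi_prev)`: a species present
#' with probability `psi_prev` persists with probability `phi`, otherwise
#' the site is colonised with probability `gamma`. Vectorised elementwise.
#'
#' @param psiPrev,phi,gamma probabilities in `[0, 1]`.
#' @return occupancy probability for the next year.
#' @examples
#' occupancyRecursion(0.4, phi = 0.7, gamma = 0.2)  # 0.40
#' @export
occupancyRecursion <- function(psiPrev, phi, gamma) {
  args <- c(psiPrev, phi, gamma)
  if (any(args < 0 | args > 1, na.rm = TRUE))
    stop("occupancyRecursion arguments must lie in [0, 1]")
  phi * psiPrev + gamma * (1 - psiPrev)
}

#' Marginal log-likelihood of one species' history at one site
#'
#' Sums the likelihood over both latent yearly occurrence sequences with a
#' log-domain forward recursion over the two-state chain. Emissions are
#' Bernoulli products over the conducted surveys of a year: an occupied
#' year emits each detection with its survey-specific probability; an
#' unoccupied year emits all-zero histories with probability one and
#' anything else with probability zero.
#'
#' This is the reference R implementation; the fitting engine uses an
#' equivalent compiled version (see [totalLoglik()]).
#'
#' @param v 0/1 matrix, years x surveys.
#' @param observed logical matrix, years x surveys; `FALSE` marks surveys
#'   not conducted.
#' @param psi1 first-year occupancy probability.
#' @param gamma,phi length-K vectors of colonisation/persistence
#'   probabilities (entries for years >= 2 are used).
#' @param p detection probability matrix, years x surveys.
#' @return scalar log-likelihood.
#' @export
marginalLoglik <- function(v, observed, psi1, gamma, phi, p) {
  K <- nrow(v)
  if (!all(dim(v) == dim(observed)) || !all(dim(v) == dim(p)))
    stop("v, observed and p must share years x surveys dimensions")
  if (length(gamma) < K || length(phi) < K)
    stop("gamma and phi must have one entry per year")
  emis <- function(k) {
    use <- observed[k, ]
    vi <- v[k, use]; pi <- p[k, use]
    e1 <- sum(log(ifelse(vi == 1, pi, 1 - pi)))
    e0 <- if (any(vi == 1)) -Inf else 0
    c(e0, e1)
  }
  lse2 <- function(a, b) {
    if (a == -Inf) return(b)
    if (b == -Inf) return(a)
    m <- max(a, b)
    m + log1p(exp(-abs(a - b)))
  }
  e <- emis(1)
  la0 <- log(1 - psi1) + e[1]
  la1 <- log(psi1) + e[2]
  if (K > 1) for (k in 2:K) {
    e <- emis(k)
    n1 <- lse2(la1 + log(phi[k]), la0 + log(gamma[k])) + e[2]
    n0 <- lse2(la1 + log(1 - phi[k]), la0 + log(1 - gamma[k])) + e[1]
    la1 <- n1; la0 <- n0
  }
  lse2(la0, la1)
}

#' Total marginalised log-likelihood of a detection array
#'
#' Sum of [marginalLoglik()] over all species and sites, computed by the
#' compiled forward recursion.
#'
#' @inheritParams detectionProbability
#' @param bySpecies if `TRUE`, return the per-species site sums instead of
#'   the grand total.
#' @return scalar (or named per-species vector) log-likelihood.
#' @export
totalLoglik <- function(darr, params, covs, bySpecies = FALSE) {
  covs <- .alignCovariates(covs, darr)
  ll <- occuLoglikCpp(darr@V, array(as.integer(darr@mask), dim(darr@mask)),
                      covs@restored,
                      covs@woody[, seq_len(nYears(darr)), drop = FALSE],
                      as.numeric(darr@date), as.numeric(darr@flowers),
                      covs@dPrime, covs@degree,
                      as.integer(dim(darr@V)), .canonicalParams(params),
                      FALSE)
  if (any(is.nan(ll)))
    stop("log-likelihood is NaN for species ",
         paste(speciesIds(darr)[is.nan(ll)], collapse = ", "))
  if (bySpecies) stats::setNames(ll, speciesIds(darr)) else sum(ll)
}
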
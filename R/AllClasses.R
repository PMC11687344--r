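#' @import methods
NULL

#' Binary detection array with survey covariates
#'
#' Container for the detection/non-detection tensor `V[i, j, k, l]`
#' (species x site x year x survey) together with the survey mask and the
#' standardised per-survey covariates (day of year and total log floral
#' abundance) consumed by the occupancy likelihood. Built from long-format
#' survey records with [buildDetectionArray()]; species never detected
#' anywhere are excluded (they carry no information under a model that
#' conditions on the observed community) and listed in `droppedSpecies()`.
#'
#' @slot V integer array, species x site x year x survey, 0/1 (0 at
#'   unobserved cells).
#' @slot mask logical array, site x year x survey; `TRUE` where a survey was
#'   conducted. The mask is shared by all species.
#' @slot date,flowers numeric arrays, site x year x survey, z-score
#'   standardised day of year and `log1p` total floral count; 0 at
#'   unobserved cells.
#' @slot species,sites character vectors of retained species and site ids.
#' @slot dropped character vector of species removed for having no
#'   detections.
#' @slot standardizers named list of the `mean`/`sd` pairs used for `date`
#'   and `flowers`, kept so scenarios can be expressed on the raw scale.
#'
#' @seealso [buildDetectionArray()], [covariateBundle()]
#' @export
setClass("DetectionArray",
  representation(
    V = "array", mask = "array", date = "array", flowers = "array",
    species = "character", sites = "character", dropped = "character",
    standardizers = "list"
  )
)

setValidity("DetectionArray", function(object) {
  d <- dim(object@V)
  msg <- character()
  if (length(d) != 4L) msg <- c(msg, "V must be a 4-d array [species, site, year, survey]")
  if (length(object@species) != d[1]) msg <- c(msg, "length(species) must equal dim(V)[1]")
  if (length(object@sites) != d[2]) msg <- c(msg, "length(sites) must equal dim(V)[2]")
  if (!identical(dim(object@mask), d[-1])) msg <- c(msg, "mask must be [site, year, survey]")
  if (!identical(dim(object@date), d[-1]) || !identical(dim(object@flowers), d[-1]))
    msg <- c(msg, "date and flowers must be [site, year, survey]")
  obs <- rep(object@mask, each = d[1])
  v <- object@V[obs]
  if (length(v) && !all(v %in% c(0L, 1L))) msg <- c(msg, "V must be binary at observed cells")
  if (any(object@V[!obs] != 0L)) msg <- c(msg, "V must be 0 at masked cells")
  if (d[1] > 0) {
    det <- apply(object@V, 1, sum)
    if (any(det == 0)) {
      msg <- c(msg, paste0("species with zero detections must be dropped: ",
                           paste(object@species[det == 0], collapse = ", ")))
    }
  }
  if (length(msg)) msg else TRUE
})

#' Species- and site-level covariates for the occupancy model
#'
#' Holds the standardised ecological covariates entering the linear
#' predictors of initial occurrence, colonisation, persistence and
#' detection: specialisation d' and (log) degree per species, the binary
#' restoration flag per site, and the yearly woody floral abundance summary
#' per site. Restoration is a binary factor and is deliberately left
#' unstandardised.
#'
#' @slot dPrime,degree named numeric vectors (one per species), z-scored;
#'   degree is log-transformed before standardisation because it is
#'   right-skewed.
#' @slot restored named numeric vector of 0/1 site flags.
#' @slot woody numeric matrix, site x year, standardised mean `log1p` woody
#'   floral counts.
#' @slot standardizers list of the standardisers applied (`dprime`,
#'   `degree`, `woody`).
#' @export
setClass("CovariateBundle",
  representation(
    dPrime = "numeric", degree = "numeric", restored = "numeric",
    woody = "matrix", standardizers = "list"
  )
)

setValidity("CovariateBundle", function(object) {
  msg <- character()
  if (length(object@dPrime) != length(object@degree))
    msg <- c(msg, "dPrime and degree must have one entry per species")
  if (is.null(names(object@dPrime)) || is.null(names(object@restored)))
    msg <- c(msg, "dPrime and restored must be named by species/site id")
  if (!all(object@restored %in% c(0, 1)))
    msg <- c(msg, "restored must be binary 0/1")
  if (nrow(object@woody) != length(object@restored))
    msg <- c(msg, "woody must have one row per site")
  if (length(msg)) msg else TRUE
})

#' Plant-genus by pollinator interaction network
#'
#' A non-negative count matrix `A[i, g]` of interactions between pollinator
#' species (rows) and plant genera (columns). Species with no interactions
#' are excluded at construction; genera receiving no interactions are
#' dropped (their availability is zero).
#'
#' @slot counts integer-valued matrix with species ids as rownames and genus
#'   names as colnames.
#' @seealso [interactionNetwork()], [specializationScores()]
#' @export
setClass("InteractionNetwork", representation(counts = "matrix"))

setValidity("InteractionNetwork", function(object) {
  A <- object@counts
  msg <- character()
  if (is.null(rownames(A)) || is.null(colnames(A)))
    msg <- c(msg, "counts must have species rownames and genus colnames")
  if (any(A < 0) || any(A != round(A))) msg <- c(msg, "counts must be non-negative integers")
  if (nrow(A) && any(rowSums(A) == 0)) msg <- c(msg, "species with no interactions must be excluded")
  if (ncol(A) && any(colSums(A) == 0)) msg <- c(msg, "genera with no interactions must be excluded")
  if (sum(A) == 0) msg <- c(msg, "network is empty")
  if (length(msg)) msg else TRUE
})

#' Convergence report for an MCMC fit
#'
#' Records the three convergence gates used throughout the package: maximum
#' split R-hat below 1.05, minimum effective-sample-size ratio (ESS divided
#' by stored steps) above 0.1, and zero divergent transitions. `converged`
#' is `TRUE` exactly when all three hold. The random-walk sampler used here
#' has no divergences by construction, so `nDivergent` is informative only
#' for externally supplied diagnostics.
#'
#' @slot converged logical.
#' @slot maxRhat,minEssRatio numeric scalars.
#' @slot nDivergent integer.
#' @seealso [fitReport()]
#' @export
setClass("FitReport",
  representation(converged = "logical", maxRhat = "numeric",
                 minEssRatio = "numeric", nDivergent = "integer")
)

setValidity("FitReport", function(object) {
  ok <- object@maxRhat < 1.05 && object@minEssRatio > 0.1 && object@nDivergent == 0L
  if (identical(object@converged, ok)) TRUE else
    "converged flag inconsistent with the diagnostic gates"
})

#' Posterior sample from the dynamic occupancy model
#'
#' @slot draws numeric matrix of posterior draws (rows) by named parameters
#'   (columns), concatenated across chains.
#' @slot chain integer vector assigning each row to its chain.
#' @slot report a [FitReport-class] with the convergence gates.
#' @slot covariates the [CovariateBundle-class] the model was fitted with.
#' @slot dims named integer vector (S, J, K, L).
#' @slot variant `"community"` (d'-based slopes of the core model) or
#'   `"randomSlopes"` (species-specific ecological slopes).
#' @slot config list echoing iterations, warmup, chains, seed and priors.
#' @export
setClass("OccupancyFit",
  representation(draws = "matrix", chain = "integer", report = "FitReport",
                 covariates = "CovariateBundle", dims = "integer",
                 variant = "character", config = "list")
)

#' Posterior sample from the pollen-limitation logistic model
#'
#' @slot draws,chain,report as in [OccupancyFit-class].
#' @slot sites character vector of site ids.
#' @slot restored numeric 0/1 per site.
#' @slot nPairs integer vector: retained pair count per site.
#' @slot config list of sampler settings.
#' @export
setClass("PollenFit",
  representation(draws = "matrix", chain = "integer", report = "FitReport",
                 sites = "character", restored = "numeric",
                 nPairs = "integer", config = "list")
)

#' Posterior species-richness distribution under a covariate scenario
#'
#' @slot richness integer matrix of richness draws: one row per posterior
#'   draw x simulation rep, one column per year.
#' @slot scenario the scenario list the projection was run under.
#' @slot summary data.frame of per-year posterior mean and 50%/95% BCIs.
#' @export
setClass("RichnessDistribution",
  representation(richness = "matrix", scenario = "list", summary = "data.frame")
)
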
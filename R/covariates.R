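#' Assemble the ecological covariates for the occupancy model
#'
#' Matches specialisation scores, site restoration flags and yearly woody
#' floral summaries into one standardised bundle. Continuous covariates are
#' z-scored (degree on the log scale first, being right-skewed); restoration
#' stays a raw binary factor.
#'
#' @param scores data.frame with `species_id`, `d_prime`, `degree` (e.g.
#'   from [specializationScores()]).
#' @param sites data.frame with `site_id`, `restored`.
#' @param woody data.frame with `site_id`, `year_index`, `woody` (log-scale
#'   yearly summaries from [summarizeWoody()]).
#' @return a [CovariateBundle-class].
#' @export
covariateBundle <- function(scores, sites, woody) {
  for (col in c("species_id", "d_prime", "degree"))
    if (is.null(scores[[col]])) stop("scores is missing column ", col)
  for (col in c("site_id", "restored"))
    if (is.null(sites[[col]])) stop("sites is missing column ", col)
  for (col in c("site_id", "year_index", "woody"))
    if (is.null(woody[[col]])) stop("woody is missing column ", col)
  if (any(scores$degree < 1)) stop("degree must be a positive integer")

  ord <- order(scores$species_id)
  scores <- scores[ord, ]
  sites <- sites[order(sites$site_id), ]
  K <- max(woody$year_index)
  wmat <- matrix(NA_real_, nrow(sites), K,
                 dimnames = list(sites$site_id, NULL))
  wmat[cbind(match(woody$site_id, sites$site_id), woody$year_index)] <- woody$woody
  if (anyNA(wmat)) stop("woody summaries missing for some site-years")

  dpStd <- standardizeCovariate(scores$d_prime)
  degStd <- standardizeCovariate(log(scores$degree))
  wStd <- standardizeCovariate(as.vector(wmat))
  wmatStd <- matrix(wStd$values, nrow(sites), K,
                    dimnames = dimnames(wmat))

  dP <- dpStd$values; names(dP) <- scores$species_id
  dg <- degStd$values; names(dg) <- scores$species_id
  rs <- as.numeric(sites$restored); names(rs) <- sites$site_id

  new("CovariateBundle", dPrime = dP, degree = dg, restored = rs,
      woody = wmatStd,
      standardizers = list(dprime = dpStd$standardizer,
                           degree = degStd$standardizer,
                           woody = wStd$standardizer))
}

# align a CovariateBundle to the species/sites of a DetectionArray,
# erroring on anything unmatched
.alignCovariates <- function(covs, darr) {
  sp <- speciesIds(darr); st <- siteIds(darr)
  mSp <- match(sp, names(covs@dPrime))
  if (anyNA(mSp))
    stop("covariates missing for species: ",
         paste(utils::head(sp[is.na(mSp)], 5), collapse = ", "))
  mSt <- match(st, names(covs@restored))
  if (anyNA(mSt))
    stop("covariates missing for sites: ",
         paste(utils::head(st[is.na(mSt)], 5), collapse = ", "))
  if (ncol(covs@woody) < nYears(darr))
    stop("woody covariate has fewer years than the detection array")
  new("CovariateBundle",
      dPrime = covs@dPrime[mSp], degree = covs@degree[mSp],
      restored = covs@restored[mSt],
      woody = covs@woody[mSt, seq_len(nYears(darr)), drop = FALSE],
      standardizers = covs@standardizers)
}
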
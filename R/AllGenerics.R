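#' @rdname DetectionArray-class
#' @param object,x a `DetectionArray` (or other metaoccu object, see the
#'   method pages).
#' @export
setGeneric("nSpecies", function(x) standardGeneric("nSpecies"))

#' @rdname DetectionArray-class
#' @export
setGeneric("nSites", function(x) standardGeneric("nSites"))

#' @rdname DetectionArray-class
#' @export
setGeneric("nYears", function(x) standardGeneric("nYears"))

#' @rdname DetectionArray-class
#' @export
setGeneric("nSurveys", function(x) standardGeneric("nSurveys"))

#' @rdname DetectionArray-class
#' @export
setGeneric("detections", function(x) standardGeneric("detections"))

#' @rdname DetectionArray-class
#' @export
setGeneric("surveyMask", function(x) standardGeneric("surveyMask"))

#' @rdname DetectionArray-class
#' @export
setGeneric("speciesIds", function(x) standardGeneric("speciesIds"))

#' @rdname DetectionArray-class
#' @export
setGeneric("siteIds", function(x) standardGeneric("siteIds"))

#' @rdname DetectionArray-class
#' @export
setGeneric("droppedSpecies", function(x) standardGeneric("droppedSpecies"))

#' Interaction availability of each plant genus
#'
#' Availability is approximated as the share of all interactions in the
#' network received by each plant genus: `q_g = A_g / m` where `A_g` is the
#' genus column total and `m` the grand total. The vector sums to one.
#'
#' @param network an [InteractionNetwork-class].
#' @return named numeric vector over genera.
#' @export
setGeneric("availability", function(network) standardGeneric("availability"))

#' @rdname specializationScores
#' @export
setGeneric("specializationScores",
           function(network) standardGeneric("specializationScores"))

#' Extract posterior draws
#'
#' @param x a fitted model object.
#' @return numeric matrix, rows = draws, columns = named parameters.
#' @export
setGeneric("posteriorDraws", function(x) standardGeneric("posteriorDraws"))

#' Extract the convergence report of a fit
#'
#' @param x a fitted model object.
#' @return a [FitReport-class].
#' @export
setGeneric("convergence", function(x) standardGeneric("convergence"))

#' Summarise posterior draws of a fit
#'
#' @param x a fitted model object.
#' @param pars optional character vector of parameter names (defaults to
#'   the community-level parameters).
#' @return a data.frame with columns `name`, `mean`, `l50`, `u50`, `l95`,
#'   `u95`, `label`.
#' @export
setGeneric("summarizeFit", function(x, pars = NULL) standardGeneric("summarizeFit"))
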
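#' @rdname DetectionArray-class
#' @export
setMethod("nSpecies", "DetectionArray", function(x) dim(x@V)[1])
#' @rdname DetectionArray-class
#' @export
setMethod("nSites", "DetectionArray", function(x) dim(x@V)[2])
#' @rdname DetectionArray-class
#' @export
setMethod("nYears", "DetectionArray", function(x) dim(x@V)[3])
#' @rdname DetectionArray-class
#' @export
setMethod("nSurveys", "DetectionArray", function(x) dim(x@V)[4])
#' @rdname DetectionArray-class
#' @export
setMethod("detections", "DetectionArray", function(x) x@V)
#' @rdname DetectionArray-class
#' @export
setMethod("surveyMask", "DetectionArray", function(x) x@mask)
#' @rdname DetectionArray-class
#' @export
setMethod("speciesIds", "DetectionArray", function(x) x@species)
#' @rdname DetectionArray-class
#' @export
setMethod("siteIds", "DetectionArray", function(x) x@sites)
#' @rdname DetectionArray-class
#' @export
setMethod("droppedSpecies", "DetectionArray", function(x) x@dropped)

#' @rdname DetectionArray-class
#' @export
setMethod("show", "DetectionArray", function(object) {
  d <- dim(object@V)
  cat("DetectionArray:", d[1], "species x", d[2], "sites x", d[3],
      "years x", d[4], "surveys\n")
  cat("  surveys conducted:", sum(object@mask), "of", length(object@mask), "\n")
  cat("  detections:", sum(object@V), "\n")
  if (length(object@dropped))
    cat("  species dropped (never detected):", length(object@dropped), "\n")
})

#' @rdname InteractionNetwork-class
#' @param object an `InteractionNetwork`.
#' @export
setMethod("show", "InteractionNetwork", function(object) {
  A <- object@counts
  cat("InteractionNetwork:", nrow(A), "pollinator species x", ncol(A),
      "plant genera,", sum(A), "interactions\n")
})

#' @rdname DetectionArray-class
#' @export
setMethod("nSpecies", "InteractionNetwork", function(x) nrow(x@counts))

#' @rdname DetectionArray-class
#' @export
setMethod("nSpecies", "CovariateBundle", function(x) length(x@dPrime))
#' @rdname DetectionArray-class
#' @export
setMethod("nSites", "CovariateBundle", function(x) length(x@restored))

#' @rdname OccupancyFit-class
#' @param x,object an `OccupancyFit`.
#' @export
setMethod("posteriorDraws", "OccupancyFit", function(x) x@draws)
#' @rdname OccupancyFit-class
#' @export
setMethod("convergence", "OccupancyFit", function(x) x@report)
#' @rdname OccupancyFit-class
#' @export
setMethod("show", "OccupancyFit", function(object) {
  cat("OccupancyFit (", object@variant, " variant)\n", sep = "")
  cat("  data:", object@dims["S"], "species,", object@dims["J"], "sites,",
      object@dims["K"], "years,", object@dims["L"], "surveys\n")
  cat("  draws:", nrow(object@draws), "kept over",
      length(unique(object@chain)), "chains,", ncol(object@draws),
      "parameters\n")
  show(object@report)
})

#' @rdname PollenFit-class
#' @param x,object a `PollenFit`.
#' @export
setMethod("posteriorDraws", "PollenFit", function(x) x@draws)
#' @rdname PollenFit-class
#' @export
setMethod("convergence", "PollenFit", function(x) x@report)
#' @rdname PollenFit-class
#' @export
setMethod("show", "PollenFit", function(object) {
  cat("PollenFit:", length(object@sites), "sites,", sum(object@nPairs),
      "retained pairs\n")
  show(object@report)
})

#' @rdname FitReport-class
#' @param object a `FitReport`.
#' @export
setMethod("show", "FitReport", function(object) {
  cat(sprintf("  %s (max R-hat %.3f, min ESS ratio %.3f, divergences %d)\n",
              if (object@converged) "converged" else "NOT converged",
              object@maxRhat, object@minEssRatio, object@nDivergent))
})

#' @rdname RichnessDistribution-class
#' @param object a `RichnessDistribution`.
#' @export
setMethod("show", "RichnessDistribution", function(object) {
  cat("RichnessDistribution over", nrow(object@richness), "draws x",
      ncol(object@richness), "years\n")
  print(object@summary, row.names = FALSE)
})
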
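#' Z-score standardisation with an invertible record
#'
#' Centres and scales a covariate to mean 0 and (sample) standard deviation
#' 1, returning both the transformed values and the standardiser needed to
#' map scenario values back and forth. Binary design factors (e.g. the
#' restoration flag) are left out of standardisation by convention and
#' should not be passed here.
#'
#' @param x numeric vector with at least two distinct finite values.
#' @return list with elements `values` (standardised vector) and
#'   `standardizer` (named numeric `c(mean, sd)`).
#' @examples
#' s <- standardizeCovariate(c(1, 2, 3))
#' round(mean(s$values), 12)  # 0
#' sd(s$values)               # 1
#' @export
standardizeCovariate <- function(x) {
  if (!is.numeric(x)) stop("covariate must be numeric")
  x <- as.numeric(x)
  if (anyNA(x)) stop("covariate contains missing values")
  m <- mean(x)
  s <- stats::sd(x)
  if (!is.finite(s) || s == 0)
    stop("cannot standardize a constant covariate (sd = 0)")
  list(values = (x - m) / s, standardizer = c(mean = m, sd = s))
}

#' @rdname standardizeCovariate
#' @param std a standardizer as returned by [standardizeCovariate()].
#' @export
applyStandardizer <- function(x, std) (x - std[["mean"]]) / std[["sd"]]

#' @rdname standardizeCovariate
#' @export
invertStandardizer <- function(x, std) x * std[["sd"]] + std[["mean"]]
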
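#' Score paired control/supplemented flowers for pollen limitation
#'
#' For each pair, the seed ratio is control seeds divided by supplemented
#' seeds. Pairs are excluded when the supplemented flower did not fruit
#' (missing or zero seeds, which leaves the ratio undefined) or when the
#' control produced more than twice the supplemented seeds (implausible
#' pair, e.g. damage to the supplemented flower). Retained pairs are
#' classified pollen limited when the control yields less than 50% of the
#' supplemented seeds; a ratio of exactly 0.5 is not limited (strict
#' reading of the `< 50%` criterion).
#'
#' @param pairs data.frame with columns `site_id`, `plant_id`,
#'   `control_seeds`, `supplemented_seeds` (`NA` = supplemented flower did
#'   not fruit).
#' @return the input with added columns `ratio`, `excluded`, `reason`
#'   (`NA`, `"no fruit"` or `"control > 2x supplemented"`) and `limited`
#'   (0/1, `NA` when excluded).
#' @examples
#' scorePollenPairs(data.frame(site_id = "a", plant_id = 1:3,
#'                             control_seeds = c(30, 210, 40),
#'                             supplemented_seeds = c(100, 100, NA)))
#' @export
scorePollenPairs <- function(pairs) {
  need <- c("site_id", "plant_id", "control_seeds", "supplemented_seeds")
  missing <- setdiff(need, names(pairs))
  if (length(missing))
    stop("pairs are missing column(s): ", paste(missing, collapse = ", "))
  if (any(pairs$control_seeds < 0, na.rm = TRUE) ||
      any(pairs$supplemented_seeds < 0, na.rm = TRUE))
    stop("seed counts must be non-negative")

  noFruit <- is.na(pairs$supplemented_seeds) | pairs$supplemented_seeds == 0
  ratio <- ifelse(noFruit, NA_real_,
                  pairs$control_seeds / pairs$supplemented_seeds)
  tooHigh <- !noFruit & ratio > 2
  pairs$ratio <- ratio
  pairs$excluded <- noFruit | tooHigh
  pairs$reason <- ifelse(noFruit, "no fruit",
                         ifelse(tooHigh, "control > 2x supplemented",
                                NA_character_))
  pairs$limited <- ifelse(pairs$excluded, NA_integer_,
                          as.integer(ratio < 0.5))
  pairs
}

#' Probability of pollen limitation from a logit-scale intercept
#'
#' @param x logit-scale value (e.g. the posterior mean site intercept).
#' @return inverse-logit probability.
#' @examples
#' limitationProbability(-0.79)  # ~0.31
#' @export
limitationProbability <- function(x) stats::plogis(x)

#' @rdname fitPollenModel
#' @export
pollenPriors <- function(slope_sd = 2, hypermean_sd = 2, hypersd_scale = 1) {
  stopifnot(slope_sd > 0, hypermean_sd > 0, hypersd_scale > 0)
  list(slope_sd = slope_sd, hypermean_sd = hypermean_sd,
       hypersd_scale = hypersd_scale)
}

#' Fit the site-random-intercept pollen-limitation model
#'
#' Bayesian logistic regression for the probability that a retained pair is
#' pollen limited: `logit(theta_j) = beta0_j + beta1 * restored_j` with
#' site intercepts `beta0_j ~ Normal(mu_beta0, sigma_beta0)`. Priors are
#' weakly informative (`beta1`, `mu_beta0 ~ Normal(0, 2)`;
#' `sigma_beta0 ~ half-Normal(0, 1)`), which keeps estimates finite even
#' under complete separation at a site. Sampled by the same adaptive
#' random-walk scheme as the occupancy model (site intercepts updated in
#' parallel against their independent site likelihoods, hypermean by Gibbs).
#'
#' @param pairs scored pairs from [scorePollenPairs()] (excluded pairs are
#'   dropped here).
#' @param sites data.frame with `site_id`, `restored` for every site with
#'   retained pairs.
#' @param priors from [pollenPriors()].
#' @param iterations,warmup,chains,seed sampler configuration.
#' @return a [PollenFit-class].
#' @export
fitPollenModel <- function(pairs, sites, priors = pollenPriors(),
                           iterations = 4000, warmup = floor(iterations / 2),
                           chains = 3, seed = 1) {
  if (is.null(pairs$limited)) pairs <- scorePollenPairs(pairs)
  keep <- pairs[!pairs$excluded, , drop = FALSE]
  if (!nrow(keep)) stop("all pairs were excluded; nothing to fit")
  sid <- sort(unique(keep$site_id))
  if (length(sid) < 2) stop("need retained pairs from at least 2 sites")
  m <- match(sid, sites$site_id)
  if (anyNA(m)) stop("sites table is missing: ",
                     paste(sid[is.na(m)], collapse = ", "))
  r <- as.numeric(sites$restored[m])
  y <- as.numeric(tapply(keep$limited, factor(keep$site_id, levels = sid), sum))
  n <- as.numeric(table(factor(keep$site_id, levels = sid)))
  J <- length(sid)

  sitesLik <- function(b0, b1) {
    stats::dbinom(y, n, stats::plogis(b0 + b1 * r), log = TRUE)
  }
  kept <- iterations - warmup
  chainDraws <- vector("list", chains)
  for (ch in seq_len(chains)) {
    set.seed((seed + 7919L * (ch - 1L)) %% .Machine$integer.max)
    b0 <- stats::rnorm(J, 0, 0.5); b1 <- stats::rnorm(1, 0, 0.25)
    mu <- stats::rnorm(1, 0, 0.5); sig <- stats::runif(1, 0.5, 1.5)
    ll <- sitesLik(b0, b1)
    lsB0 <- rep(log(0.8), J); lsB1 <- log(0.5); lsSig <- log(0.5)
    acB0 <- rep(0L, J); acB1 <- 0L; acSig <- 0L; batchNum <- 0
    out <- matrix(NA_real_, kept, J + 3)
    for (t in seq_len(iterations)) {
      # site intercepts: independent slices, updated in parallel
      prop <- b0 + exp(lsB0) * stats::rnorm(J)
      llP <- sitesLik(prop, b1)
      lr <- llP - ll + stats::dnorm(prop, mu, sig, log = TRUE) -
        stats::dnorm(b0, mu, sig, log = TRUE)
      acc <- log(stats::runif(J)) < lr
      b0[acc] <- prop[acc]; ll[acc] <- llP[acc]; acB0 <- acB0 + acc
      # restoration effect
      propB1 <- b1 + exp(lsB1) * stats::rnorm(1)
      llP <- sitesLik(b0, propB1)
      lr <- sum(llP) - sum(ll) +
        stats::dnorm(propB1, 0, priors$slope_sd, log = TRUE) -
        stats::dnorm(b1, 0, priors$slope_sd, log = TRUE)
      if (log(stats::runif(1)) < lr) { b1 <- propB1; ll <- llP; acB1 <- acB1 + 1L }
      # hypermean (conjugate) and hyper-sd (log-scale Metropolis)
      prec <- J / sig^2 + 1 / priors$hypermean_sd^2
      mu <- stats::rnorm(1, (sum(b0) / sig^2) / prec, sqrt(1 / prec))
      propS <- sig * exp(exp(lsSig) * stats::rnorm(1))
      lr <- sum(stats::dnorm(b0, mu, propS, log = TRUE)) -
        sum(stats::dnorm(b0, mu, sig, log = TRUE)) -
        0.5 * (propS^2 - sig^2) / priors$hypersd_scale^2 +
        log(propS) - log(sig)
      if (log(stats::runif(1)) < lr) { sig <- propS; acSig <- acSig + 1L }

      if (t <= warmup && t %% 50 == 0) {
        batchNum <- batchNum + 1
        d <- min(0.1, 1 / sqrt(batchNum))
        lsB0 <- lsB0 + ifelse(acB0 > 22, d, -d)
        lsB1 <- lsB1 + if (acB1 > 22) d else -d
        lsSig <- lsSig + if (acSig > 22) d else -d
        acB0 <- rep(0L, J); acB1 <- 0L; acSig <- 0L
      }
      if (t > warmup) out[t - warmup, ] <- c(b0, mu, sig, b1)
    }
    colnames(out) <- c(paste0("beta_0[", sid, "]"), "mu_beta0",
                       "sigma_beta0", "beta_1")
    chainDraws[[ch]] <- out
  }
  diag <- .mcmcDiagnostics(chainDraws)
  report <- fitReport(diag$maxRhat, diag$minEssRatio, 0L)
  if (!report@converged)
    warning(sprintf("pollen fit did not pass convergence gates (max R-hat %.3f)",
                    diag$maxRhat))
  new("PollenFit", draws = do.call(rbind, chainDraws),
      chain = rep(seq_len(chains), each = kept), report = report,
      sites = sid, restored = r, nPairs = as.integer(n),
      config = list(iterations = iterations, warmup = warmup,
                    chains = chains, seed = seed, priors = priors))
}
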
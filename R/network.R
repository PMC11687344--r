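#' Build a pollinator x plant-genus interaction network
#'
#' Aggregates an interaction edge list (one row per observed pollinator x
#' plant-genus interaction batch, with a count) into the count matrix
#' `A[i, g]`. Records from different sources (own surveys, regional
#' datasets) are simply pooled; an optional `source` column is accepted and
#' ignored beyond provenance. Species with no interactions and genera
#' receiving none are dropped.
#'
#' @param edges data.frame with columns `pollinator_species`, `plant_genus`,
#'   `count` (and optionally `source`), or a path to such a CSV.
#' @return an [InteractionNetwork-class].
#' @export
interactionNetwork <- function(edges) {
  if (is.character(edges)) edges <- utils::read.csv(edges, stringsAsFactors = FALSE)
  need <- c("pollinator_species", "plant_genus", "count")
  missing <- setdiff(need, names(edges))
  if (length(missing))
    stop("interaction edge list is missing column(s): ",
         paste(missing, collapse = ", "))
  if (any(edges$count < 0)) stop("interaction counts must be non-negative")
  A <- tapply(edges$count,
              list(factor(edges$pollinator_species),
                   factor(edges$plant_genus)),
              sum, default = 0)
  A <- A[rowSums(A) > 0, colSums(A) > 0, drop = FALSE]
  storage.mode(A) <- "double"
  new("InteractionNetwork", counts = A)
}

#' @rdname availability
#' @export
setMethod("availability", "InteractionNetwork", function(network) {
  A <- network@counts
  colSums(A) / sum(A)
})

#' Kullback-Leibler specialisation of one interaction profile
#'
#' The raw specialisation `d` of a consumer is the Kullback-Leibler
#' divergence of its interaction-frequency distribution `p'` from the
#' availability distribution `q`:
#' `d = sum_g p'_g * ln(p'_g / q_g)`, summing over the genera the species
#' actually uses. Natural logarithms throughout.
#'
#' @param counts non-negative interaction counts of one species over genera.
#' @param q availability vector over the same genera (sums to 1; must be
#'   positive wherever `counts > 0`).
#' @return non-negative scalar `d`.
#' @export
klSpecialization <- function(counts, q) {
  ai <- sum(counts)
  if (ai <= 0) stop("species has no interactions (row total is zero)")
  if (length(counts) != length(q)) stop("counts and q differ in length")
  use <- counts > 0
  if (any(q[use] <= 0)) stop("q must be positive on genera the species uses")
  p <- counts[use] / ai
  sum(p * log(p / q[use]))
}

#' Normalisation bounds for Bluethgen's d
#'
#' `dMax = ln(m / A_i)` is attained by exclusive use of a genus whose total
#' equals the species' own interaction total. `dMin` is the smallest `d`
#' achievable by allocating the species' `A_i` interactions (integer units)
#' across genera, found by largest-remainder proportional allocation
#' followed by single-unit local swaps until no swap lowers `d`; ties in
#' the largest-remainder step go to the lower genus index, making the
#' search deterministic.
#'
#' @param counts interaction counts of one species over genera.
#' @param network the [InteractionNetwork-class] the species belongs to
#'   (fixes `q` and the grand total `m`).
#' @return named numeric `c(dMin, dMax)`.
#' @export
dExtremes <- function(counts, network) {
  ai <- sum(counts)
  if (ai < 1) stop("species must have at least one interaction")
  m <- sum(network@counts)
  q <- availability(network)
  dMax <- log(m / ai)

  # largest-remainder start
  raw <- ai * q
  alloc <- floor(raw)
  rem <- ai - sum(alloc)
  if (rem > 0) {
    ord <- order(-(raw - alloc), seq_along(q))
    alloc[ord[seq_len(rem)]] <- alloc[ord[seq_len(rem)]] + 1
  }
  dOf <- function(a) {
    use <- a > 0
    p <- a[use] / ai
    sum(p * log(p / q[use]))
  }
  cur <- dOf(alloc)
  repeat {
    best <- cur; bestFrom <- 0L; bestTo <- 0L
    for (g in which(alloc > 0)) {
      for (h in seq_along(alloc)) {
        if (h == g) next
        a2 <- alloc
        a2[g] <- a2[g] - 1; a2[h] <- a2[h] + 1
        d2 <- dOf(a2)
        if (d2 < best - 1e-15) { best <- d2; bestFrom <- g; bestTo <- h }
      }
    }
    if (bestFrom == 0L) break
    alloc[bestFrom] <- alloc[bestFrom] - 1
    alloc[bestTo] <- alloc[bestTo] + 1
    cur <- best
  }
  # the observed allocation is itself feasible, so dMin never exceeds it
  dMin <- min(cur, dOf(counts))
  c(dMin = dMin, dMax = dMax)
}

#' Standardised specialisation d' and degree per pollinator species
#'
#' For every species in the network, computes the raw Kullback-Leibler
#' specialisation `d` against genus availability, its attainable extremes,
#' the standardised score `d' = (d - dMin) / (dMax - dMin)` in `[0, 1]`,
#' and the degree (number of genera the species interacts with). A single
#' score per species is computed from the whole pooled network. In the
#' degenerate case `dMax = dMin` (e.g. a one-genus network offering no
#' choice) `d'` is defined as 0.
#'
#' @param network an [InteractionNetwork-class].
#' @return data.frame with columns `species_id`, `degree`, `d`, `d_min`,
#'   `d_max`, `d_prime`.
#' @export
setMethod("specializationScores", "InteractionNetwork", function(network) {
  A <- network@counts
  q <- availability(network)
  res <- lapply(seq_len(nrow(A)), function(i) {
    counts <- A[i, ]
    d <- klSpecialization(counts, q)
    ex <- dExtremes(counts, network)
    dp <- if (ex["dMax"] - ex["dMin"] < 1e-12) 0
          else (d - ex["dMin"]) / (ex["dMax"] - ex["dMin"])
    data.frame(species_id = rownames(A)[i],
               degree = sum(counts > 0),
               d = d, d_min = unname(ex["dMin"]), d_max = unname(ex["dMax"]),
               d_prime = unname(dp))
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
})
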
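# Pool distributions: a metabolite pool's labeling state is a probability
# distribution over binary label vectors (one bit per carbon). With at most
# 6 carbons there are <= 64 states, so distributions are dense numeric
# vectors indexed by the bit pattern (state index = 1 + sum over labeled
# carbons i of 2^(i-1)); all carbon-fate maps are exact pushforwards.

#' Create a pool labeling distribution
#'
#' @param carbons Number of carbons in the pool (1-6).
#' @param probs Optional numeric vector of length `2^carbons` (state
#'   probabilities; state index 1 is the fully unlabeled molecule). Defaults
#'   to a fully unlabeled pool.
#' @return Object of class `pool_dist`: numeric vector of length
#'   `2^carbons` with attribute `carbons`.
#' @export
pool_dist <- function(carbons, probs = NULL) {
  carbons <- as.integer(carbons)
  stopifnot(carbons >= 1L, carbons <= 6L)
  n <- 2L^carbons
  if (is.null(probs)) {
    probs <- c(1, rep(0, n - 1L))
  }
  probs <- as.numeric(probs)
  if (length(probs) != n) stop("probs must have length 2^carbons", call. = FALSE)
  if (any(probs < -1e-12)) stop("negative probability", call. = FALSE)
  if (abs(sum(probs) - 1) > 1e-9) stop("probabilities must sum to 1", call. = FALSE)
  structure(pmax(probs, 0), carbons = carbons, class = "pool_dist")
}

state_index <- function(positions, carbons) {
  if (length(positions) == 0L) return(1L)
  stopifnot(all(positions >= 1L), all(positions <= carbons))
  1L + sum(2L^(as.integer(positions) - 1L))
}

state_positions <- function(index, carbons) {
  which(bitwAnd(index - 1L, bitwShiftL(1L, 0:(carbons - 1L))) != 0L)
}

#' Distribution concentrated on given labeling patterns
#'
#' @param carbons Pool carbon count.
#' @param patterns List of integer position vectors (use `integer(0)` for the
#'   unlabeled state).
#' @param probs Probabilities, one per pattern; any remaining mass goes to the
#'   unlabeled state.
#' @export
pool_dist_from_patterns <- function(carbons, patterns, probs) {
  stopifnot(length(patterns) == length(probs))
  p <- rep(0, 2L^carbons)
  for (i in seq_along(patterns)) {
    p[state_index(patterns[[i]], carbons)] <-
      p[state_index(patterns[[i]], carbons)] + probs[i]
  }
  rest <- 1 - sum(probs)
  if (rest < -1e-9) stop("pattern probabilities exceed 1", call. = FALSE)
  p[1L] <- p[1L] + max(rest, 0)
  pool_dist(carbons, p)
}

#' Probability of an exact labeling pattern
#' @param dist A `pool_dist`.
#' @param positions Integer vector of labeled carbon positions.
#' @export
pattern_prob <- function(dist, positions) {
  unname(dist[state_index(positions, attr(dist, "carbons"))])
}

# Pushforward through a carbon-fate map. `map` is an integer vector of length
# `in_carbons`: map[i] = destination carbon of input carbon i, or NA if the
# carbon is lost (CO2 etc.). Probability mass is conserved.
apply_carbon_map <- function(dist, map, out_carbons) {
  cin <- attr(dist, "carbons")
  stopifnot(length(map) == cin)
  n_in <- 2L^cin
  out <- rep(0, 2L^out_carbons)
  for (s in seq_len(n_in)) {
    if (dist[s] == 0) next
    pos <- state_positions(s, cin)
    dest <- map[pos]
    dest <- dest[!is.na(dest)]
    out[state_index(dest, out_carbons)] <- out[state_index(dest, out_carbons)] + dist[s]
  }
  pool_dist(out_carbons, out)
}

# Mixture of distributions over the same carbon count.
mix_dists <- function(dists, weights) {
  stopifnot(length(dists) == length(weights), abs(sum(weights) - 1) < 1e-9)
  carbons <- attr(dists[[1L]], "carbons")
  p <- rep(0, 2L^carbons)
  for (i in seq_along(dists)) {
    stopifnot(attr(dists[[i]], "carbons") == carbons)
    p <- p + weights[i] * as.numeric(dists[[i]])
  }
  pool_dist(carbons, p)
}

#' Expected number of 13C atoms in a pool
#' @param dist A `pool_dist`.
#' @export
expected_label_count <- function(dist) {
  carbons <- attr(dist, "carbons")
  counts <- vapply(seq_along(dist),
                   function(s) length(state_positions(s, carbons)), integer(1))
  sum(as.numeric(dist) * counts)
}

# End-to-end carbon reversal (C1<->Cn, C2<->Cn-1, ...); used for the
# succinate/fumarate symmetry checks.
reverse_dist <- function(dist) {
  carbons <- attr(dist, "carbons")
  apply_carbon_map(dist, rev(seq_len(carbons)), carbons)
}
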
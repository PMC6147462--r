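# Independent brute-force oracle for label propagation.
#
# Molecules are logical vectors (one element per carbon, TRUE = 13C).
# Carbon fates are re-derived here from textbook stereochemistry by explicit
# atom bookkeeping, independent of the package's distribution pushforwards:
# every stochastic choice (triose half, per-turn acetyl draw, succinate
# end-to-end flip) is enumerated exhaustively with its probability, and
# outcome probabilities are summed per labeling state.

mol_glycolysis <- function(glc, half) {
  # half 1: glucose C1,C2,C3 -> pyruvate C3,C2,C1; half 2: C4,C5,C6 -> C1,C2,C3
  if (half == 1L) c(glc[3], glc[2], glc[1]) else c(glc[4], glc[5], glc[6])
}

mol_pdh <- function(pyr) c(pyr[2], pyr[3])          # C1 lost as CO2

mol_citrate_to_og <- function(acetyl, oaa) {
  # citrate synthase + aconitase + IDH; OAA C1 released as the IDH CO2
  c(oaa[4], oaa[3], oaa[2], acetyl[2], acetyl[1])
}

mol_og_to_succ <- function(og, flip) {
  s <- og[2:5]                                      # OG C1 lost as CO2
  if (flip) rev(s) else s
}

mol_glu_to_gaba <- function(glu) c(glu[5], glu[4], glu[3], glu[2])

# state key for a logical label vector
mol_key <- function(m) paste(as.integer(m), collapse = "")

# Exhaustive enumeration of the TCA chain for a fixed acetyl outcome set.
# acetyl_outcomes: list of list(labels = logical(2), prob = p), summing to 1;
# a fresh acetyl is drawn each turn. Returns list(og = list of per-turn
# distributions (named numeric, keys from mol_key over 5 carbons),
# oaa = per-turn post-scrambling OAA distributions).
oracle_tca <- function(acetyl_outcomes, turns) {
  og_acc <- replicate(turns, new.env(parent = emptyenv()))
  oaa_acc <- replicate(turns, new.env(parent = emptyenv()))
  add <- function(env, key, p) {
    env[[key]] <- (if (is.null(env[[key]])) 0 else env[[key]]) + p
  }
  recurse <- function(turn, oaa, prob) {
    if (turn > turns) return(invisible())
    for (ao in acetyl_outcomes) {
      og <- mol_citrate_to_og(ao$labels, oaa)
      p1 <- prob * ao$prob
      add(og_acc[[turn]], mol_key(og), p1)
      for (flip in c(FALSE, TRUE)) {
        succ <- mol_og_to_succ(og, flip)
        p2 <- p1 * 0.5
        add(oaa_acc[[turn]], mol_key(succ), p2)
        recurse(turn + 1L, succ, p2)
      }
    }
  }
  recurse(1L, rep(FALSE, 4L), 1)
  to_named <- function(env) unlist(as.list(env))
  list(og = lapply(og_acc, to_named), oaa = lapply(oaa_acc, to_named))
}

# Convert a pool_dist to the oracle's named representation for comparison.
dist_to_named <- function(dist) {
  carbons <- attr(dist, "carbons")
  keys <- vapply(seq_along(dist), function(s) {
    bits <- as.integer(bitwAnd(s - 1L, bitwShiftL(1L, 0:(carbons - 1L))) != 0L)
    paste(bits, collapse = "")
  }, character(1))
  setNames(as.numeric(dist), keys)
}

# total variation distance between two named distributions
tvd <- function(a, b) {
  keys <- union(names(a), names(b))
  av <- ifelse(keys %in% names(a), a[keys], 0)
  bv <- ifelse(keys %in% names(b), b[keys], 0)
  sum(abs(av - bv)) / 2
}

# random valid pool distribution (for property tests)
random_pool_dist <- function(carbons) {
  p <- runif(2^carbons)
  pool_dist(carbons, p / sum(p))
}

# flat two-point calibration covering the simulator's metabolites
test_calibration <- function(slope = 100, intercept = 5) {
  mets <- c("Glu", "Gln", "Asp", "GABA", "Ala", "Lac")
  rows <- do.call(rbind, lapply(mets, function(met) {
    nc <- metabolite_carbons()[[met]]
    data.frame(metabolite = met, carbon = rep(seq_len(nc), each = 2),
               conc_mM = rep(c(0.5, 2), nc),
               area = intercept + slope * rep(c(0.5, 2), nc))
  }))
  calibration_table(rows$metabolite, rows$carbon, rows$conc_mM, rows$area)
}
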
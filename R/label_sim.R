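# Discrete-turn two-compartment (neuron/astrocyte) 13C label propagation.
#
# Carbon-fate maps follow standard biochemistry:
#   glycolysis     glucose C1->pyruvate C3, C2->C2, C3->C1 (one triose half)
#                  and C4->C1, C5->C2, C6->C3 (the other); equal mixture.
#   PDH            pyruvate C1 lost as CO2; C2->acetyl C1, C3->acetyl C2.
#   citrate synthase / aconitase / IDH (one composite step to oxoglutarate):
#                  acetyl C1->OG C5, acetyl C2->OG C4,
#                  OAA C2->OG C3, OAA C3->OG C2, OAA C4->OG C1,
#                  OAA C1 lost as the IDH CO2.
#   OG dehydrogenase  OG C1 lost; OG C2..C5 -> succinate C1..C4, followed by
#                  full end-to-end scrambling in the symmetric
#                  succinate/fumarate pool; succinate C_i -> OAA C_i.
#   GAD            Glu C1 lost; Glu C5->GABA C1, C4->C2, C3->C3, C2->C4.
#   transaminases  OAA->Asp and pyruvate->Ala/Lac are position-preserving;
#                  Glu<->Gln (glutamine synthetase/glutaminase) likewise.

#' Glycolysis carbon map: glucose to pyruvate
#'
#' Each glucose yields two trioses; the returned pyruvate distribution is the
#' equal mixture of both halves (C1->C3, C2->C2, C3->C1 and C4->C1, C5->C2,
#' C6->C3).
#'
#' @param glucose A 6-carbon [pool_dist()].
#' @return A 3-carbon pyruvate `pool_dist`.
#' @export
glycolysis_map <- function(glucose) {
  stopifnot(attr(glucose, "carbons") == 6L)
  top    <- apply_carbon_map(glucose, c(3L, 2L, 1L, NA, NA, NA), 3L)
  bottom <- apply_carbon_map(glucose, c(NA, NA, NA, 1L, 2L, 3L), 3L)
  mix_dists(list(top, bottom), c(0.5, 0.5))
}

#' Pyruvate dehydrogenase step
#'
#' Pyruvate C1 is released as CO2; C2 becomes acetyl C1 (carboxyl), C3
#' becomes acetyl C2 (methyl).
#'
#' @param pyruvate A 3-carbon [pool_dist()].
#' @return A 2-carbon acetyl-unit `pool_dist`.
#' @export
pdh_step <- function(pyruvate) {
  stopifnot(attr(pyruvate, "carbons") == 3L)
  apply_carbon_map(pyruvate, c(NA, 1L, 2L), 2L)
}

#' Acetate activation (acetyl-CoA synthetase)
#'
#' Position preserving: acetate C1->acetyl C1, C2->acetyl C2.
#' @param acetate A 2-carbon [pool_dist()].
#' @export
acetate_to_acetyl <- function(acetate) {
  stopifnot(attr(acetate, "carbons") == 2L)
  apply_carbon_map(acetate, c(1L, 2L), 2L)
}

#' One turn of the TCA cycle
#'
#' Condenses an acetyl unit with oxaloacetate, produces the oxoglutarate
#' distribution for this turn and the oxaloacetate distribution feeding the
#' next turn. The OG->succinate decarboxylation removes OG C1 (an
#' OAA-derived carbon); succinate/fumarate symmetry assigns equal
#' probability to each outcome vector and its end-to-end reversal.
#'
#' @param acetyl A 2-carbon [pool_dist()] (C1 carboxyl, C2 methyl).
#' @param oaa A 4-carbon oxaloacetate [pool_dist()]; independent of `acetyl`.
#' @return List with elements `og` (5-carbon oxoglutarate `pool_dist`) and
#'   `oaa_next` (4-carbon `pool_dist` for the next turn).
#' @export
tca_turn <- function(acetyl, oaa) {
  stopifnot(attr(acetyl, "carbons") == 2L, attr(oaa, "carbons") == 4L)
  og <- rep(0, 2L^5L)
  for (a in seq_len(4L)) {
    pa <- acetyl[a]
    if (pa == 0) next
    apos <- state_positions(a, 2L)
    for (o in seq_len(16L)) {
      po <- oaa[o]
      if (po == 0) next
      opos <- state_positions(o, 4L)
      # acetyl C1->OG C5, C2->OG C4; OAA C2->OG C3, C3->OG C2, C4->OG C1
      og_pos <- c(c(5L, 4L)[apos], c(NA, 3L, 2L, 1L)[opos])
      og_pos <- og_pos[!is.na(og_pos)]
      i <- state_index(og_pos, 5L)
      og[i] <- og[i] + pa * po
    }
  }
  og <- pool_dist(5L, og)
  succ <- apply_carbon_map(og, c(NA, 1L, 2L, 3L, 4L), 4L)     # OG C1 lost
  succ <- mix_dists(list(succ, reverse_dist(succ)), c(0.5, 0.5))
  list(og = og, oaa_next = succ)                               # fumarate->malate->OAA preserve positions
}

#' Oxoglutarate to glutamate with unlabeled dilution
#'
#' Position-preserving transamination mixed with an unlabeled glutamate pool
#' at the given fraction (exchange with pre-existing unlabeled metabolite).
#'
#' @param og A 5-carbon [pool_dist()].
#' @param dilution Fraction in \[0,1\] replaced by unlabeled glutamate.
#' @export
og_to_glu <- function(og, dilution = 0) {
  stopifnot(attr(og, "carbons") == 5L, dilution >= 0, dilution <= 1)
  mix_dists(list(og, pool_dist(5L)), c(1 - dilution, dilution))
}

#' Glutamate decarboxylase step (GABA shunt)
#'
#' Glu C1 is lost as CO2; Glu C5->GABA C1, C4->C2, C3->C3, C2->C4.
#'
#' @param glu A 5-carbon [pool_dist()].
#' @return A 4-carbon GABA `pool_dist`.
#' @export
glu_to_gaba <- function(glu) {
  stopifnot(attr(glu, "carbons") == 5L)
  apply_carbon_map(glu, c(NA, 4L, 3L, 2L, 1L), 4L)
}

#' Oxaloacetate to aspartate (transamination, position preserving)
#' @param oaa A 4-carbon [pool_dist()].
#' @export
oaa_to_asp <- function(oaa) {
  stopifnot(attr(oaa, "carbons") == 4L)
  apply_carbon_map(oaa, c(1L, 2L, 3L, 4L), 4L)
}

# Pyruvate carboxylase (anaplerosis): pyruvate C1->OAA C1, C2->C2, C3->C3;
# the carboxylating CO2 (OAA C4) is taken as unlabeled. Off by default.
pc_step <- function(pyruvate) {
  stopifnot(attr(pyruvate, "carbons") == 3L)
  apply_carbon_map(pyruvate, c(1L, 2L, 3L), 4L)
}

# Natural-abundance 13C: each unlabeled carbon is independently 13C with
# probability p (1.1%). Excluded from the default simulation path.
add_natural_abundance <- function(dist, p = 0.011) {
  carbons <- attr(dist, "carbons")
  out <- rep(0, 2L^carbons)
  for (s in seq_along(dist)) {
    if (dist[s] == 0) next
    labeled <- state_positions(s, carbons)
    free <- setdiff(seq_len(carbons), labeled)
    nf <- length(free)
    for (k in 0:(2L^nf - 1L)) {
      extra <- free[bitwAnd(k, bitwShiftL(1L, seq_len(nf) - 1L)) != 0L]
      pr <- p^length(extra) * (1 - p)^(nf - length(extra))
      i <- state_index(c(labeled, extra), carbons)
      out[i] <- out[i] + dist[s] * pr
    }
  }
  pool_dist(carbons, out)
}
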
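# NMR-observable isotopomer classes (the rows of a printed isotopomer table:
# singly labeled positions and adjacent doubly labeled pairs actually
# resolved for each metabolite). Labeled states outside these classes are
# aggregated into an explicit "other" class, never dropped, so that label
# mass remains auditable.
OBSERVABLE_CLASSES <- list(
  Glu  = list(4L, 3L, 2L, 1L, c(4L, 5L), c(2L, 3L), c(3L, 4L), c(1L, 2L)),
  Gln  = list(4L, 3L, 2L, 1L, c(4L, 5L), c(2L, 3L), c(3L, 4L), c(1L, 2L)),
  Asp  = list(4L, 3L, 2L, 1L, c(3L, 4L), c(2L, 3L), c(1L, 2L)),
  GABA = list(4L, 3L, 2L, 1L, c(3L, 4L), c(2L, 3L), c(1L, 2L)),
  Ala  = list(3L, 2L, 1L),
  Lac  = list(3L, 2L, 1L)
)

#' Simulation configuration for the two-compartment label generator
#'
#' Defaults describe a 150-min steady-state co-infusion of
#' \[1-13C\]glucose (neuronal route) and \[1,2-13C\]acetate (astrocytic
#' route) in control vs hypermetabolic-knockout mouse brain, abstracted as a
#' fixed number of discrete TCA turns.
#'
#' @param glucose_c1_fraction Fraction of brain glucose labeled at C1 (0-1).
#' @param acetate_c12_fraction Fraction of brain acetate labeled at C1+C2 (0-1).
#' @param turns Number of TCA turns (1-6).
#' @param groups Character vector of group ids (first is the control).
#' @param glucose_flux_scale Named per-group multiplier on labeled-glucose
#'   delivery (neuronal route).
#' @param acetate_flux_scale Named per-group multiplier on labeled-acetate
#'   delivery (astrocytic route).
#' @param dilution Unlabeled-dilution fraction applied at the
#'   oxoglutarate-to-glutamate exchange in both compartments (0-1).
#' @param gln_transfer Fraction of the neuronal transmitter glutamate pool
#'   replaced by astrocyte-derived glutamine (glutamate-glutamine cycle).
#' @param astro_fraction Fraction of the measured whole-tissue Glu and Asp
#'   pools residing in astrocytes.
#' @param pool_size_mM Named vector of total pool sizes (mM) per metabolite.
#' @param n_replicates Replicates per group (>= 2).
#' @param cv Coefficient of variation of multiplicative log-normal replicate
#'   noise (0 disables noise).
#' @param seed Integer random seed, recorded in the output metadata.
#' @param pyruvate_carboxylase Fraction of each turn's OAA input supplied by
#'   pyruvate carboxylation (anaplerosis); 0 disables (default).
#' @param natural_abundance Logical; add 1.1% natural-abundance 13C to every
#'   reported pool (default FALSE: tracer-attributable label only).
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(glucose_c1_fraction = 0.30,
                       acetate_c12_fraction = 0.25,
                       turns = 3L,
                       groups = c("CTL", "KO"),
                       glucose_flux_scale = c(CTL = 1, KO = 1.3),
                       acetate_flux_scale = c(CTL = 1, KO = 1.15),
                       dilution = 0.15,
                       gln_transfer = 0.30,
                       astro_fraction = 0.10,
                       pool_size_mM = c(Glu = 12.2, Gln = 5.0, Asp = 2.7,
                                        GABA = 2.7, Ala = 0.8, Lac = 3.0),
                       n_replicates = 4L,
                       cv = 0.10,
                       seed = 1L,
                       pyruvate_carboxylase = 0,
                       natural_abundance = FALSE) {
  cfg <- list(glucose_c1_fraction = glucose_c1_fraction,
              acetate_c12_fraction = acetate_c12_fraction,
              turns = as.integer(turns), groups = groups,
              glucose_flux_scale = glucose_flux_scale,
              acetate_flux_scale = acetate_flux_scale,
              dilution = dilution, gln_transfer = gln_transfer,
              astro_fraction = astro_fraction, pool_size_mM = pool_size_mM,
              n_replicates = as.integer(n_replicates), cv = cv,
              seed = as.integer(seed),
              pyruvate_carboxylase = pyruvate_carboxylase,
              natural_abundance = isTRUE(natural_abundance))
  frac_fields <- c("glucose_c1_fraction", "acetate_c12_fraction", "dilution",
                   "gln_transfer", "astro_fraction", "pyruvate_carboxylase")
  for (f in frac_fields) {
    v <- cfg[[f]]
    if (!is.numeric(v) || length(v) != 1L || v < 0 || v > 1) {
      stop(f, " must be a single number in [0,1]", call. = FALSE)
    }
  }
  if (cfg$turns < 1L || cfg$turns > 6L) stop("turns must be in 1..6", call. = FALSE)
  if (cfg$n_replicates < 2L) stop("n_replicates must be >= 2", call. = FALSE)
  if (cfg$cv < 0) stop("cv must be >= 0", call. = FALSE)
  for (f in c("glucose_flux_scale", "acetate_flux_scale")) {
    if (!all(cfg$groups %in% names(cfg[[f]]))) {
      stop(f, " must name every group", call. = FALSE)
    }
    if (any(cfg[[f]] < 0)) stop(f, " must be non-negative", call. = FALSE)
  }
  missing_pool <- setdiff(names(OBSERVABLE_CLASSES), names(cfg$pool_size_mM))
  if (length(missing_pool)) {
    stop("pool_size_mM must name: ", paste(missing_pool, collapse = ", "), call. = FALSE)
  }
  class(cfg) <- "sim_config"
  cfg
}

# Propagate label through one compartment's TCA cycle. Returns the turn-wise
# OG mixture (what transaminates out to Glu) and the OAA entering the final
# turn (what transaminates out to Asp: an OAA carbon has completed >= 1 turn
# before it can carry label).
run_tca_chain <- function(acetyl, turns, pc_fraction = 0, pyruvate = NULL) {
  oaa <- pool_dist(4L)
  ogs <- vector("list", turns)
  asp_source <- oaa
  for (t in seq_len(turns)) {
    if (pc_fraction > 0 && !is.null(pyruvate)) {
      oaa <- mix_dists(list(oaa, pc_step(pyruvate)), c(1 - pc_fraction, pc_fraction))
    }
    if (t == turns) asp_source <- oaa
    step <- tca_turn(acetyl, oaa)
    ogs[[t]] <- step$og
    oaa <- step$oaa_next
  }
  list(og_mix = mix_dists(ogs, rep(1 / turns, turns)), asp_source = asp_source)
}

# Deterministic per-group expected labeling distributions for the measured
# pools. Exposed for testing; run_two_compartment() adds pool sizes,
# replicates and noise on top.
compartment_distributions <- function(cfg, group) {
  f_glc <- min(cfg$glucose_c1_fraction * cfg$glucose_flux_scale[[group]], 1)
  f_ace <- min(cfg$acetate_c12_fraction * cfg$acetate_flux_scale[[group]], 1)

  # neuronal route: glucose -> pyruvate -> acetyl -> TCA
  glucose <- pool_dist_from_patterns(6L, list(1L), f_glc)
  pyr <- glycolysis_map(glucose)
  acetyl_n <- pdh_step(pyr)
  n <- run_tca_chain(acetyl_n, cfg$turns, cfg$pyruvate_carboxylase, pyr)

  # astrocytic route: acetate -> acetyl -> TCA -> Glu -> Gln
  acetate <- pool_dist_from_patterns(2L, list(c(1L, 2L)), f_ace)
  acetyl_a <- acetate_to_acetyl(acetate)
  a <- run_tca_chain(acetyl_a, cfg$turns)

  glu_a <- og_to_glu(a$og_mix, cfg$dilution)
  gln <- glu_a                                       # glutamine synthetase: positions preserved
  glu_n <- og_to_glu(n$og_mix, cfg$dilution)
  # glutamate-glutamine cycle: astrocytic Gln returned to the neuronal pool
  glu_n <- mix_dists(list(glu_n, gln), c(1 - cfg$gln_transfer, cfg$gln_transfer))

  w <- cfg$astro_fraction
  dists <- list(
    Glu  = mix_dists(list(glu_n, glu_a), c(1 - w, w)),
    Gln  = gln,
    GABA = glu_to_gaba(glu_n),
    Asp  = mix_dists(list(oaa_to_asp(n$asp_source), oaa_to_asp(a$asp_source)),
                     c(1 - w, w)),
    Ala  = pyr,                                      # ALT: position preserving
    Lac  = pyr                                       # LDH: position preserving
  )
  if (cfg$natural_abundance) dists <- lapply(dists, add_natural_abundance)
  dists
}

# Collapse a full labeling distribution onto the NMR-observable classes of a
# metabolite. Returns data.frame(pattern, prob); labeled states not matching
# any class fall into "[other]Met"; unlabeled mass is excluded (a 13C table
# reports labeled species only).
aggregate_to_classes <- function(dist, metabolite) {
  classes <- OBSERVABLE_CLASSES[[metabolite]]
  carbons <- attr(dist, "carbons")
  labels <- vapply(classes, function(p) format(label_pattern(metabolite, p)),
                   character(1))
  probs <- vapply(classes, function(p) pattern_prob(dist, p), numeric(1))
  other <- 1 - dist[1L] - sum(probs)
  data.frame(pattern = c(labels, paste0("[other]", metabolite)),
             prob = c(probs, max(other, 0)),
             stringsAsFactors = FALSE)
}

#' Run the two-compartment label-propagation generator
#'
#' Simulates dual-tracer labeling of brain Glu, Gln, Asp, GABA, Ala and Lac:
#' the neuronal chain (glucose to pyruvate to acetyl-CoA to `turns` TCA turns
#' to glutamate to GABA, with alanine/lactate position-preserving from
#' pyruvate) and the astrocytic chain (acetate to acetyl-CoA to TCA to
#' glutamate to glutamine, with glutamine returned to the neuronal glutamate
#' pool). Per-group flux scales multiply labeled-substrate delivery.
#' Replicate concentrations are mean pool size times class probability with
#' multiplicative log-normal noise at the configured CV.
#'
#' @param cfg A [sim_config()].
#' @return List with `iso` (an `isotopomer_table`, including per-metabolite
#'   `[other]` aggregate rows) and `totals` (a `total_pool_table`); both carry
#'   attributes `seed` and `config`.
#' @export
run_two_compartment <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed)
  iso <- list()
  totals <- list()
  sdlog <- sqrt(log(1 + cfg$cv^2))
  noise <- function(n) {
    if (cfg$cv == 0) rep(1, n) else rlnorm(n, meanlog = -sdlog^2 / 2, sdlog = sdlog)
  }
  for (g in cfg$groups) {
    dists <- compartment_distributions(cfg, g)
    for (r in seq_len(cfg$n_replicates)) {
      rep_id <- paste0(g, "_", r)
      for (met in names(dists)) {
        cls <- aggregate_to_classes(dists[[met]], met)
        total_r <- cfg$pool_size_mM[[met]] * noise(1L)
        # one multiplicative draw per concentration: the configured CV is the
        # dispersion of the reported concentration itself
        conc <- cfg$pool_size_mM[[met]] * cls$prob * noise(nrow(cls))
        iso[[length(iso) + 1L]] <- data.frame(
          group = g, replicate = rep_id, pattern = cls$pattern,
          conc_mM = conc, stringsAsFactors = FALSE)
        totals[[length(totals) + 1L]] <- data.frame(
          group = g, replicate = rep_id, metabolite = met,
          total_mM = total_r, stringsAsFactors = FALSE)
      }
    }
  }
  iso_df <- do.call(rbind, iso)
  other <- grepl("^\\[other\\]", iso_df$pattern)
  iso_tab <- new_isotopomer_table(iso_df[!other, , drop = FALSE])
  # re-attach the audit rows for label-mass accounting (not parseable patterns)
  attr(iso_tab, "other_classes") <- iso_df[other, , drop = FALSE]
  tot_df <- do.call(rbind, totals)
  tot_tab <- total_pool_table(tot_df$group, tot_df$replicate,
                              tot_df$metabolite, tot_df$total_mM)
  attr(iso_tab, "seed") <- cfg$seed
  attr(iso_tab, "config") <- cfg
  attr(tot_tab, "seed") <- cfg$seed
  list(iso = iso_tab, totals = tot_tab)
}

# Doublet rule: a doubly labeled pattern with adjacent carbons shows a
# doublet at each of its two resonances; anything else observed is a singlet.
multiplet_class <- function(positions) {
  if (length(positions) == 2L && diff(sort(positions)) == 1L) "doublet" else "singlet"
}

#' Generate synthetic peak areas from an isotopomer table
#'
#' Inverse of quantification: for each record and each labeled position,
#' emits a peak with area `(conc * slope + intercept) * noise`, scaled to the
#' spectrum's internal-standard area. Doubly labeled adjacent-carbon
#' patterns emit doublets, all others singlets.
#'
#' @param iso An `isotopomer_table`.
#' @param cal A `calibration_table` covering every (metabolite, carbon) used.
#' @param is_area_ref Reference internal-standard area (area units); each
#'   spectrum's IS area is drawn around this value (exactly equal at cv = 0).
#' @param seed Integer seed.
#' @param cv Multiplicative noise CV on areas (0 = noiseless).
#' @return A `peak_table`.
#' @export
simulate_peaks <- function(iso, cal, is_area_ref = 1000, seed = 1L, cv = 0) {
  stopifnot(inherits(iso, "isotopomer_table"), inherits(cal, "calibration_table"))
  curves <- fit_standard_curve(cal)
  set.seed(seed)
  sdlog <- sqrt(log(1 + cv^2))
  rows <- list()
  spectra <- unique(iso[c("group", "replicate")])
  is_area <- setNames(
    if (cv == 0) rep(is_area_ref, nrow(spectra))
    else is_area_ref * rlnorm(nrow(spectra), -sdlog^2 / 2, sdlog),
    paste(spectra$group, spectra$replicate, sep = "\r"))
  for (i in seq_len(nrow(iso))) {
    pat <- parse_pattern(iso$pattern[i])
    spec_key <- paste(iso$group[i], iso$replicate[i], sep = "\r")
    scale <- is_area[[spec_key]] / is_area_ref
    for (pos in pat$positions) {
      cv_key <- paste(pat$metabolite, pos)
      cu <- curves[curves$metabolite == pat$metabolite & curves$carbon == pos, ]
      if (nrow(cu) == 0L) {
        stop("missing calibration for ", pat$metabolite, " C", pos, call. = FALSE)
      }
      area <- (iso$conc_mM[i] * cu$slope + cu$intercept) * scale
      if (cv > 0) area <- area * rlnorm(1L, -sdlog^2 / 2, sdlog)
      rows[[length(rows) + 1L]] <- data.frame(
        group = iso$group[i], replicate = iso$replicate[i],
        metabolite = pat$metabolite, carbon = pos,
        multiplet = multiplet_class(pat$positions),
        pattern = iso$pattern[i], area = area,
        is_area = is_area[[spec_key]], stringsAsFactors = FALSE)
    }
  }
  peak_table(do.call(rbind, rows))
}
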
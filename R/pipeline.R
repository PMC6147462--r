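# End-to-end orchestration: simulate -> (optionally quantify via synthetic
# peaks) -> analyze -> report, with seed provenance. A single global seed is
# expanded into per-stage substreams by fixed offsets (+1 simulation,
# +2 peak synthesis, +3 electrophysiology) so stages are individually
# reproducible.

#' Build a pipeline configuration
#'
#' @param out_dir Output directory (created if absent).
#' @param seed Global integer seed; recorded in the run manifest and expanded
#'   into per-stage substreams.
#' @param input `"simulate"` (default: generate data with the two-compartment
#'   simulator), `"table1"` (packaged published group means), or a list with
#'   paths `iso` and `totals` naming CSV inputs.
#' @param sim Named list of [sim_config()] overrides (seed is supplied by the
#'   pipeline).
#' @param quantify_roundtrip If `TRUE`, simulated concentrations are
#'   converted to synthetic peak areas and re-quantified through standard
#'   curves before analysis (exercises the full NMR quantification path).
#' @param control,treated Group ids to compare.
#' @param flavor t-test flavor (`"student"` or `"welch"`).
#' @param matched_denominator,bh Analysis flags, see
#'   [glucose_cycling_ratio()] and [compare_groups()].
#' @param nat_abundance_correction If `TRUE`, subtract 1.1% of the total pool
#'   per carbon from each isotopomer concentration before analysis.
#' @param ltp Either `NULL` (skip the electrophysiology stage) or a list with
#'   elements `potentiation` (length-2 numeric, control/treated), `n_slices`,
#'   `noise_sd`, `baseline_slope`.
#' @return List of class `pipeline_config`.
#' @export
pipeline_config <- function(out_dir,
                            seed = 1L,
                            input = "simulate",
                            sim = list(),
                            quantify_roundtrip = FALSE,
                            control = "CTL", treated = "KO",
                            flavor = "student",
                            matched_denominator = FALSE,
                            bh = FALSE,
                            nat_abundance_correction = FALSE,
                            ltp = list(potentiation = c(1.3, 1.6),
                                       n_slices = 10L, noise_sd = 0.05,
                                       baseline_slope = 0.5)) {
  if (identical(ltp, FALSE) || (is.list(ltp) && length(ltp) == 0L)) ltp <- NULL
  cfg <- list(out_dir = out_dir, seed = as.integer(seed), input = input,
              sim = sim, quantify_roundtrip = isTRUE(quantify_roundtrip),
              control = control, treated = treated, flavor = flavor,
              matched_denominator = isTRUE(matched_denominator),
              bh = isTRUE(bh),
              nat_abundance_correction = isTRUE(nat_abundance_correction),
              ltp = ltp)
  if (is.list(input)) {
    for (f in c("iso", "totals")) {
      if (is.null(input[[f]])) stop("input list must name '", f, "'", call. = FALSE)
      if (!file.exists(input[[f]])) {
        stop("input stage: missing file for '", f, "': ", input[[f]], call. = FALSE)
      }
    }
  } else if (!input %in% c("simulate", "table1")) {
    stop("input must be 'simulate', 'table1', or a list of paths", call. = FALSE)
  }
  class(cfg) <- "pipeline_config"
  cfg
}

#' Read a pipeline configuration from a JSON file
#'
#' @param path JSON file whose keys mirror [pipeline_config()] arguments.
#' @export
read_pipeline_config <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  do.call(pipeline_config, raw)
}

stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    stop("pipeline stage '", name, "': ", conditionMessage(e), call. = FALSE)
  })
}

# Flat synthetic calibration covering every (metabolite, carbon) in use:
# two exact points per curve (slope 100 au/mM, intercept 5 au).
default_calibration <- function(metabolites = names(OBSERVABLE_CLASSES)) {
  rows <- list()
  for (met in metabolites) {
    for (carbon in seq_len(METABOLITE_CARBONS[[met]])) {
      rows[[length(rows) + 1L]] <- data.frame(
        metabolite = met, carbon = carbon,
        conc_mM = c(0.5, 2.0), area = c(5 + 0.5 * 100, 5 + 2.0 * 100),
        stringsAsFactors = FALSE)
    }
  }
  df <- do.call(rbind, rows)
  calibration_table(df$metabolite, df$carbon, df$conc_mM, df$area)
}

#' Run the full analysis pipeline
#'
#' Deterministic given the config seed. Writes `group_comparison.csv`,
#' `ratio_report.csv`, `enrichment.csv`, `ltp_summary.csv` (when the ephys
#' stage is enabled) and a machine-readable `manifest.json` (seed, package
#' version, input hashes) into the output directory.
#'
#' @param cfg A [pipeline_config()].
#' @return Invisible list with the in-memory result tables and the manifest.
#' @export
run_pipeline <- function(cfg) {
  stopifnot(inherits(cfg, "pipeline_config"))
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  input_hashes <- list()

  mean_level <- identical(cfg$input, "table1")
  if (mean_level) {
    iso <- stage("input", table1_as_isotopomer_table())
    totals <- stage("input", table2_as_total_pool_table())
  } else if (is.list(cfg$input)) {
    iso <- stage("input", read_isotopomer_table(cfg$input$iso))
    totals <- stage("input", read_total_pool_table(cfg$input$totals))
    input_hashes <- as.list(tools::md5sum(c(iso = cfg$input$iso,
                                            totals = cfg$input$totals)))
  } else {
    sim_args <- cfg$sim
    sim_args$seed <- cfg$seed + 1L
    scfg <- stage("simulate", do.call(sim_config, sim_args))
    simulated <- stage("simulate", run_two_compartment(scfg))
    iso <- simulated$iso
    totals <- simulated$totals
  }

  if (cfg$quantify_roundtrip && !mean_level) {
    cal <- default_calibration()
    peaks <- stage("quantify", simulate_peaks(iso, cal, is_area_ref = 1000,
                                              seed = cfg$seed + 2L, cv = 0))
    curves <- stage("quantify", fit_standard_curve(cal))
    iso <- stage("quantify", areas_to_concentrations(peaks, curves, is_area_ref = 1000))
  }

  if (cfg$nat_abundance_correction) {
    iso <- stage("analyze", nat_abundance_correct(iso, totals))
  }

  if (mean_level) {
    t1 <- table1_isotopomers()
    comparison <- stage("analyze", compare_groups_summary(
      data.frame(pattern = t1$pattern, mean_control = t1$mean_ctl,
                 disp_control = t1$disp_ctl, mean_treated = t1$mean_ko,
                 disp_treated = t1$disp_ko, stringsAsFactors = FALSE),
      n = t1$n, dispersion_kind = t1$dispersion_kind[1], flavor = cfg$flavor))
  } else {
    comparison <- stage("analyze", compare_groups(iso, cfg$control, cfg$treated,
                                                  flavor = cfg$flavor, bh = cfg$bh))
  }
  ratios <- stage("analyze", ratio_report(iso, cfg$control, cfg$treated,
                                          matched_denominator = cfg$matched_denominator))
  enrichment <- stage("analyze", suppressWarnings(suppressMessages(
    fractional_enrichment(iso, totals))))

  write_report(comparison, file.path(cfg$out_dir, "group_comparison.csv"))
  rr <- ratios
  gi <- attr(ratios, "glycolytic_index")
  write_report(rr, file.path(cfg$out_dir, "ratio_report.csv"))
  write_report(enrichment, file.path(cfg$out_dir, "enrichment.csv"))

  ltp_summary <- NULL
  if (!is.null(cfg$ltp)) {
    ltp_summary <- stage("ltp", {
      lp <- cfg$ltp
      groups <- c(cfg$control, cfg$treated)
      rows <- list()
      per_slice <- list()
      for (gi_ix in 1:2) {
        vals <- vapply(seq_len(lp$n_slices), function(s) {
          rec <- simulate_recording(baseline_slope = lp$baseline_slope,
                                    potentiation = lp$potentiation[gi_ix],
                                    noise_sd = lp$noise_sd,
                                    seed = cfg$seed + 3L + 100L * gi_ix + s)
          ltp_value(normalize_ltp(rec))
        }, numeric(1))
        per_slice[[gi_ix]] <- vals
        rows[[gi_ix]] <- data.frame(group = groups[gi_ix], n_slices = lp$n_slices,
                                    ltp_pct = mean(vals), sd = sd(vals),
                                    stringsAsFactors = FALSE)
      }
      tt <- ltp_group_test(per_slice[[1]], per_slice[[2]], flavor = cfg$flavor)
      out <- do.call(rbind, rows)
      out$p_between <- tt$p
      out
    })
    write_report(ltp_summary, file.path(cfg$out_dir, "ltp_summary.csv"))
  }

  manifest <- list(package = "neurotracer",
                   version = as.character(packageVersion("neurotracer")),
                   seed = cfg$seed,
                   input = if (is.list(cfg$input)) "files" else cfg$input,
                   input_md5 = input_hashes,
                   glycolytic_index = if (is.null(gi)) NA else gi,
                   outputs = list.files(cfg$out_dir, pattern = "\\.csv$"))
  jsonlite::write_json(manifest, file.path(cfg$out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(list(comparison = comparison, ratios = ratios,
                 enrichment = enrichment, ltp = ltp_summary,
                 manifest = manifest))
}

#' Natural-abundance correction
#'
#' Subtracts 1.1% of the metabolite's total pool per labeled carbon from
#' each isotopomer concentration (floored at 0). Off by default throughout
#' the package; tracer experiments report tracer-attributable label.
#'
#' @param iso An `isotopomer_table`.
#' @param totals A `total_pool_table` (group-mean totals are used).
#' @param p Natural 13C abundance (default 0.011).
#' @return Corrected `isotopomer_table`.
#' @export
nat_abundance_correct <- function(iso, totals, p = 0.011) {
  grp_means <- aggregate(totals$total_mM,
                         by = list(group = totals$group, metabolite = totals$metabolite),
                         FUN = mean)
  key <- setNames(grp_means$x, paste(grp_means$group, grp_means$metabolite, sep = "\r"))
  conc <- iso$conc_mM
  for (i in seq_len(nrow(iso))) {
    k <- paste(iso$group[i], iso$metabolite[i], sep = "\r")
    if (!is.na(key[k])) {
      n_pos <- length(parse_pattern(iso$pattern[i])$positions)
      conc[i] <- max(conc[i] - n_pos * p * key[[k]], 0)
    }
  }
  isotopomer_table(iso$group, iso$replicate, iso$pattern, conc)
}
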
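# Metabolic ratios, group comparison, and small scalar assays.
#
# Ratio formulas (dual-tracer convention):
#   glucose cycling ratio   ([3-13C]X - [1,2-13C]X) / [4-13C]Glu
#   acetate cycling ratio   [1,2-13C]X / [4,5-13C]X
#   acetate vs glucose      [4,5-13C]X / [4-13C]X   (X = Glu or Gln)
#                           [1,2-13C]GABA / [2-13C]GABA
#   glycolytic index        % change of [3-13C]Ala between groups
# The glucose cycling denominator is the glutamate C4 pool even for the Gln
# variant, exactly as the formula is conventionally printed;
# `matched_denominator = TRUE` switches to [4-13C]Gln.

# Mean concentration of one pattern within one group; errors if absent.
group_pattern_mean <- function(iso, group, pattern) {
  pattern <- format(parse_pattern(pattern))
  v <- iso$conc_mM[iso$group == group & iso$pattern == pattern]
  if (length(v) == 0L) {
    stop("pattern ", pattern, " not present for group '", group, "'", call. = FALSE)
  }
  mean(v)
}

ratio_guard <- function(num, den, what) {
  if (den <= 0) stop("zero or negative denominator in ", what, call. = FALSE)
  num / den
}

#' Glucose (neuronal) cycling ratio
#'
#' `([3-13C]target - [1,2-13C]target) / [4-13C]Glu`, computed on group means.
#' Indexes how many TCA turns glucose-derived label completes before exiting
#' to glutamate/glutamine; 0 after a single turn.
#'
#' @param iso An `isotopomer_table`.
#' @param group Group id.
#' @param target `"Glu"` or `"Gln"`.
#' @param matched_denominator If `TRUE`, the Gln variant divides by
#'   \[4-13C\]Gln instead of \[4-13C\]Glu.
#' @return Scalar ratio.
#' @export
glucose_cycling_ratio <- function(iso, group, target = c("Glu", "Gln"),
                                  matched_denominator = FALSE) {
  target <- match.arg(target)
  den_met <- if (matched_denominator) target else "Glu"
  num <- group_pattern_mean(iso, group, paste0("[3-13C]", target)) -
    group_pattern_mean(iso, group, paste0("[1,2-13C]", target))
  den <- group_pattern_mean(iso, group, paste0("[4-13C]", den_met))
  ratio_guard(num, den, "glucose cycling ratio")
}

#' Acetate (astrocytic) cycling ratio
#'
#' `[1,2-13C]target / [4,5-13C]target` on group means.
#'
#' @inheritParams glucose_cycling_ratio
#' @export
acetate_cycling_ratio <- function(iso, group, target = c("Glu", "Gln")) {
  target <- match.arg(target)
  num <- group_pattern_mean(iso, group, paste0("[1,2-13C]", target))
  den <- group_pattern_mean(iso, group, paste0("[4,5-13C]", target))
  ratio_guard(num, den, "acetate cycling ratio")
}

#' Acetate-versus-glucose utilization index
#'
#' `[4,5-13C]X / [4-13C]X` for glutamate and glutamine;
#' `[1,2-13C]GABA / [2-13C]GABA` for GABA. Estimates the relative astrocytic
#' versus neuronal contribution to each pool.
#'
#' @inheritParams glucose_cycling_ratio
#' @param target `"Glu"`, `"Gln"` or `"GABA"`.
#' @export
acetate_vs_glucose_index <- function(iso, group, target = c("Glu", "Gln", "GABA")) {
  target <- match.arg(target)
  if (target == "GABA") {
    num <- group_pattern_mean(iso, group, "[1,2-13C]GABA")
    den <- group_pattern_mean(iso, group, "[2-13C]GABA")
  } else {
    num <- group_pattern_mean(iso, group, paste0("[4,5-13C]", target))
    den <- group_pattern_mean(iso, group, paste0("[4-13C]", target))
  }
  ratio_guard(num, den, "acetate vs glucose index")
}

#' Glycolytic index
#'
#' Percent change of the \[3-13C\]alanine group mean between a control and a
#' treated group (a between-group scalar).
#'
#' @param iso An `isotopomer_table` containing both groups.
#' @param control,treated Group ids.
#' @export
glycolytic_index <- function(iso, control, treated) {
  ctl <- group_pattern_mean(iso, control, "[3-13C]Ala")
  trt <- group_pattern_mean(iso, treated, "[3-13C]Ala")
  percent_change(ctl, trt)
}

#' Percent change between two means
#'
#' `100 * (treated - control) / control`.
#'
#' @param control,treated Numeric scalars (control mean must be non-zero).
#' @export
percent_change <- function(control, treated) {
  if (any(control == 0)) stop("zero control mean in percent change", call. = FALSE)
  100 * (treated - control) / control
}

#' Two-tailed two-sample t-test
#'
#' Student pooled-variance by default (`flavor = "student"`); Welch
#' (`flavor = "welch"`) behind the flag. Accepts either raw value vectors or
#' summary statistics (mean, sd, n) for each group, since printed tables
#' store only mean +/- dispersion. When both SDs are zero and the means are
#' equal, returns t = 0, p = 1 with a `degenerate` flag.
#'
#' @param a,b Numeric vectors of raw values, or lists/named vectors with
#'   elements `mean`, `sd`, `n`.
#' @param flavor `"student"` or `"welch"`.
#' @return List with `t`, `df`, `p`, `flavor`, `degenerate`.
#' @export
two_tailed_t <- function(a, b, flavor = c("student", "welch")) {
  flavor <- match.arg(flavor)
  s <- function(x) {
    if (is.list(x) || !is.null(names(x))) {
      list(mean = as.numeric(x[["mean"]]), sd = as.numeric(x[["sd"]]),
           n = as.numeric(x[["n"]]))
    } else {
      list(mean = mean(x), sd = sd(x), n = length(x))
    }
  }
  ga <- s(a); gb <- s(b)
  if (ga$n < 2 || gb$n < 2) stop("each group needs n >= 2", call. = FALSE)
  if (ga$sd < 0 || gb$sd < 0) stop("sd must be >= 0", call. = FALSE)
  if (ga$sd == 0 && gb$sd == 0) {
    if (ga$mean == gb$mean) {
      return(list(t = 0, df = ga$n + gb$n - 2, p = 1, flavor = flavor,
                  degenerate = TRUE))
    }
    return(list(t = Inf * sign(ga$mean - gb$mean), df = ga$n + gb$n - 2, p = 0,
                flavor = flavor, degenerate = TRUE))
  }
  if (flavor == "student") {
    df <- ga$n + gb$n - 2
    sp2 <- ((ga$n - 1) * ga$sd^2 + (gb$n - 1) * gb$sd^2) / df
    se <- sqrt(sp2 * (1 / ga$n + 1 / gb$n))
  } else {
    va <- ga$sd^2 / ga$n; vb <- gb$sd^2 / gb$n
    se <- sqrt(va + vb)
    df <- (va + vb)^2 / (va^2 / (ga$n - 1) + vb^2 / (gb$n - 1))
  }
  t_stat <- (ga$mean - gb$mean) / se
  p <- 2 * pt(-abs(t_stat), df)
  list(t = t_stat, df = df, p = p, flavor = flavor, degenerate = FALSE)
}

#' Group comparison table (printed-table shaped)
#'
#' One row per pattern: per-group mean, SD, n, percent change, two-tailed t
#' p value, and significance flags at 0.05 and 0.01.
#'
#' @param iso An `isotopomer_table` containing both groups.
#' @param control,treated Group ids.
#' @param flavor t-test flavor, see [two_tailed_t()].
#' @param bh If `TRUE`, adds a Benjamini-Hochberg adjusted p column `p_adj`.
#' @return data.frame of class `group_comparison`.
#' @export
compare_groups <- function(iso, control, treated, flavor = "student", bh = FALSE) {
  stopifnot(inherits(iso, "isotopomer_table"))
  patterns <- intersect(unique(iso$pattern[iso$group == control]),
                        unique(iso$pattern[iso$group == treated]))
  rows <- lapply(patterns, function(p) {
    va <- iso$conc_mM[iso$group == control & iso$pattern == p]
    vb <- iso$conc_mM[iso$group == treated & iso$pattern == p]
    tt <- two_tailed_t(va, vb, flavor = flavor)
    data.frame(pattern = p,
               mean_control = mean(va), sd_control = sd(va), n_control = length(va),
               mean_treated = mean(vb), sd_treated = sd(vb), n_treated = length(vb),
               pct_change = if (mean(va) == 0) NA_real_ else
                 percent_change(mean(va), mean(vb)),
               t = tt$t, p = tt$p, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$dispersion_kind <- "sd"
  if (bh) out$p_adj <- stats::p.adjust(out$p, method = "BH")
  out$sig_05 <- out$p <= 0.05
  out$sig_01 <- out$p <= 0.01
  class(out) <- c("group_comparison", "data.frame")
  out
}

#' Group comparison from summary statistics
#'
#' For mean +/- dispersion inputs (printed-table style). `dispersion_kind`
#' states whether the dispersion columns are SDs or SEMs; SEMs are converted
#' to SDs via `sd = sem * sqrt(n)` before testing.
#'
#' @param df data.frame with columns pattern, mean_control, disp_control,
#'   mean_treated, disp_treated.
#' @param n Per-group sample size (scalar or vector).
#' @param dispersion_kind `"sd"` or `"sem"`.
#' @param flavor t-test flavor.
#' @return data.frame of class `group_comparison`.
#' @export
compare_groups_summary <- function(df, n, dispersion_kind = c("sd", "sem"),
                                   flavor = "student") {
  dispersion_kind <- match.arg(dispersion_kind)
  n <- rep_len(n, nrow(df))
  to_sd <- function(disp, n) if (dispersion_kind == "sem") disp * sqrt(n) else disp
  rows <- lapply(seq_len(nrow(df)), function(i) {
    sda <- to_sd(df$disp_control[i], n[i])
    sdb <- to_sd(df$disp_treated[i], n[i])
    tt <- two_tailed_t(list(mean = df$mean_control[i], sd = sda, n = n[i]),
                       list(mean = df$mean_treated[i], sd = sdb, n = n[i]),
                       flavor = flavor)
    data.frame(pattern = df$pattern[i],
               mean_control = df$mean_control[i], sd_control = sda, n_control = n[i],
               mean_treated = df$mean_treated[i], sd_treated = sdb, n_treated = n[i],
               pct_change = percent_change(df$mean_control[i], df$mean_treated[i]),
               t = tt$t, p = tt$p, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$dispersion_kind <- "sd"
  out$sig_05 <- out$p <= 0.05
  out$sig_01 <- out$p <= 0.01
  class(out) <- c("group_comparison", "data.frame")
  out
}

#' Ratio report for one or more groups
#'
#' All per-group metabolic ratios in one table; the between-group glycolytic
#' index is attached as attribute `glycolytic_index` when both group ids are
#' given and \[3-13C\]Ala is present.
#'
#' @inheritParams compare_groups
#' @param matched_denominator Passed to [glucose_cycling_ratio()].
#' @return data.frame of class `ratio_report` (one row per group).
#' @export
ratio_report <- function(iso, control, treated = NULL, matched_denominator = FALSE) {
  groups <- c(control, treated)
  # a ratio whose pattern is absent or whose denominator class is zero in
  # this data set is reported as NA rather than aborting the whole report
  safe <- function(expr) tryCatch(expr, error = function(e) NA_real_)
  rows <- lapply(groups, function(g) {
    data.frame(
      group = g,
      glucose_cycling_glu = safe(glucose_cycling_ratio(iso, g, "Glu")),
      glucose_cycling_gln = safe(glucose_cycling_ratio(iso, g, "Gln",
                                                       matched_denominator = matched_denominator)),
      acetate_cycling_glu = safe(acetate_cycling_ratio(iso, g, "Glu")),
      acetate_cycling_gln = safe(acetate_cycling_ratio(iso, g, "Gln")),
      acetate_vs_glucose_glu = safe(acetate_vs_glucose_index(iso, g, "Glu")),
      acetate_vs_glucose_gln = safe(acetate_vs_glucose_index(iso, g, "Gln")),
      acetate_vs_glucose_gaba = safe(acetate_vs_glucose_index(iso, g, "GABA")),
      stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (!is.null(treated) && "[3-13C]Ala" %in% iso$pattern) {
    attr(out, "glycolytic_index") <- glycolytic_index(iso, control, treated)
  }
  class(out) <- c("ratio_report", "data.frame")
  out
}

#' Standardized uptake value (SUV)
#'
#' Tissue radioactivity concentration divided by injected activity per unit
#' body weight (even-distribution reference). Inputs must be in mutually
#' consistent units.
#'
#' @param tissue_conc Tissue activity concentration.
#' @param injected_activity Injected activity.
#' @param body_weight Body weight.
#' @export
suv <- function(tissue_conc, injected_activity, body_weight) {
  if (any(c(tissue_conc, injected_activity, body_weight) <= 0)) {
    stop("all SUV inputs must be > 0", call. = FALSE)
  }
  tissue_conc / (injected_activity / body_weight)
}

#' Phospho-AKT to total AKT ratio
#'
#' @param phospho Phospho(Ser473)-AKT signal (>= 0).
#' @param total Total AKT signal (> 0).
#' @export
pakt_ratio <- function(phospho, total) {
  if (any(total <= 0)) stop("total AKT signal must be > 0", call. = FALSE)
  if (any(phospho < 0)) stop("phospho signal must be >= 0", call. = FALSE)
  phospho / total
}
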
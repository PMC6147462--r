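# Standard-curve quantification: peak area vs known 13C concentration per
# (metabolite, carbon), internal-standard normalization, and fractional
# enrichment against HPLC total (12C+13C) pools.

#' Fit standard curves from a calibration table
#'
#' Ordinary least-squares line (area ~ conc) per (metabolite, carbon), with
#' the coefficient of determination stored as a fit diagnostic.
#'
#' @param cal A `calibration_table`.
#' @return data.frame of class `standard_curves`: metabolite, carbon, slope
#'   (area per mM), intercept (area), r_squared, n_points.
#' @export
fit_standard_curve <- function(cal) {
  stopifnot(inherits(cal, "calibration_table"))
  key <- interaction(cal$metabolite, cal$carbon, drop = TRUE)
  out <- lapply(split(seq_len(nrow(cal)), key), function(idx) {
    d <- cal[idx, , drop = FALSE]
    if (length(unique(d$conc_mM)) < 2L) {
      stop("zero concentration spread for ", d$metabolite[1], " C", d$carbon[1],
           call. = FALSE)
    }
    fit <- lm(area ~ conc_mM, data = d)
    ss_res <- sum(residuals(fit)^2)
    ss_tot <- sum((d$area - mean(d$area))^2)
    data.frame(metabolite = d$metabolite[1], carbon = d$carbon[1],
               slope = unname(coef(fit)[2]), intercept = unname(coef(fit)[1]),
               r_squared = if (ss_tot > 0) 1 - ss_res / ss_tot else 1,
               n_points = nrow(d), stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  if (any(res$slope <= 0)) {
    bad <- res[res$slope <= 0, ][1, ]
    stop("non-positive calibration slope for ", bad$metabolite, " C", bad$carbon,
         call. = FALSE)
  }
  class(res) <- c("standard_curves", "data.frame")
  res
}

#' Convert peak areas to 13C concentrations
#'
#' Each peak area is rescaled by (reference IS area / spectrum IS area), then
#' inverted through its (metabolite, carbon) standard curve:
#' `conc = (scaled area - intercept) / slope`, floored at 0 (with an
#' `clipped` audit attribute counting floored values). Peaks belonging to a
#' multi-position pattern are averaged across positions (they measure the
#' same species).
#'
#' @param peaks A `peak_table`.
#' @param curves A `standard_curves` table from [fit_standard_curve()].
#' @param is_area_ref Reference internal-standard area the curves were
#'   acquired at.
#' @return An `isotopomer_table`.
#' @export
areas_to_concentrations <- function(peaks, curves, is_area_ref = 1000) {
  stopifnot(inherits(peaks, "peak_table"), inherits(curves, "standard_curves"))
  if (is_area_ref <= 0) stop("reference internal-standard area must be > 0", call. = FALSE)
  conc <- numeric(nrow(peaks))
  for (i in seq_len(nrow(peaks))) {
    cu <- curves[curves$metabolite == peaks$metabolite[i] &
                   curves$carbon == peaks$carbon[i], ]
    if (nrow(cu) == 0L) {
      stop("missing standard curve for ", peaks$metabolite[i], " C",
           peaks$carbon[i], call. = FALSE)
    }
    scaled <- peaks$area[i] * is_area_ref / peaks$is_area[i]
    conc[i] <- (scaled - cu$intercept) / cu$slope
  }
  clipped <- sum(conc < 0)
  conc <- pmax(conc, 0)
  agg <- aggregate(conc,
                   by = list(group = peaks$group, replicate = peaks$replicate,
                             pattern = peaks$pattern),
                   FUN = mean)
  out <- isotopomer_table(agg$group, agg$replicate, agg$pattern, agg$x)
  attr(out, "clipped") <- clipped
  out
}

#' Fractional enrichment of 13C isotopomers
#'
#' Enrichment (%) = 100 x isotopomer concentration / total (12C+13C) pool
#' concentration of the same metabolite. Matching is at replicate level when
#' replicate ids align between `iso` and `totals`; otherwise the group-mean
#' total is used (a notice is emitted). Values are clipped to \[0, 100\] with
#' a `clipped` audit attribute. Metabolites without totals are skipped with a
#' warning.
#'
#' @param iso An `isotopomer_table`.
#' @param totals A `total_pool_table`.
#' @return data.frame of class `enrichment_table`: group, replicate, pattern,
#'   metabolite, enrichment_pct.
#' @export
fractional_enrichment <- function(iso, totals) {
  stopifnot(inherits(iso, "isotopomer_table"), inherits(totals, "total_pool_table"))
  if (any(totals$total_mM <= 0)) stop("total concentration must be > 0", call. = FALSE)
  have <- unique(totals$metabolite)
  skip <- setdiff(unique(iso$metabolite), have)
  if (length(skip)) {
    warning("no totals for metabolite(s), skipped: ", paste(skip, collapse = ", "),
            call. = FALSE)
  }
  d <- iso[iso$metabolite %in% have, , drop = FALSE]
  rep_key <- paste(totals$group, totals$replicate, totals$metabolite, sep = "\r")
  rep_tot <- setNames(totals$total_mM, rep_key)
  grp_means <- aggregate(totals$total_mM,
                         by = list(group = totals$group, metabolite = totals$metabolite),
                         FUN = mean)
  grp_tot <- setNames(grp_means$x, paste(grp_means$group, grp_means$metabolite, sep = "\r"))
  used_group_mean <- FALSE
  tot <- numeric(nrow(d))
  for (i in seq_len(nrow(d))) {
    k <- paste(d$group[i], d$replicate[i], d$metabolite[i], sep = "\r")
    if (!is.na(rep_tot[k])) {
      tot[i] <- rep_tot[[k]]
    } else {
      tot[i] <- grp_tot[[paste(d$group[i], d$metabolite[i], sep = "\r")]]
      used_group_mean <- TRUE
    }
  }
  if (used_group_mean) {
    message("fractional_enrichment: replicate-level totals unavailable for some ",
            "records; fell back to group-mean totals")
  }
  enr <- 100 * d$conc_mM / tot
  clipped <- sum(enr > 100)
  enr <- pmin(enr, 100)
  out <- data.frame(group = d$group, replicate = d$replicate, pattern = d$pattern,
                    metabolite = d$metabolite, enrichment_pct = enr,
                    stringsAsFactors = FALSE)
  attr(out, "clipped") <- clipped
  class(out) <- c("enrichment_table", "data.frame")
  out
}
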
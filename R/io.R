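# Tabular readers/writers. All files are UTF-8 text with a header row;
# comma-separated by default, tab auto-detected from the header line.

detect_sep <- function(path) {
  header <- readLines(path, n = 1L, warn = FALSE)
  if (grepl("\t", header)) "\t" else ","
}

read_table_file <- function(path, required_cols, dialect = c("auto", "csv", "tsv")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  sep <- switch(dialect, auto = detect_sep(path), csv = ",", tsv = "\t")
  df <- read.csv(path, sep = sep, stringsAsFactors = FALSE,
                 check.names = FALSE, fileEncoding = "UTF-8")
  missing <- setdiff(required_cols, names(df))
  if (length(missing)) {
    stop("missing required column(s) in ", path, ": ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  df
}

new_isotopomer_table <- function(df) {
  df$pattern <- canonicalize_patterns(df$pattern)
  df$conc_mM <- as.numeric(df$conc_mM)
  if (any(!is.finite(df$conc_mM))) stop("non-finite concentration", call. = FALSE)
  if (any(df$conc_mM < 0)) stop("negative concentration", call. = FALSE)
  key <- paste(df$group, df$replicate, df$pattern, sep = "\r")
  if (anyDuplicated(key)) {
    dup <- df[duplicated(key), , drop = FALSE][1L, ]
    stop("duplicate (group, replicate, pattern) key: ",
         dup$group, "/", dup$replicate, "/", dup$pattern, call. = FALSE)
  }
  df$metabolite <- vapply(df$pattern, function(p) parse_pattern(p)$metabolite,
                          character(1), USE.NAMES = FALSE)
  class(df) <- c("isotopomer_table", "data.frame")
  df
}

#' Build an isotopomer table from records
#'
#' Replicate-level 13C isotopomer concentrations (mM) per
#' (group, replicate, pattern). Keys must be unique; concentrations finite
#' and non-negative. Patterns are canonicalized.
#'
#' @param group,replicate Character/integer vectors of group and replicate ids.
#' @param pattern Character vector of pattern strings (see [parse_pattern()]).
#' @param conc_mM Numeric concentrations in mM.
#' @return A data.frame of class `isotopomer_table` with an added
#'   `metabolite` column.
#' @export
isotopomer_table <- function(group, replicate, pattern, conc_mM) {
  new_isotopomer_table(data.frame(group = as.character(group),
                                  replicate = as.character(replicate),
                                  pattern = as.character(pattern),
                                  conc_mM = as.numeric(conc_mM),
                                  stringsAsFactors = FALSE))
}

#' Read an isotopomer concentration table
#'
#' Expects header columns `group, replicate, pattern, conc_mM`.
#'
#' @param path Path to a CSV/TSV file.
#' @param dialect `"auto"` (default; tab detected from header), `"csv"` or `"tsv"`.
#' @return An `isotopomer_table`.
#' @export
read_isotopomer_table <- function(path, dialect = "auto") {
  df <- read_table_file(path, c("group", "replicate", "pattern", "conc_mM"), dialect)
  new_isotopomer_table(df[c("group", "replicate", "pattern", "conc_mM")])
}

#' Write an isotopomer table
#' @param x An `isotopomer_table`.
#' @param path Output path (CSV).
#' @export
write_isotopomer_table <- function(x, path) {
  write_report(x[c("group", "replicate", "pattern", "conc_mM")], path)
}

#' Read a total-pool (12C+13C) concentration table
#'
#' Expects header columns `group, replicate, metabolite, total_mM`.
#' Totals-vs-isotopomer consistency is enforced at enrichment computation,
#' not at ingestion.
#'
#' @inheritParams read_isotopomer_table
#' @return A data.frame of class `total_pool_table`.
#' @export
read_total_pool_table <- function(path, dialect = "auto") {
  df <- read_table_file(path, c("group", "replicate", "metabolite", "total_mM"), dialect)
  total_pool_table(df$group, df$replicate, df$metabolite, df$total_mM)
}

#' @rdname read_total_pool_table
#' @param group,replicate,metabolite,total_mM Record fields.
#' @export
total_pool_table <- function(group, replicate, metabolite, total_mM) {
  df <- data.frame(group = as.character(group), replicate = as.character(replicate),
                   metabolite = as.character(metabolite),
                   total_mM = as.numeric(total_mM), stringsAsFactors = FALSE)
  if (any(!is.finite(df$total_mM))) stop("non-finite total concentration", call. = FALSE)
  bad <- setdiff(unique(df$metabolite), names(METABOLITE_CARBONS))
  if (length(bad)) stop("unknown metabolite(s): ", paste(bad, collapse = ", "), call. = FALSE)
  class(df) <- c("total_pool_table", "data.frame")
  df
}

#' Read a calibration table (known 13C concentration vs peak area)
#'
#' Expects columns `metabolite, carbon, conc_mM, area`. Requires at least two
#' distinct concentrations per (metabolite, carbon) and non-negative areas.
#'
#' @inheritParams read_isotopomer_table
#' @return A data.frame of class `calibration_table`.
#' @export
read_calibration_table <- function(path, dialect = "auto") {
  df <- read_table_file(path, c("metabolite", "carbon", "conc_mM", "area"), dialect)
  calibration_table(df$metabolite, df$carbon, df$conc_mM, df$area)
}

#' @rdname read_calibration_table
#' @param metabolite,carbon,conc_mM,area Record fields.
#' @export
calibration_table <- function(metabolite, carbon, conc_mM, area) {
  df <- data.frame(metabolite = as.character(metabolite),
                   carbon = as.integer(carbon),
                   conc_mM = as.numeric(conc_mM),
                   area = as.numeric(area), stringsAsFactors = FALSE)
  if (any(df$area < 0)) stop("negative peak area in calibration", call. = FALSE)
  n_distinct <- tapply(df$conc_mM, paste(df$metabolite, df$carbon),
                       function(v) length(unique(v)))
  if (any(n_distinct < 2)) {
    stop("calibration needs >= 2 distinct concentrations per (metabolite, carbon)",
         call. = FALSE)
  }
  class(df) <- c("calibration_table", "data.frame")
  df
}

#' Read a peak-area table
#'
#' One row per observed resonance: columns `group, replicate, metabolite,
#' carbon, multiplet, pattern, area, is_area` where `is_area` is the
#' internal-standard (1,4-dioxane) area of the spectrum the peak came from
#' (one value per spectrum, i.e. per (group, replicate)).
#'
#' @inheritParams read_isotopomer_table
#' @return A data.frame of class `peak_table`.
#' @export
read_peak_table <- function(path, dialect = "auto") {
  df <- read_table_file(path, c("group", "replicate", "metabolite", "carbon",
                                "multiplet", "pattern", "area", "is_area"), dialect)
  peak_table(df)
}

peak_table <- function(df) {
  df$carbon <- as.integer(df$carbon)
  df$area <- as.numeric(df$area)
  df$is_area <- as.numeric(df$is_area)
  if (any(df$is_area <= 0)) stop("internal-standard area must be > 0", call. = FALSE)
  if (!all(df$multiplet %in% c("singlet", "doublet"))) {
    stop("multiplet class must be 'singlet' or 'doublet'", call. = FALSE)
  }
  spec <- paste(df$group, df$replicate, sep = "\r")
  n_is <- tapply(df$is_area, spec, function(v) length(unique(v)))
  if (any(n_is != 1)) {
    stop("each spectrum (group, replicate) must carry a single internal-standard area",
         call. = FALSE)
  }
  df$pattern <- canonicalize_patterns(df$pattern)
  class(df) <- c("peak_table", "data.frame")
  df
}

#' Write a result table to CSV
#'
#' Deterministic column order (as given), fixed precision (6 significant
#' digits for numeric columns), re-readable with [read_report()].
#'
#' @param results A data.frame.
#' @param path Output path.
#' @export
write_report <- function(results, path) {
  df <- as.data.frame(results)
  for (nm in names(df)) {
    if (is.numeric(df[[nm]])) df[[nm]] <- signif(df[[nm]], 6)
  }
  dir <- dirname(path)
  if (!dir.exists(dir)) stop("unwritable path (missing directory): ", dir, call. = FALSE)
  write.csv(df, path, row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' @rdname write_report
#' @export
read_report <- function(path) {
  read.csv(path, stringsAsFactors = FALSE, fileEncoding = "UTF-8")
}
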
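#' @importFrom stats rnorm rlnorm setNames approx lm coef residuals pt sd aggregate
#' @importFrom utils read.csv write.csv packageVersion
NULL

# Carbon counts used for position validation. Backbone numbering is standard
# biochemical numbering (C1 = carboxyl / anomeric carbon). NAA C6 (the acetyl
# methyl resonance) is observable, hence 6.
METABOLITE_CARBONS <- c(
  Glu = 5L, Gln = 5L, Asp = 4L, NAA = 6L, GABA = 4L,
  MI = 6L, Ala = 3L, Lac = 3L, Glc = 6L
)

#' Known metabolite abbreviations
#'
#' @return Named integer vector of carbon counts, names are the metabolite
#'   abbreviations accepted by [parse_pattern()].
#' @export
metabolite_carbons <- function() METABOLITE_CARBONS

#' Construct a labeling pattern
#'
#' A `label_pattern` identifies a positional isotopomer: a metabolite plus the
#' set of carbon positions carrying 13C, e.g. glutamate labeled at C4 and C5.
#'
#' @param metabolite Metabolite abbreviation (one of `names(metabolite_carbons())`).
#' @param positions Integer vector of 1-based carbon positions.
#' @return Object of class `label_pattern` with fields `metabolite`, `positions`.
#' @examples
#' label_pattern("Glu", c(4, 5))
#' @export
label_pattern <- function(metabolite, positions) {
  metabolite <- as.character(metabolite)
  if (!metabolite %in% names(METABOLITE_CARBONS)) {
    stop("unknown metabolite abbreviation: '", metabolite, "'", call. = FALSE)
  }
  positions <- sort(unique(as.integer(positions)))
  if (length(positions) == 0L) {
    stop("empty position list for ", metabolite, call. = FALSE)
  }
  nc <- METABOLITE_CARBONS[[metabolite]]
  if (any(positions < 1L) || any(positions > nc)) {
    stop("position out of range for ", metabolite, " (has ", nc, " carbons): ",
         paste(positions, collapse = ","), call. = FALSE)
  }
  structure(list(metabolite = metabolite, positions = positions),
            class = "label_pattern")
}

#' Parse an isotopomer pattern string
#'
#' Accepts the dialect used in printed isotopomer tables:
#' `"[4-13C]Glu"`, `"[1,2-13C]GABA"`, with either comma or hyphen between
#' positions and optional caret superscript markup (`"[4-^13^C]Glu"`).
#'
#' @param text A single pattern string.
#' @return A [label_pattern()].
#' @examples
#' parse_pattern("[1,2-13C]GABA")
#' parse_pattern("[4-^13^C]Glu")
#' @export
parse_pattern <- function(text) {
  if (length(text) != 1L || !is.character(text)) {
    stop("parse_pattern() expects a single character string", call. = FALSE)
  }
  x <- gsub("\\^", "", trimws(text))     # drop superscript markup
  m <- regmatches(x, regexec("^\\[([0-9]+(?:[,-][0-9]+)*)[ -]*13C\\] ?([A-Za-z]+)$", x))[[1]]
  if (length(m) != 3L) {
    stop("malformed pattern string: '", text, "'", call. = FALSE)
  }
  positions <- as.integer(strsplit(m[2], "[,-]")[[1]])
  label_pattern(m[3], positions)
}

#' @export
format.label_pattern <- function(x, ...) {
  sprintf("[%s-13C]%s", paste(x$positions, collapse = ","), x$metabolite)
}

#' @export
print.label_pattern <- function(x, ...) {
  cat(format(x), "\n")
  invisible(x)
}

#' @export
as.character.label_pattern <- function(x, ...) format(x)

#' Canonicalize pattern strings
#'
#' Vectorized parse-then-format; errors on any malformed entry.
#'
#' @param x Character vector of pattern strings.
#' @return Character vector in canonical `"[p1,p2-13C]Met"` form.
#' @export
canonicalize_patterns <- function(x) {
  vapply(x, function(s) format(parse_pattern(s)), character(1), USE.NAMES = FALSE)
}

# All canonical pattern strings for a metabolite (non-empty position subsets).
# Used by property tests; exhaustive but small (<= 2^6 - 1 per metabolite).
all_patterns <- function(metabolite) {
  nc <- METABOLITE_CARBONS[[metabolite]]
  out <- character(0)
  for (k in seq_len(2^nc - 1L)) {
    pos <- which(bitwAnd(k, bitwShiftL(1L, 0:(nc - 1L))) != 0L)
    out <- c(out, format(label_pattern(metabolite, pos)))
  }
  out
}
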
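#' Severity lexicons
#'
#' A severity lexicon maps side-effect terms (lower-cased, lemmatized single
#' tokens) to positive weights; heavier weights mark medically more serious
#' reactions. Tokens not present in the lexicon receive `default_weight`
#' (and still count in the denominator of the severity score).
#'
#' @param terms character vector of terms.
#' @param weights numeric vector of positive weights, same length as `terms`.
#' @param default_weight weight assigned to out-of-lexicon tokens
#'   (non-negative, default 1).
#' @return An object of class `severity_lexicon`.
#' @seealso [read_lexicon()], [default_lexicon()], [severity_score()]
#' @export
severity_lexicon <- function(terms, weights, default_weight = 1) {
  terms <- tolower(trimws(as.character(terms)))
  weights <- as.numeric(weights)
  if (length(terms) != length(weights))
    stop("terms and weights must have the same length")
  if (any(!is.finite(weights)) || any(weights <= 0))
    stop("all lexicon weights must be finite and > 0")
  if (!is.finite(default_weight) || default_weight < 0)
    stop("default_weight must be finite and >= 0")
  if (anyDuplicated(terms))
    stop("duplicate lexicon terms: ",
         paste(unique(terms[duplicated(terms)]), collapse = ", "))
  w <- stats::setNames(weights, terms)
  structure(list(weights = w, default_weight = default_weight),
            class = "severity_lexicon")
}

#' Read a severity lexicon from a TSV file
#'
#' Expects two tab-separated columns `term<TAB>weight`, one entry per line;
#' lines starting with `#` are comments.
#'
#' @param path path to the TSV file.
#' @param default_weight see [severity_lexicon()].
#' @return A `severity_lexicon`.
#' @export
read_lexicon <- function(path, default_weight = 1) {
  if (!file.exists(path)) stop("lexicon file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- lengths(parts) < 2
  if (any(bad)) stop("malformed lexicon line(s): ",
                     paste(lines[bad], collapse = "; "))
  severity_lexicon(vapply(parts, `[[`, "", 1L),
                   as.numeric(vapply(parts, `[[`, "", 2L)),
                   default_weight = default_weight)
}

#' Built-in three-tier toy lexicon
#'
#' A ~40-term lexicon with mild (weight 1), moderate (weight 2) and severe
#' (weight 3) tiers, shipped for tests and examples in place of proprietary
#' terminologies such as MedDRA. Any user-supplied two-column lexicon can be
#' substituted via [read_lexicon()].
#'
#' @param default_weight see [severity_lexicon()].
#' @return A `severity_lexicon`.
#' @export
default_lexicon <- function(default_weight = 1) {
  read_lexicon(system.file("extdata", "severity_lexicon.tsv",
                           package = "drugsel", mustWork = TRUE),
               default_weight = default_weight)
}

#' @export
print.severity_lexicon <- function(x, ...) {
  cat("Severity lexicon:", length(x$weights), "terms, weights in [",
      min(x$weights), ",", max(x$weights), "], default",
      x$default_weight, "\n")
  invisible(x)
}
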
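#' Tokenize and normalize side-effect free text
#'
#' Lower-cases, strips punctuation and digits, splits on whitespace and
#' applies a small rule-based English lemmatizer (de-pluralization with
#' guards for -ss/-us/-is endings, -ies to -y). Deterministic for a fixed
#' input; frozen by golden-file tests.
#'
#' @param text a single character string (NA or "" give an empty token list).
#' @return Character vector of tokens (possibly length 0).
#' @examples
#' clean_tokens("Hives; difficult breathing")
#' @export
clean_tokens <- function(text) {
  if (length(text) != 1L) stop("clean_tokens() expects a single string")
  if (is.na(text) || !nzchar(text)) return(character(0))
  x <- tolower(text)
  x <- gsub("[^a-z]+", " ", x)
  toks <- strsplit(trimws(x), " ", fixed = TRUE)[[1L]]
  toks <- toks[nzchar(toks)]
  if (!length(toks)) return(character(0))
  vapply(toks, lemmatize_token, character(1L), USE.NAMES = FALSE)
}

# Light rule-based lemmatizer: noun de-pluralization only. Verbs and
# inflections other than plural -s are left as-is ("breathing" stays).
lemmatize_token <- function(tok) {
  n <- nchar(tok)
  if (n < 4L) return(tok)
  if (grepl("(ss|us|is)$", tok)) return(tok)          # dizziness, virus, ...
  if (grepl("ies$", tok) && n > 4L) return(sub("ies$", "y", tok))
  if (grepl("(ches|shes|xes|zes)$", tok)) return(sub("es$", "", tok))
  if (grepl("s$", tok)) return(sub("s$", "", tok))    # hives -> hive
  tok
}

#' Lexicon-weighted side-effect severity score
#'
#' The severity of a token list is the frequency-weighted mean lexicon
#' weight, S = sum_j w_j f_j / sum_j f_j, where f_j counts occurrences of
#' term j and out-of-lexicon tokens contribute the lexicon's
#' `default_weight` (and count in the denominator). An empty token list
#' scores 0.
#'
#' @param tokens character vector of tokens (see [clean_tokens()]).
#' @param lexicon a [severity_lexicon()].
#' @return A single numeric severity score.
#' @examples
#' lex <- severity_lexicon(c("a", "b"), c(1, 4))
#' severity_score(c("a", "a", "b"), lex)  # 2
#' @export
severity_score <- function(tokens, lexicon) {
  stopifnot(inherits(lexicon, "severity_lexicon"))
  if (!length(tokens)) return(0)
  w <- unname(lexicon$weights[tokens])
  w[is.na(w)] <- lexicon$default_weight
  mean(w)
}

#' Read a drug-review table from CSV
#'
#' Reads a comma-delimited UTF-8 table with a header row and builds an
#' unnormalized `drug_table`. Rows missing the drug name, rating or review
#' count are dropped (the drop count is recorded); conditions and drug
#' classes are label-encoded in first-appearance order so codes are stable
#' under re-encoding of the same table.
#'
#' Default column names are `drug_name, medical_condition, rating,
#' side_effects, no_of_reviews, drug_classes`; `schema_map` remaps any of
#' the logical names `drug_name, condition, rating, side_effects, reviews,
#' drug_class` to other column headers.
#'
#' @param path path to the CSV file.
#' @param schema_map optional named list/vector remapping column names.
#' @return A `drug_table` (unnormalized; see [compute_severity()] and
#'   [normalize_features()], or [prepare_drug_table()] for the full
#'   pipeline).
#' @export
read_drug_table <- function(path, schema_map = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE,
                        colClasses = "character")
  as_drug_table(df, schema_map = schema_map)
}

#' Build a drug table from a data frame
#'
#' @param df a data frame in the drug-review schema (see
#'   [read_drug_table()]).
#' @inheritParams read_drug_table
#' @return A `drug_table`.
#' @export
as_drug_table <- function(df, schema_map = NULL) {
  map <- list(drug_name = "drug_name", condition = "medical_condition",
              rating = "rating", side_effects = "side_effects",
              reviews = "no_of_reviews", drug_class = "drug_classes")
  if (!is.null(schema_map)) map <- utils::modifyList(map, as.list(schema_map))
  missing_cols <- setdiff(unlist(map), names(df))
  if (length(missing_cols))
    stop("schema error: missing column(s): ",
         paste(missing_cols, collapse = ", "))

  drug_name <- trimws(as.character(df[[map$drug_name]]))
  rating <- suppressWarnings(as.numeric(df[[map$rating]]))
  reviews <- suppressWarnings(as.numeric(gsub(",", "", df[[map$reviews]],
                                              fixed = TRUE)))
  keep <- !is.na(rating) & !is.na(reviews) & !is.na(drug_name) &
    nzchar(drug_name)
  n_dropped <- sum(!keep)
  if (!any(keep)) stop("empty-table error: no records survive filtering")

  condition <- as.character(df[[map$condition]])[keep]
  drug_class <- as.character(df[[map$drug_class]])[keep]
  drug_class[is.na(drug_class)] <- ""
  out <- data.frame(
    drug_name = drug_name[keep],
    condition = condition,
    rating_raw = rating[keep],
    review_count = reviews[keep],
    side_effect_text = as.character(df[[map$side_effects]])[keep],
    drug_class = drug_class,
    condition_code = match(condition, unique(condition)),
    class_code = match(drug_class, unique(drug_class)),
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  structure(out, n_dropped = n_dropped, normalized = FALSE,
            class = c("drug_table", "data.frame"))
}

#' Compute per-record side-effect severity
#'
#' Tokenizes each record's side-effect text ([clean_tokens()]) and scores it
#' with [severity_score()]. With `metric = "token_count"` the raw token
#' count is used as the side-effect magnitude instead of the lexicon score
#' (the two readings of "side-effect length"); the default is the lexicon
#' severity.
#'
#' @param table a `drug_table`.
#' @param lexicon a [severity_lexicon()]; defaults to the built-in tiers.
#' @param metric `"severity"` (lexicon-weighted, default) or
#'   `"token_count"`.
#' @return The table with `severity` and `n_tokens` columns added.
#' @export
compute_severity <- function(table, lexicon = default_lexicon(),
                             metric = c("severity", "token_count")) {
  stopifnot(inherits(table, "drug_table"))
  metric <- match.arg(metric)
  toks <- lapply(table$side_effect_text, clean_tokens)
  table$n_tokens <- lengths(toks)
  table$severity <- if (metric == "severity") {
    vapply(toks, severity_score, numeric(1L), lexicon = lexicon)
  } else {
    as.numeric(lengths(toks))
  }
  attr(table, "side_effect_metric") <- metric
  table
}

#' Min-max normalize the three selection criteria
#'
#' Maps rating, severity and review count to \[0, 1\] via
#' (X - Xmin) / (Xmax - Xmin). A degenerate feature (Xmax = Xmin) maps to 0
#' for all records. The normalization statistics are stored on the table so
#' scores are reproducible; passing stored `stats` re-applies them
#' unchanged (idempotence).
#'
#' @param table a `drug_table` with `severity` computed.
#' @param stats optional previously stored statistics
#'   (`attr(table, "norm_stats")`); if `NULL`, computed from the table.
#' @return The table with `rating_norm`, `severity_norm`, `reviews_norm`
#'   columns and a `norm_stats` attribute.
#' @export
normalize_features <- function(table, stats = NULL) {
  stopifnot(inherits(table, "drug_table"))
  if (is.null(table$severity))
    stop("severity not computed; call compute_severity() first")
  if (is.null(stats)) {
    stats <- list(rating = range(table$rating_raw),
                  severity = range(table$severity),
                  reviews = range(table$review_count))
  }
  minmax <- function(x, r) {
    if (r[2L] > r[1L]) (x - r[1L]) / (r[2L] - r[1L]) else rep(0, length(x))
  }
  table$rating_norm <- minmax(table$rating_raw, stats$rating)
  table$severity_norm <- minmax(table$severity, stats$severity)
  table$reviews_norm <- minmax(table$review_count, stats$reviews)
  attr(table, "norm_stats") <- stats
  attr(table, "normalized") <- TRUE
  table
}

#' Full preprocessing pipeline
#'
#' Convenience wrapper: load (or accept) a drug-review table, compute
#' severity and min-max normalize. Deterministic: two calls on the same
#' input give identical tables.
#'
#' @param x a CSV path or a data frame in the drug-review schema.
#' @inheritParams read_drug_table
#' @inheritParams compute_severity
#' @return A normalized `drug_table`.
#' @export
prepare_drug_table <- function(x, schema_map = NULL,
                               lexicon = default_lexicon(),
                               metric = c("severity", "token_count")) {
  tab <- if (is.character(x)) read_drug_table(x, schema_map)
         else as_drug_table(x, schema_map)
  tab <- compute_severity(tab, lexicon = lexicon, metric = metric)
  normalize_features(tab)
}

is_normalized <- function(table) isTRUE(attr(table, "normalized"))

#' Write a normalized table and its normalization sidecar
#'
#' Writes the table as CSV plus a JSON sidecar (same path with extension
#' `.json`) holding the min-max statistics and the drop count.
#'
#' @param table a normalized `drug_table`.
#' @param path output CSV path.
#' @return Invisibly, the two paths written.
#' @export
write_drug_table <- function(table, path) {
  stopifnot(inherits(table, "drug_table"))
  utils::write.csv(as.data.frame(table), path, row.names = FALSE)
  sidecar <- sub("\\.csv$", "", path)
  sidecar <- paste0(sidecar, ".json")
  st <- attr(table, "norm_stats")
  json <- sprintf(paste0(
    '{"n_records": %d, "n_dropped": %d, "norm_stats": {',
    '"rating": [%.10g, %.10g], "severity": [%.10g, %.10g], ',
    '"reviews": [%.10g, %.10g]}}'),
    nrow(table), attr(table, "n_dropped") %||% 0L,
    st$rating[1L], st$rating[2L], st$severity[1L], st$severity[2L],
    st$reviews[1L], st$reviews[2L])
  writeLines(json, sidecar)
  invisible(c(csv = path, json = sidecar))
}

#' @export
print.drug_table <- function(x, ...) {
  cat(sprintf("Drug table: %d records (%d dropped on load)%s\n",
              nrow(x), attr(x, "n_dropped") %||% 0L,
              if (is_normalized(x)) ", normalized" else ""))
  print.data.frame(utils::head(as.data.frame(x)[,
    intersect(c("drug_name", "condition", "rating_raw", "review_count",
                "severity"), names(x))]), ...)
  invisible(x)
}
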
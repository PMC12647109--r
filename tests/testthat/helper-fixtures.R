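# Fixtures are generated in code; heavier shared ones are cached per session.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (is.null(.fixture_cache[[key]])) .fixture_cache[[key]] <- force(expr)
  .fixture_cache[[key]]
}

# Build a normalized drug_table directly from raw criterion values.
toy_table <- function(rating, severity, reviews) {
  n <- length(rating)
  df <- data.frame(
    drug_name = sprintf("d%02d", seq_len(n)),
    condition = rep("pain", n),
    rating_raw = rating,
    review_count = reviews,
    side_effect_text = rep("", n),
    drug_class = rep("", n),
    condition_code = rep(1L, n),
    class_code = rep(1L, n),
    stringsAsFactors = FALSE)
  tab <- structure(df, n_dropped = 0L, normalized = FALSE,
                   class = c("drug_table", "data.frame"))
  tab$severity <- severity
  normalize_features(tab)
}

# Planted-small instance (D = 12, k = 3) shared by optimizer tests.
small_fixture <- function() {
  cached("small", {
    gen <- generate_drug_table(synth_preset("planted-small", seed = 7))
    tab <- prepare_drug_table(gen$table)
    bf <- brute_force_optimum(tab, 3)
    list(gen = gen, tab = tab, bf = bf)
  })
}

# A mid-sized unplanted table for bound/penalty property checks.
unplanted_fixture <- function() {
  cached("unplanted50", {
    df <- generate_unplanted(synthetic_spec(D = 50, seed = 19))
    prepare_drug_table(df)
  })
}

write_temp_csv <- function(df) {
  p <- tempfile(fileext = ".csv")
  utils::write.csv(df, p, row.names = FALSE)
  p
}

# Independent severity oracle: explicit term-frequency loop.
severity_oracle <- function(tokens, lexicon) {
  if (!length(tokens)) return(0)
  counts <- table(tokens)
  terms <- names(counts)
  w <- vapply(terms, function(tm) {
    if (tm %in% names(lexicon$weights)) unname(lexicon$weights[[tm]])
    else lexicon$default_weight
  }, numeric(1L))
  sum(w * as.numeric(counts)) / sum(counts)
}
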
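test_that("loading drops incomplete rows and label-encodes by first appearance", {
  df <- data.frame(
    drug_name = c("a", "b", "c", "d", "e"),
    medical_condition = c("pain", "acne", "pain", "acne", "flu"),
    rating = c("8.1", "", "7.0", "9.9", "5.5"),
    side_effects = rep("nausea", 5),
    no_of_reviews = c("10", "20", "1,234", "4", "7"),
    drug_classes = c("x", "y", "x", "", "y"),
    stringsAsFactors = FALSE)
  tab <- read_drug_table(write_temp_csv(df))
  expect_s3_class(tab, "drug_table")
  expect_equal(nrow(tab), 4L)
  expect_equal(attr(tab, "n_dropped"), 1L)
  expect_equal(tab$condition_code, c(1L, 1L, 2L, 3L))   # pain, pain, acne, flu
  expect_equal(tab$review_count[2L], 1234)               # comma thousands
  # re-encoding the same table gives identical codes
  tab2 <- read_drug_table(write_temp_csv(df))
  expect_identical(tab$condition_code, tab2$condition_code)
  expect_identical(tab$class_code, tab2$class_code)
})

test_that("schema errors name the missing column and empty tables are refused", {
  df <- data.frame(drug = "a", medical_condition = "pain", rating = "8",
                   side_effects = "", no_of_reviews = "1",
                   drug_classes = "")
  expect_error(read_drug_table(write_temp_csv(df)), "drug_name")
  # schema_map remaps the nonstandard header
  tab <- read_drug_table(write_temp_csv(df),
                         schema_map = list(drug_name = "drug"))
  expect_equal(tab$drug_name, "a")
  bad <- df; names(bad)[names(bad) == "drug"] <- "drug_name"
  bad$rating <- ""
  expect_error(read_drug_table(write_temp_csv(bad)), "empty-table")
})

test_that("tokenization is lower-cased, punctuation-free and lemmatized", {
  # golden outputs of the frozen rule-based lemmatizer
  expect_equal(clean_tokens("Hives; difficult breathing"),
               c("hive", "difficult", "breathing"))
  expect_equal(clean_tokens(""), character(0))
  expect_equal(clean_tokens(NA_character_), character(0))
  expect_equal(clean_tokens("DIZZINESS, dizziness."),
               c("dizziness", "dizziness"))
  expect_equal(clean_tokens("allergies, rashes!"), c("allergy", "rash"))
  # deterministic
  expect_identical(clean_tokens("Nausea & vomiting (severe)"),
                   clean_tokens("Nausea & vomiting (severe)"))
})

test_that("severity score is the frequency-weighted mean lexicon weight", {
  lex <- severity_lexicon(c("a", "b"), c(1, 4))
  expect_equal(severity_score(c("a", "a", "b"), lex), 2)
  expect_equal(severity_score(rep("a", 7), severity_lexicon("a", 3)), 3)
  expect_equal(severity_score(character(0), lex), 0)
  # out-of-lexicon tokens take default_weight and count in the denominator
  lex1 <- severity_lexicon("a", 2, default_weight = 1)
  expect_equal(severity_score(c("a", "zzz"), lex1), 1.5)
})

test_that("severity matches a brute-force frequency oracle on random token lists", {
  lex <- default_lexicon()
  vocab <- c(names(lex$weights), "unknownone", "unknowntwo")
  set.seed(404)
  ok <- vapply(seq_len(1000), function(i) {
    toks <- sample(vocab, sample(0:50, 1L), replace = TRUE)
    abs(severity_score(toks, lex) - severity_oracle(toks, lex)) <= 1e-12
  }, logical(1L))
  expect_true(all(ok))
})

test_that("min-max normalization maps to [0,1] with degenerate features at 0", {
  tab <- toy_table(rating = c(2, 6, 10), severity = c(1, 2, 3),
                   reviews = c(7, 7, 7))
  expect_equal(tab$rating_norm, c(0, 0.5, 1))
  expect_equal(tab$reviews_norm, c(0, 0, 0))   # constant feature
  up <- unplanted_fixture()
  for (col in c("rating_norm", "severity_norm", "reviews_norm")) {
    expect_equal(min(up[[col]]), 0)
    expect_equal(max(up[[col]]), 1)
  }
})

test_that("normalization with stored statistics is idempotent", {
  up <- unplanted_fixture()
  again <- normalize_features(up, stats = attr(up, "norm_stats"))
  expect_identical(up$rating_norm, again$rating_norm)
  expect_identical(up$severity_norm, again$severity_norm)
  expect_identical(up$reviews_norm, again$reviews_norm)
})

test_that("the full preprocessing pipeline is deterministic", {
  df <- generate_unplanted(synthetic_spec(D = 30, seed = 5))
  p <- write_temp_csv(df)
  t1 <- prepare_drug_table(p)
  t2 <- prepare_drug_table(p)
  expect_identical(t1, t2)
})

test_that("lexicon TSV round-trips with comments and validation", {
  p <- tempfile(fileext = ".tsv")
  writeLines(c("# comment", "nausea\t1", "seizure\t3"), p)
  lex <- read_lexicon(p)
  expect_equal(unname(lex$weights[c("nausea", "seizure")]), c(1, 3))
  expect_error(severity_lexicon("a", -1), "> 0")
  expect_error(severity_lexicon(c("a", "a"), c(1, 2)), "duplicate")
})

test_that("table export writes the CSV and a normalization sidecar", {
  up <- unplanted_fixture()
  p <- tempfile(fileext = ".csv")
  paths <- write_drug_table(up, p)
  expect_true(all(file.exists(paths)))
  side <- paste(readLines(paths["json"]), collapse = "")
  expect_match(side, "norm_stats")
  expect_match(side, sprintf('"n_records": %d', nrow(up)))
})
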
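test_that("diagnosis codes roll up to the third ICD level", {
  expect_equal(rollup_icd("C341M"), "C34")
  expect_equal(rollup_icd("I10"), "I10")
  expect_equal(rollup_icd("E119"), "E11")
  expect_equal(rollup_icd(c("A0123", "B9"), level = 3), c("A01", "B9"))
  expect_error(rollup_icd(""), "empty")
})

test_that("lab bins are empirical quantiles with degenerate fallbacks", {
  lb <- data.table::data.table(component = "X", specimen = "P", unit = "u",
                               value = 1:100)
  b <- fit_lab_bins(lb, q = 10)
  tok <- lab_token(lb, b)
  expect_equal(as.vector(table(tok)[unique(tok)]), rep(10L, 10))
  const <- data.table::data.table(component = "K", specimen = "P",
                                  unit = "u", value = rep(5, 20))
  bc <- fit_lab_bins(const, q = 10)
  expect_equal(length(bc$edges[["K_P_u"]]), 2L)
  expect_equal(unique(lab_token(const, bc)), "K_P_u@5-5")
  # non-numeric values are skipped and counted
  mix <- data.table::data.table(component = "X", specimen = "P", unit = "u",
                                value = c("1", "2", "oops", NA, "3"))
  bm <- fit_lab_bins(mix, q = 2)
  expect_equal(bm$n_skipped, 2L)
})

test_that("decile occupancies match a sort-and-slice oracle on lognormal data", {
  set.seed(7)
  v <- rlnorm(5000, 1, 0.8)
  lb <- data.table::data.table(component = "L", specimen = "P", unit = "u",
                               value = v)
  b <- fit_lab_bins(lb, q = 10)
  occ <- table(lab_token(lb, b))
  expect_equal(length(occ), 10L)
  expect_true(all(abs(occ / 5000 - 0.1) < 0.02))
  oracle_edges <- sort(v)[c(1, round(seq_len(9) / 10 * 5000 + 0.5))]
  expect_true(all(abs(b$edges[["L_P_u"]][2:10] - oracle_edges[2:10]) <
                    diff(range(v)) * 0.01))
})

test_that("lab tokens render edges like 8-8.5 and clamp out-of-range values", {
  b <- structure(list(q = 10, edges = list(
    "HEMOGLOBIN_B_mmol/L" = c(5, 6, 7, 7.5, 8, 8.5, 9, 9.5, 10, 10.5, 11)),
    n_skipped = 0L), class = "lab_binning")
  rec <- function(v) data.table::data.table(component = "HEMOGLOBIN",
                                            specimen = "B", unit = "mmol/L",
                                            value = v)
  expect_equal(lab_token(rec(8.2), b), "HEMOGLOBIN_B_mmol/L@8-8.5")
  expect_equal(lab_token(rec(1), b), "HEMOGLOBIN_B_mmol/L@5-6")
  expect_equal(lab_token(rec(99), b), "HEMOGLOBIN_B_mmol/L@10.5-11")
  expect_warning(out <- lab_token(data.table::data.table(
    component = "NEW", specimen = "B", unit = "x", value = 1), b), "unseen")
  expect_equal(out, "UNK")
})

test_that("every re-tokenized training value lies inside its own bin", {
  set.seed(11)
  v <- c(rnorm(500, 10, 3), rlnorm(500, 0, 1))
  lb <- data.table::data.table(component = "A", specimen = "B", unit = "u",
                               value = v)
  b <- fit_lab_bins(lb, q = 10)
  toks <- lab_token(lb, b)
  rng <- regmatches(toks, regexpr("@.*$", toks))
  parts <- do.call(rbind, strsplit(sub("@", "", rng), "-(?=[0-9.])",
                                   perl = TRUE))
  lo <- as.numeric(parts[, 1]); hi <- as.numeric(parts[, 2])
  # edges print at 4 significant digits; allow that rounding slack
  eps <- pmax(abs(v), 1) * 1e-3
  expect_true(all(v >= lo - eps & v <= hi + eps))
})

test_that("note cleaning lowercases, strips punctuation and drops lexicon tokens", {
  lex <- default_note_lexicons()
  expect_equal(preprocess_note(c("Pain,", "in", "the", "chest"),
                               list(stopwords = c("in", "the"),
                                    negations = character(),
                                    signature_patterns = character())),
               c("pain", "chest"))
  expect_equal(preprocess_note(character(0)), character(0))
  expect_equal(preprocess_note(c("Dr-Jensen", "ikke", "febrile", ".", ",")),
               "febrile")
  w <- fixture_world()
  cleaned <- unlist(preprocess_notes(head(w$ehr$notes$text, 500)),
                    use.names = FALSE)
  expect_length(intersect(cleaned, c(lex$stopwords, lex$negations)), 0)
  expect_false(any(grepl("^dr-", cleaned)))
})

test_that("vocabulary construction follows min_freq and id conventions", {
  v <- build_vocab(c("A", "A", "B"), min_freq = 2)
  expect_identical(v$tokens, "A")
  expect_equal(unname(v$index[["A"]]), 2L)
  expect_equal(wardflow:::encode_tokens("B", v), 1L)  # UNK
  v1 <- build_vocab(c("A", "A", "B"), min_freq = 1)
  expect_false(any(wardflow:::encode_tokens(c("A", "B"), v1) == 1L))
  # descending frequency, lexicographic tie-break
  v2 <- build_vocab(c(rep("z", 3), rep("a", 2), rep("b", 2)), min_freq = 1)
  expect_identical(v2$tokens, c("z", "a", "b"))
  expect_error(build_vocab(character(0)), "empty")
})

test_that("vocabulary size is non-increasing in min_freq on a Zipf corpus", {
  set.seed(3)
  corpus <- paste0("w", sample(1:200, 5000, replace = TRUE,
                               prob = 1 / (1:200)))
  sizes <- vapply(1:8, function(mf) vocab_size(build_vocab(corpus, mf)),
                  integer(1))
  expect_true(all(diff(sizes) <= 0))
  # oracle: recount per threshold
  tab <- table(corpus)
  expect_equal(sizes, vapply(1:8, function(mf)
    sum(tab >= mf) + 2L, integer(1)))
})

test_that("encoding keeps the most recent tokens and round-trips", {
  v <- build_vocab(c("A", "A", "B"), min_freq = 1)
  e <- encode_sequence(c("A", "B"), v, 5)
  expect_identical(e$ids, c(unname(v$index[["A"]]), unname(v$index[["B"]]),
                            0L, 0L, 0L))
  expect_identical(e$mask, c(1L, 1L, 0L, 0L, 0L))
  s12 <- as.character(1:12)
  v2 <- build_vocab(s12, 1)
  e2 <- encode_sequence(s12, v2, 9)
  expect_identical(decode_sequence(e2$ids, v2), as.character(4:12))
  # rare tokens decode to UNK in the retained suffix
  set.seed(4)
  for (i in 1:20) {
    corpus <- paste0("t", sample(1:30, 200, TRUE))
    vv <- build_vocab(corpus, min_freq = 3)
    x <- paste0("t", sample(1:40, 15, TRUE))
    enc <- encode_sequence(x, vv, 10)
    kept <- tail(x, 10)
    expected <- ifelse(kept %in% vv$tokens, kept, "UNK")
    expect_identical(decode_sequence(enc$ids, vv), expected)
  }
})

test_that("vocabularies and bins depend only on the training split", {
  w <- fixture_world()
  ehr2 <- w$ehr
  non_train <- w$cohort$splits[split != "train"]$patient_id
  # scramble every non-training record's content
  ehr2$labs <- data.table::copy(ehr2$labs)
  sel <- ehr2$labs$patient_id %in% non_train
  ehr2$labs[sel, value := rev(value)]
  ehr2$notes <- data.table::copy(ehr2$notes)
  seln <- ehr2$notes$patient_id %in% non_train
  ehr2$notes[seln, text := "scrambled content entirely"]
  ehr2$diagnoses <- data.table::copy(ehr2$diagnoses)
  seld <- ehr2$diagnoses$patient_id %in% non_train
  ehr2$diagnoses[seld, code := "Z99"]
  tk2 <- fit_tokenizer(ehr2, w$cohort)
  expect_identical(tk2$vocabs$diag$tokens, w$tokenizer$vocabs$diag$tokens)
  expect_identical(tk2$vocabs$lab$tokens, w$tokenizer$vocabs$lab$tokens)
  expect_identical(tk2$vocabs$note$tokens, w$tokenizer$vocabs$note$tokens)
  expect_identical(tk2$binning$edges, w$tokenizer$binning$edges)
})

test_that("vocabularies survive a JSON round-trip", {
  v <- build_vocab(c(rep("alpha", 5), rep("beta", 3), "gamma"), min_freq = 2,
                   domain = "note")
  path <- withr::local_tempfile(fileext = ".json")
  write_vocab(v, path)
  v2 <- read_vocab(path)
  expect_identical(v2$tokens, v$tokens)
  expect_identical(v2$index, v$index)
})
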
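# Multi-domain tokenization: ICD roll-up, quantile-binned laboratory tokens,
# clinical-note cleaning, vocabulary construction and padded integer encoding.
# Vocabularies and bin edges are fitted on the training split only.

#' Roll a diagnosis code up to a coarser ICD level
#'
#' Returns the first `level` characters of the code (e.g. `"C341M"` rolls up
#' to `"C34"` at level 3); codes shorter than `level` are returned unchanged.
#' Vectorized.
#'
#' @param code character vector of alphanumeric diagnosis codes.
#' @param level number of leading characters to keep (default 3).
#' @return character vector of rolled-up tokens.
#' @export
rollup_icd <- function(code, level = 3) {
  if (any(is.na(code)) || any(!nzchar(code))) {
    stop("empty diagnosis code", call. = FALSE)
  }
  substr(code, 1L, level)
}

.lab_key <- function(component, specimen, unit) {
  paste(component, specimen, unit, sep = "_")
}

#' Fit per-analyte quantile bins on training laboratory values
#'
#' For every (component, specimen, unit) key the empirical `q`-quantiles of
#' the training values become the bin edges. Analytes with fewer than `q`
#' distinct values fall back to as many bins as the data support; a constant
#' analyte yields a single degenerate bin. Non-numeric values are skipped and
#' counted.
#'
#' @param labs training-split lab records with columns `component`,
#'   `specimen`, `unit`, `value`.
#' @param q number of quantile bins (default 10, i.e. deciles).
#' @return a `lab_binning` object: list with `q`, `edges` (named list of
#'   numeric edge vectors) and `n_skipped`.
#' @export
fit_lab_bins <- function(labs, q = 10) {
  lb <- data.table::as.data.table(labs)
  assert_cols(lb, c("component", "specimen", "unit", "value"), "labs")
  val <- suppressWarnings(as.numeric(lb$value))
  n_skipped <- sum(is.na(val) & !is.na(lb$value)) + sum(is.na(lb$value))
  lb <- lb[!is.na(val)]
  lb[, v := val[!is.na(val)]]
  lb[, key := .lab_key(component, specimen, unit)]
  edges <- lapply(split(lb$v, lb$key), function(v) {
    e <- unique(stats::quantile(v, probs = seq(0, 1, length.out = q + 1),
                                type = 7, names = FALSE))
    if (length(e) == 1L) e <- c(e, e)  # constant analyte: single degenerate bin
    e
  })
  structure(list(q = q, edges = edges, n_skipped = n_skipped),
            class = "lab_binning")
}

# 4 significant digits, trailing zeros stripped (decile label style "8-8.5")
.fmt_edge <- function(x) {
  vapply(x, function(xi) format(signif(xi, 4), trim = TRUE,
                                scientific = FALSE),
         character(1))
}

#' Render laboratory records as quantile tokens
#'
#' Token format is `COMPONENT_SPECIMEN_unit@lo-hi` where `lo`/`hi` are the
#' decile edges of the bin holding the value (e.g.
#' `"HEMOGLOBIN_B_mmol/L@8-8.5"`). Values outside the training range clamp to
#' the first/last bin; analyte keys unseen during fitting yield `"UNK"` with
#' a warning.
#'
#' @param labs lab records with `component`, `specimen`, `unit`, `value`.
#' @param binning a [fit_lab_bins()] result.
#' @return character vector of tokens, one per record.
#' @export
lab_token <- function(labs, binning) {
  stopifnot(inherits(binning, "lab_binning"))
  lb <- data.table::as.data.table(labs)
  key <- .lab_key(lb$component, lb$specimen, lb$unit)
  val <- suppressWarnings(as.numeric(lb$value))
  out <- character(nrow(lb))
  known <- key %in% names(binning$edges)
  if (any(!known)) {
    warning(sprintf("%d lab record(s) with analyte key unseen in training; %s",
                    sum(!known), "emitting UNK"), call. = FALSE)
    out[!known] <- "UNK"
  }
  for (k in unique(key[known])) {
    idx <- which(key == k)
    e <- binning$edges[[k]]
    nb <- length(e) - 1L
    bin <- findInterval(val[idx], e, all.inside = TRUE)  # clamps to end bins
    bin <- pmin(pmax(bin, 1L), nb)
    lab <- paste0(k, "@", .fmt_edge(e[-length(e)]), "-", .fmt_edge(e[-1L]))
    out[idx] <- lab[bin]
  }
  out
}

#' Default stop-word, negation and signature lexicons for note cleaning
#' @return list with `stopwords`, `negations`, `signature_patterns`.
#' @export
default_note_lexicons <- function() {
  list(
    stopwords = c("og", "i", "paa", "the", "in", "of", "at", "a", "an",
                  "and", "to", "den", "det", "er", "som", "med", "for"),
    negations = c("ikke", "not", "no", "uden", "without", "never", "neither"),
    signature_patterns = c("^dr-", "^md-")
  )
}

#' Clean a clinical-note token stream
#'
#' Lower-cases tokens, drops tokens matching clinician-signature patterns,
#' strips punctuation characters, and removes punctuation-only tokens,
#' stop words and negation terms. Token order is preserved.
#'
#' @param tokens character vector of raw tokens, or a single string that is
#'   split on whitespace.
#' @param lexicons list as returned by [default_note_lexicons()].
#' @return character vector of cleaned tokens.
#' @export
preprocess_note <- function(tokens, lexicons = default_note_lexicons()) {
  if (length(tokens) == 1L && grepl("\\s", tokens)) {
    tokens <- strsplit(tokens, "\\s+")[[1L]]
  }
  if (!length(tokens)) return(character(0))
  tok <- tolower(tokens)
  for (pat in lexicons$signature_patterns) {
    tok <- tok[!grepl(pat, tok)]
  }
  tok <- gsub("[[:punct:]]", "", tok)
  tok <- tok[nzchar(tok)]
  tok[!(tok %in% c(lexicons$stopwords, lexicons$negations))]
}

# vectorized cleaning of many note texts; returns a list of token vectors.
# The cleaning rules run once per unique raw token and are mapped back, which
# keeps large corpora fast; the result matches preprocess_note() per note.
preprocess_notes <- function(texts, lexicons = default_note_lexicons()) {
  toks <- strsplit(texts, "\\s+")
  lens <- lengths(toks)
  flat <- unlist(toks, use.names = FALSE)
  note_id <- rep.int(seq_along(texts), lens)
  u <- unique(flat)
  u_low <- tolower(u)
  u_keep <- rep(TRUE, length(u))
  for (pat in lexicons$signature_patterns) {
    u_keep <- u_keep & !grepl(pat, u_low)
  }
  u_clean <- gsub("[[:punct:]]", "", u_low)
  u_keep <- u_keep & nzchar(u_clean) &
    !(u_clean %in% c(lexicons$stopwords, lexicons$negations))
  m <- match(flat, u)
  keep <- u_keep[m]
  unname(split(u_clean[m][keep],
               factor(note_id[keep], levels = seq_along(texts))))
}

PAD_ID <- 0L
UNK_ID <- 1L

#' Build a per-domain vocabulary with PAD/UNK conventions
#'
#' Tokens with training frequency below `min_freq` are dropped (they encode
#' to UNK). Ids are assigned by descending frequency with lexicographic
#' tie-break; PAD is always id 0 and UNK id 1.
#'
#' @param tokens character vector: the training-split token stream.
#' @param min_freq minimum retained frequency (default 1).
#' @param domain optional domain tag stored with the vocabulary.
#' @return a `wardflow_vocab`: list with `domain`, `min_freq`, `tokens`
#'   (retained tokens in id order, ids 2, 3, ...), `freqs`, and `index`
#'   (named id lookup).
#' @export
build_vocab <- function(tokens, min_freq = 1, domain = "") {
  if (!length(tokens)) stop_data("cannot build a vocabulary from an empty corpus")
  cnt <- data.table::data.table(token = tokens)[, .N, by = token]
  cnt <- cnt[N >= min_freq]
  data.table::setorder(cnt, -N, token)
  toks <- cnt$token
  freqs <- cnt$N
  index <- seq_along(toks) + 1L
  names(index) <- toks
  structure(list(domain = domain, min_freq = min_freq, tokens = toks,
                 freqs = freqs, index = index),
            class = "wardflow_vocab")
}

#' @export
print.wardflow_vocab <- function(x, ...) {
  cat(sprintf("<wardflow_vocab domain=%s size=%d (+PAD,UNK) min_freq=%d>\n",
              x$domain, length(x$tokens), x$min_freq))
  invisible(x)
}

#' Vocabulary size including PAD and UNK
#' @param vocab a `wardflow_vocab`.
#' @return integer count of ids.
#' @export
vocab_size <- function(vocab) length(vocab$tokens) + 2L

encode_tokens <- function(tokens, vocab) {
  ids <- unname(vocab$index[tokens])
  ids[is.na(ids)] <- UNK_ID
  as.integer(ids)
}

#' Encode a token sequence to a fixed-length id vector with mask
#'
#' Keeps the `pad_size` most recent tokens (the oldest are truncated first),
#' maps out-of-vocabulary tokens to UNK, and right-pads with PAD. The mask
#' marks real (non-PAD) positions.
#'
#' @param tokens character vector in chronological order.
#' @param vocab a [build_vocab()] result.
#' @param pad_size fixed sequence length (>= 1).
#' @return list with integer `ids` and 0/1 `mask`, both of length `pad_size`.
#' @export
encode_sequence <- function(tokens, vocab, pad_size) {
  if (pad_size < 1) stop_config("pad_size must be >= 1")
  kept <- if (length(tokens) > pad_size) {
    tokens[(length(tokens) - pad_size + 1L):length(tokens)]
  } else tokens
  ids <- integer(pad_size)
  mask <- integer(pad_size)
  n <- length(kept)
  if (n) {
    ids[seq_len(n)] <- encode_tokens(kept, vocab)
    mask[seq_len(n)] <- 1L
  }
  list(ids = ids, mask = mask)
}

#' Decode an id sequence back to tokens
#'
#' PAD positions are dropped; UNK ids decode to `"UNK"`.
#'
#' @param ids integer id vector.
#' @param vocab the vocabulary used to encode.
#' @return character vector.
#' @export
decode_sequence <- function(ids, vocab) {
  ids <- ids[ids != PAD_ID]
  out <- character(length(ids))
  out[ids == UNK_ID] <- "UNK"
  known <- ids > UNK_ID
  out[known] <- vocab$tokens[ids[known] - 1L]
  out
}

#' Write a vocabulary to JSON
#' @param vocab a `wardflow_vocab`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_vocab <- function(vocab, path) {
  jsonlite::write_json(list(domain = vocab$domain, min_freq = vocab$min_freq,
                            tokens = vocab$tokens, freqs = vocab$freqs),
                       path, auto_unbox = TRUE)
  invisible(path)
}

#' Read a vocabulary from JSON
#' @param path file written by [write_vocab()].
#' @return a `wardflow_vocab`.
#' @export
read_vocab <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  v <- build_vocab(rep(x$tokens, x$freqs), min_freq = x$min_freq,
                   domain = x$domain)
  v
}

#' Fit all tokenizer artifacts on the training split
#'
#' Restricts every stream to records of training-split patients (labs and
#' notes additionally to records inside training admissions' observation
#' windows), then fits lab bins and builds the three vocabularies. Test and
#' validation rows never influence the result.
#'
#' @param ehr a `wardflow_ehr`.
#' @param cohort a [build_cohort()] result.
#' @param min_freq named list of per-domain minimum frequencies.
#' @param q lab quantile bins.
#' @param icd_level diagnosis roll-up level.
#' @param lexicons note-cleaning lexicons.
#' @return list with `vocabs` (diag/lab/note), `binning`, `icd_level`,
#'   `lexicons`.
#' @export
fit_tokenizer <- function(ehr, cohort,
                          min_freq = list(diag = 2L, lab = 2L, note = 2L),
                          q = 10, icd_level = 3,
                          lexicons = default_note_lexicons()) {
  train_pat <- cohort$splits[cohort$splits$split == "train", ]$patient_id
  dx <- ehr$diagnoses[ehr$diagnoses$patient_id %in% train_pat, ]
  lb <- ehr$labs[ehr$labs$patient_id %in% train_pat, ]
  nt <- ehr$notes[ehr$notes$patient_id %in% train_pat, ]
  binning <- fit_lab_bins(lb, q = q)
  diag_vocab <- build_vocab(rollup_icd(dx$code, icd_level),
                            min_freq$diag, "diag")
  lab_vocab <- build_vocab(lab_token(lb, binning), min_freq$lab, "lab")
  note_tokens <- unlist(preprocess_notes(nt$text, lexicons), use.names = FALSE)
  note_vocab <- build_vocab(note_tokens, min_freq$note, "note")
  list(vocabs = list(diag = diag_vocab, lab = lab_vocab, note = note_vocab),
       binning = binning, icd_level = icd_level, lexicons = lexicons)
}
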
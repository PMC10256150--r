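# Shared fixtures, built once per test run and memoised in an environment.
# All fixtures are generated in code; nothing is stored on disk.

.fixture_env <- new.env(parent = emptyenv())

memo <- function(name, build) {
  if (!exists(name, envir = .fixture_env)) {
    assign(name, build(), envir = .fixture_env)
  }
  get(name, envir = .fixture_env)
}

# A strong-signal synthetic world at desk scale with a trained small GRU:
# used by the training, calibration, evaluation and attribution tests.
fixture_world <- function() {
  memo("world", function() {
    cfg <- synth_config_strong(n_patients = 2500, seed = 101)
    ehr <- generate_ehr(cfg)
    cohort <- build_cohort(ehr, seed = 7)
    tokenizer <- fit_tokenizer(ehr, cohort)
    samples <- build_samples(ehr, cohort, tokenizer, delta_hours = 12,
                             window_hours = 24)
    spec <- model_spec_for(samples, tokenizer, hidden = 8, cell = "GRU")
    model <- train_model(samples, spec, epochs = 4, batch_size = 256,
                         lr = 3e-3, seed = 5)
    list(cfg = cfg, ehr = ehr, cohort = cohort, tokenizer = tokenizer,
         samples = samples, spec = spec, model = model)
  })
}

# heavier attribution runs shared by the module and acceptance tests
fixture_attr_complete <- function() {
  memo("attr_complete", function() {
    w <- fixture_world()
    set.seed(5)
    idx <- sample(which(w$samples$meta$split == "test"), 48)
    bl <- sample(which(w$samples$meta$split == "validation"), 64)
    gs <- gradient_shap(w$model, w$samples, idx, bl, w$tokenizer$vocabs,
                        n_draws = 256, seed = 6)
    list(gs = gs, sid = w$samples$meta$sample_id[idx])
  })
}

fixture_attr_signs <- function() {
  memo("attr_signs", function() {
    w <- fixture_world()
    set.seed(7)
    idx <- sample(which(w$samples$meta$split == "test"), 600)
    bl <- sample(which(w$samples$meta$split == "validation"), 64)
    gs <- gradient_shap(w$model, w$samples, idx, bl, w$tokenizer$vocabs,
                        n_draws = 32, seed = 8)
    aggregate_attributions(gs)
  })
}

# A single-admission micro world with hand-placed records, for exact
# sequence-cutoff and leakage checks. The admission spans [0, 100h).
micro_ehr <- function(lab_times_h = c(5, 13, 40), note_times_h = c(2, 30),
                      extra_lab_h = NULL) {
  H <- 60L
  lab_t <- as.integer(c(lab_times_h, extra_lab_h) * H)
  labs <- data.table::data.table(
    patient_id = 1L, time = lab_t,
    component = "HEMOGLOBIN", specimen = "B", unit = "mmol/L",
    value = round(6 + lab_t / 600, 2))  # value is a function of time only
  notes <- data.table::data.table(
    patient_id = 1L, time = as.integer(note_times_h * H),
    text = rep("patient stable ward", length(note_times_h)))
  list(
    patients = data.table::data.table(patient_id = 1L, sex = "M",
                                      birth_time = -40L * 525960L,
                                      disconnected = FALSE),
    visits = data.table::data.table(visit_id = 1L, patient_id = 1L,
                                    start = 0L, end = 100L * H,
                                    ward = "ward", patient_type = "inpatient",
                                    acuity = "planned"),
    diagnoses = data.table::data.table(patient_id = 1L,
                                       time = c(-100000L, -50000L),
                                       code = c("C341M", "I109")),
    labs = labs, notes = notes,
    deaths = data.table::data.table(patient_id = integer(),
                                    death_time = integer()))
}

micro_world <- function(...) {
  ehr <- micro_ehr(...)
  stitched <- stitch_admissions(ehr$visits)
  elig <- apply_exclusions(stitched, ehr$patients)
  adm <- detect_outcome(elig, ehr$visits[ehr$visits$ward == "ICU", ],
                        ehr$deaths)
  adm$split <- "train"
  cohort <- list(admissions = adm, segments = elig$segments,
                 attrition = elig$attrition,
                 splits = data.table::data.table(patient_id = 1L,
                                                 split = "train"))
  tokenizer <- fit_tokenizer(ehr, cohort,
                             min_freq = list(diag = 1L, lab = 1L, note = 1L))
  list(ehr = ehr, cohort = cohort, tokenizer = tokenizer)
}

# tiny random batch for the network tests
tiny_spec <- function(cell = "GRU") {
  ensemble_spec(vocab_sizes = list(a = 7L, b = 5L),
                pad_sizes = list(a = 4L, b = 3L),
                n_static = 2L, hidden = 3L, alpha = 0.5, cell = cell)
}

tiny_batch <- function(spec, B = 5L, seed = 2) {
  withr_seed <- seed
  set.seed(withr_seed)
  doms <- list()
  for (d in names(spec$domains)) {
    sd_ <- spec$domains[[d]]
    ids <- matrix(sample(0:(sd_$V - 1L), B * sd_$pad, TRUE), B, sd_$pad)
    mask <- matrix(0L, B, sd_$pad)
    for (i in seq_len(B)) {
      n <- sample(0:sd_$pad, 1)
      if (n > 0) mask[i, seq_len(n)] <- 1L
    }
    ids[mask == 0L] <- 0L
    doms[[d]] <- list(ids = ids, mask = mask)
  }
  list(domains = doms, static = matrix(rnorm(B * spec$n_static), B))
}

# hand-built separable toy sample set: label-1 samples carry token "A",
# label-0 samples token "B"; one domain, no static signal
toy_samples <- function(n = 400, seed = 3) {
  set.seed(seed)
  vocab <- build_vocab(c(rep("A", 10), rep("B", 10)), min_freq = 1,
                       domain = "toy")
  label <- rep(0:1, length.out = n)
  ids <- matrix(0L, n, 3L)
  mask <- matrix(0L, n, 3L)
  for (i in seq_len(n)) {
    tok <- if (label[i] == 1L) "A" else "B"
    enc <- encode_sequence(rep(tok, sample(1:3, 1)), vocab, 3L)
    ids[i, ] <- enc$ids
    mask[i, ] <- enc$mask
  }
  pid <- seq_len(n)  # one patient per sample
  split <- ifelse(pid %% 5 == 0, "validation", "train")
  meta <- data.table::data.table(sample_id = seq_len(n), admission_id = pid,
                                 patient_id = pid, t = 0, label = label,
                                 outcome = "x", split = split, sex = "F",
                                 age = 50, n_prior = 0)
  structure(list(meta = meta,
                 domains = list(toy = list(ids = ids, mask = mask)),
                 static = matrix(0, n, 1,
                                 dimnames = list(NULL, "age")),
                 static_stats = NULL, delta_hours = 12, window_hours = 24,
                 pad_sizes = list(toy = 3L)),
            class = "wardflow_samples")
}

toy_tokenizer <- function() {
  vocab <- build_vocab(c(rep("A", 10), rep("B", 10)), min_freq = 1,
                       domain = "toy")
  list(vocabs = list(toy = vocab))
}

# independent oracles -------------------------------------------------------

# pairwise-concordance AUROC with ties counted 1/2
brute_auroc <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  (sum(outer(pos, neg, ">")) + 0.5 * sum(outer(pos, neg, "=="))) /
    (length(pos) * length(neg))
}

# average precision computed literally from the sorted ranking
brute_auprc <- function(scores, labels) {
  ord <- order(scores, decreasing = TRUE)
  y <- labels[ord]
  s <- scores[ord]
  ap <- 0
  n1 <- sum(y)
  prev_recall <- 0
  for (th in unique(s)) {
    sel <- s >= th
    tp <- sum(y[sel])
    prec <- tp / sum(sel)
    recall <- tp / n1
    ap <- ap + prec * (recall - prev_recall)
    prev_recall <- recall
  }
  ap
}

# exhaustive monotone least squares over all consecutive-block partitions
brute_isotonic <- function(y, w = rep(1, length(y))) {
  n <- length(y)
  best <- NULL
  best_sse <- Inf
  for (code in 0:(2^(n - 1) - 1)) {
    cuts <- which(bitwAnd(code, 2^(0:(n - 2))) > 0)
    bounds <- c(0, cuts, n)
    fit <- numeric(n)
    for (b in seq_len(length(bounds) - 1)) {
      idx <- (bounds[b] + 1):bounds[b + 1]
      fit[idx] <- sum(w[idx] * y[idx]) / sum(w[idx])
    }
    if (is.unsorted(fit)) next
    sse <- sum(w * (y - fit)^2)
    if (sse < best_sse - 1e-12) {
      best_sse <- sse
      best <- fit
    }
  }
  best
}

# stitching oracle: transitive closure over pairwise gap <= gap_min
brute_stitch_groups <- function(starts, ends, gap_min) {
  n <- length(starts)
  grp <- seq_len(n)
  repeat {
    changed <- FALSE
    for (a in seq_len(n)) for (b in seq_len(n)) {
      if (grp[a] == grp[b]) next
      gap1 <- starts[b] - ends[a]
      gap2 <- starts[a] - ends[b]
      if ((gap1 >= 0 && gap1 <= gap_min) || (gap2 >= 0 && gap2 <= gap_min)) {
        g <- min(grp[a], grp[b])
        grp[grp == grp[a] | grp == grp[b]] <- g
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  grp
}
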
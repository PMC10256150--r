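# End-to-end experiment driver: simulate -> build-cohort -> tokenize ->
# build-samples -> train -> calibrate -> evaluate (-> explain) over the
# assessment-rate x prediction-window grid. Stages are cached on disk keyed
# by a hash of the configuration that feeds them.

#' Default experiment configuration
#'
#' The grid covers assessment rates of 6, 12 and 24 hours and prediction
#' windows of 1, 2, 7 and 14 days. Model and cohort sizes default to desk
#' scale; raise `n_patients`, `hidden` and `epochs` for larger experiments.
#'
#' @param n_patients synthetic cohort size.
#' @param seed master seed; per-stage seeds derive from it.
#' @return nested configuration list.
#' @export
default_experiment_config <- function(n_patients = 4000L, seed = 1L) {
  list(
    seed = as.integer(seed),
    synth = list(n_patients = as.integer(n_patients)),
    cohort = list(gap_hours = 24, fractions = c(0.64, 0.16, 0.20)),
    tokenize = list(min_freq = list(diag = 2L, lab = 2L, note = 2L),
                    q = 10, icd_level = 3),
    sampler = list(rates = c(6, 12, 24), windows_days = c(1, 2, 7, 14),
                   pad_sizes = list(diag = 9L, lab = 28L, note = 48L),
                   include_doorstep = TRUE),
    model = list(hidden = 8L, alpha = 1, cell = "GRU"),
    training = list(epochs = 4L, batch_size = 256L, lr = 3e-3, patience = 3L),
    evaluation = list(B = 200L)
  )
}

#' Read / validate an experiment configuration from YAML
#' @param path YAML file.
#' @return configuration list merged over the defaults.
#' @export
read_experiment_config <- function(path) {
  user <- yaml::read_yaml(path)
  cfg <- utils::modifyList(default_experiment_config(), user)
  if (is.null(cfg$synth$n_patients)) {
    stop_config("config must set synth$n_patients")
  }
  cfg
}

.cfg_hash <- function(x) {
  f <- tempfile()
  on.exit(unlink(f))
  writeLines(jsonlite::toJSON(x, auto_unbox = TRUE, digits = 12,
                              force = TRUE), f)
  unname(tools::md5sum(f))
}

.stage_cache <- function(out_dir, name, key, build, cache = TRUE,
                         log = NULL) {
  path <- file.path(out_dir, "cache", paste0(name, "-", key, ".rds"))
  if (cache && file.exists(path)) {
    if (!is.null(log)) log(sprintf("stage %-14s cache hit", name))
    return(list(value = readRDS(path), hit = TRUE))
  }
  t0 <- Sys.time()
  value <- build()
  if (cache) {
    dir.create(dirname(path), showWarnings = FALSE, recursive = TRUE)
    saveRDS(value, path)
  }
  if (!is.null(log)) {
    log(sprintf("stage %-14s ran in %.1fs", name,
                as.numeric(Sys.time() - t0, units = "secs")))
  }
  list(value = value, hit = FALSE)
}

#' Run one (assessment rate, prediction window) cell
#'
#' Trains on the training split, fits isotonic calibration on the validation
#' split, and evaluates the recalibrated risks on the untouched test split.
#'
#' @param samples a `wardflow_samples` already labelled for the window.
#' @param tokenizer matching [fit_tokenizer()] result.
#' @param model_cfg list with `hidden`, `alpha`, `cell`.
#' @param train_cfg list with `epochs`, `batch_size`, `lr`, `patience`.
#' @param B bootstrap resamples for the report.
#' @param seed integer seed.
#' @return list with `model`, `calibration`, `report` (one-row table),
#'   `thresholds` (precision/recall/specificity at the standard risk
#'   thresholds), `scores` and `test_idx`.
#' @export
run_cell <- function(samples, tokenizer, model_cfg, train_cfg, B = 200L,
                     seed = 1L) {
  spec <- model_spec_for(samples, tokenizer, hidden = model_cfg$hidden,
                         alpha = model_cfg$alpha, cell = model_cfg$cell)
  model <- train_model(samples, spec, epochs = train_cfg$epochs,
                       batch_size = train_cfg$batch_size, lr = train_cfg$lr,
                       patience = train_cfg$patience %||% 5L, seed = seed)
  idx_va <- which(samples$meta$split == "validation")
  idx_te <- which(samples$meta$split == "test")
  p_va <- predict_risk(model, samples, idx_va)
  calib <- fit_isotonic(p_va, samples$meta$label[idx_va])
  p_te <- predict_risk(model, samples, idx_te, calibration = calib)
  report <- evaluate_scores(p_te, samples$meta$label[idx_te], B = B,
                            seed = seed)
  thresholds <- threshold_metrics(p_te, samples$meta$label[idx_te])
  list(model = model, calibration = calib, report = report,
       thresholds = thresholds, scores = p_te, test_idx = idx_te)
}

#' Run the full experiment grid
#'
#' Executes every pipeline stage for each (rate, window) combination,
#' reusing the simulated data, cohort and tokenizer across cells and the
#' encoded sequences across windows of the same rate. Artifacts and a
#' per-stage cache are written under `out_dir`; rerunning with an unchanged
#' configuration hits the cache everywhere.
#'
#' @param config configuration list, see [default_experiment_config()].
#' @param out_dir artifact directory.
#' @param cache reuse cached stage results (default TRUE).
#' @param verbose print stage progress.
#' @return `data.table` report with one row per grid cell (AUROC, AUPRC,
#'   calibration slope and intercept, each with 95% bootstrap intervals),
#'   also written to `report.csv` / `report.json` in `out_dir`.
#' @export
run_pipeline <- function(config = default_experiment_config(),
                         out_dir = file.path(tempdir(), "wardflow-run"),
                         cache = TRUE, verbose = TRUE) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  log_file <- file.path(out_dir, "pipeline.log")
  log <- function(msg) {
    line <- sprintf("[%s] %s", format(Sys.time(), "%H:%M:%S"), msg)
    cat(line, "\n", file = log_file, append = TRUE)
    if (verbose) message(line)
  }
  seed <- config$seed
  log(sprintf("run_pipeline seed=%d", seed))

  scfg <- do.call(synth_config,
                  c(config$synth, list(seed = seed)))
  sim <- .stage_cache(out_dir, "simulate", .cfg_hash(config$synth[
    names(config$synth) != "risk_token_pools"])[1],
    function() generate_ehr(scfg), cache, log)
  ehr <- sim$value

  key_cohort <- .cfg_hash(list(synth = config$synth, cohort = config$cohort,
                               seed = seed))
  coh <- .stage_cache(out_dir, "cohort", key_cohort, function()
    build_cohort(ehr, gap_hours = config$cohort$gap_hours,
                 fractions = config$cohort$fractions, seed = seed + 1L),
    cache, log)
  cohort <- coh$value

  key_tok <- .cfg_hash(list(k = key_cohort, tokenize = config$tokenize))
  tok <- .stage_cache(out_dir, "tokenize", key_tok, function()
    do.call(fit_tokenizer, c(list(ehr = ehr, cohort = cohort),
                             config$tokenize)), cache, log)
  tokenizer <- tok$value

  rows <- list()
  for (rate in config$sampler$rates) {
    key_sm <- .cfg_hash(list(k = key_tok, rate = rate,
                             pad = config$sampler$pad_sizes,
                             doorstep = config$sampler$include_doorstep))
    sm <- .stage_cache(out_dir, sprintf("samples-r%g", rate), key_sm,
                       function()
      build_samples(ehr, cohort, tokenizer, delta_hours = rate,
                    window_hours = 24,
                    pad_sizes = config$sampler$pad_sizes,
                    include_doorstep = config$sampler$include_doorstep),
      cache, log)
    for (wd in config$sampler$windows_days) {
      w_h <- wd * 24
      samples <- relabel_samples(sm$value, cohort, w_h)
      key_cell <- .cfg_hash(list(k = key_sm, w = w_h, model = config$model,
                                 training = config$training,
                                 B = config$evaluation$B, seed = seed))
      cell <- .stage_cache(out_dir, sprintf("cell-r%g-w%gd", rate, wd),
                           key_cell, function()
        run_cell(samples, tokenizer, config$model, config$training,
                 B = config$evaluation$B, seed = seed + 17L),
        cache, log)
      rows[[length(rows) + 1L]] <- cbind(
        data.table::data.table(rate_hours = rate, window_days = wd),
        cell$value$report)
    }
  }
  report <- data.table::rbindlist(rows)
  data.table::fwrite(report, file.path(out_dir, "report.csv"))
  jsonlite::write_json(report, file.path(out_dir, "report.json"),
                       digits = NA)
  data.table::fwrite(cohort$attrition, file.path(out_dir, "attrition.csv"))
  log("pipeline complete")
  report
}
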
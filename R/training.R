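# Model fitting: mini-batch Adam on binary cross-entropy, best-epoch
# selection on validation loss, validation AUPRC as the model-selection
# metric, and a pluggable (random-default) hyperparameter search.

.make_batch <- function(samples, idx) {
  list(domains = lapply(samples$domains, function(d)
    list(ids = d$ids[idx, , drop = FALSE],
         mask = d$mask[idx, , drop = FALSE])),
    static = samples$static[idx, , drop = FALSE])
}

#' Ensemble specification matching a sample set
#'
#' @param samples a `wardflow_samples`.
#' @param tokenizer the [fit_tokenizer()] result the samples were encoded
#'   with (provides vocabulary sizes).
#' @param hidden,alpha,cell,att_dim,emb_exponent see [ensemble_spec()].
#' @return an `ensemble_spec`.
#' @export
model_spec_for <- function(samples, tokenizer, hidden = 8L, alpha = 1,
                           cell = "GRU", att_dim = NULL, emb_exponent = 0.25) {
  vs <- lapply(tokenizer$vocabs, vocab_size)
  ensemble_spec(vocab_sizes = vs[names(samples$domains)],
                pad_sizes = samples$pad_sizes,
                n_static = ncol(samples$static),
                hidden = hidden, alpha = alpha, cell = cell,
                att_dim = att_dim, emb_exponent = emb_exponent)
}

.predict_params <- function(params, spec, samples, idx = NULL,
                            chunk = 2048L) {
  if (is.null(idx)) idx <- seq_len(n_samples(samples))
  out <- numeric(length(idx))
  for (s in seq(1L, length(idx), by = chunk)) {
    e <- min(s + chunk - 1L, length(idx))
    batch <- .make_batch(samples, idx[s:e])
    out[s:e] <- ensemble_forward(params, spec, batch)$prob
  }
  out
}

#' Train the recurrent ensemble
#'
#' Minimizes mean binary cross-entropy with Adam; checkpoints every epoch and
#' returns the parameters of the epoch with the lowest validation loss
#' (first minimum on ties). Training and validation samples must belong to
#' disjoint patient sets. Deterministic given `seed` (single-threaded BLAS).
#'
#' @param samples a `wardflow_samples` whose `meta$split` contains `train`
#'   and `validation`.
#' @param spec an [ensemble_spec()] (e.g. from [model_spec_for()]).
#' @param epochs maximum epochs.
#' @param batch_size mini-batch size.
#' @param lr Adam learning rate.
#' @param patience early-stopping patience in epochs without validation-loss
#'   improvement.
#' @param seed integer seed controlling initialization and batch order.
#' @param verbose print per-epoch progress.
#' @return a `wardflow_model`: list with `params` (best epoch), `spec`,
#'   `history` (per-epoch train loss, validation loss, validation AUPRC),
#'   `best_epoch`, `seed`.
#' @export
train_model <- function(samples, spec, epochs = 10L, batch_size = 256L,
                        lr = 1e-3, patience = 5L, seed = 1L,
                        verbose = FALSE) {
  meta <- samples$meta
  idx_tr <- which(meta$split == "train")
  idx_va <- which(meta$split == "validation")
  if (!length(idx_tr) || !length(idx_va)) {
    stop_data("samples must contain both train and validation splits")
  }
  common <- intersect(unique(meta$patient_id[idx_tr]),
                      unique(meta$patient_id[idx_va]))
  if (length(common)) {
    stop_data("train and validation share %d patient(s); patient-level %s",
              length(common), "disjointness is required")
  }
  y_tr <- meta$label[idx_tr]
  y_va <- meta$label[idx_va]
  if (sum(y_tr) == 0L) {
    stop_data("no positive labels in the training set; regenerate with a %s",
              "larger cohort or stronger signal")
  }
  with_seed(seed, {
    params <- init_ensemble(spec, seed = stats::runif(1, 1, 1e6))
    state <- adam_init(params)
    history <- data.table::data.table(epoch = integer(), train_loss = numeric(),
                                      val_loss = numeric(),
                                      val_auprc = numeric())
    best <- list(loss = Inf, params = params, epoch = 0L)
    for (ep in seq_len(epochs)) {
      perm <- sample(idx_tr)
      tot_loss <- 0
      nb <- 0L
      for (s in seq(1L, length(perm), by = batch_size)) {
        e <- min(s + batch_size - 1L, length(perm))
        bidx <- perm[s:e]
        batch <- .make_batch(samples, bidx)
        y <- meta$label[bidx]
        out <- ensemble_forward(params, spec, batch, keep_cache = TRUE)
        loss <- bce_loss(out$prob, y)
        bk <- ensemble_backward(params, spec, out,
                                (out$prob - y) / length(y))
        upd <- adam_step(params, bk$grads, state, lr = lr)
        params <- upd$params
        state <- upd$state
        tot_loss <- tot_loss + loss * length(y)
        nb <- nb + length(y)
      }
      p_va <- .predict_params(params, spec, samples, idx_va)
      val_loss <- bce_loss(p_va, y_va)
      val_auprc <- if (sum(y_va) > 0) auprc(p_va, y_va) else NA_real_
      history <- rbind(history,
                       data.table::data.table(epoch = ep,
                                              train_loss = tot_loss / nb,
                                              val_loss = val_loss,
                                              val_auprc = val_auprc))
      if (verbose) {
        message(sprintf("epoch %d: train %.5f val %.5f auprc %.4f", ep,
                        tot_loss / nb, val_loss, val_auprc))
      }
      if (val_loss < best$loss) {
        best <- list(loss = val_loss, params = params, epoch = ep)
      } else if (ep - best$epoch >= patience) {
        break
      }
    }
    structure(list(params = best$params, spec = spec, history = history,
                   best_epoch = best$epoch, seed = seed,
                   batch_size = batch_size, lr = lr),
              class = "wardflow_model")
  })
}

#' @export
print.wardflow_model <- function(x, ...) {
  cat(sprintf("<wardflow_model %s; %d epoch(s), best epoch %d (val loss %.5f)>\n",
              x$spec$cell, nrow(x$history), x$best_epoch,
              x$history$val_loss[x$best_epoch]))
  invisible(x)
}

#' Best epoch of a training history
#'
#' First index of the minimum validation loss (1-based).
#'
#' @param history a `wardflow_model`, its `history` table, or a numeric
#'   vector of per-epoch validation losses.
#' @return integer epoch index.
#' @export
select_epoch <- function(history) {
  losses <- if (inherits(history, "wardflow_model")) {
    history$history$val_loss
  } else if (is.data.frame(history)) {
    history$val_loss
  } else {
    as.numeric(history)
  }
  if (!length(losses)) stop_data("empty training history")
  which.min(losses)
}

#' Predict deterioration risk for samples
#'
#' @param model a `wardflow_model`.
#' @param samples a `wardflow_samples` encoded against the same vocabularies.
#' @param idx optional sample indices (default all).
#' @param calibration optional [fit_isotonic()] map applied to the raw risks.
#' @return numeric vector of risks in (0,1).
#' @export
predict_risk <- function(model, samples, idx = NULL, calibration = NULL) {
  p <- .predict_params(model$params, model$spec, samples, idx)
  if (!is.null(calibration)) p <- apply_calibration(calibration, p)
  p
}

#' Random hyperparameter search maximizing validation AUPRC
#'
#' Samples `budget` configurations from `space` (each element a vector of
#' candidate values for one of `hidden`, `alpha`, `cell`, `lr`,
#' `batch_size`), trains each and returns the configuration with the best
#' validation AUPRC at its best epoch. The sampling strategy is pluggable
#' via `sampler`: a function `(space, n, seed) -> list of configs`; the
#' default draws uniformly at random.
#'
#' @param samples a `wardflow_samples`.
#' @param tokenizer the matching [fit_tokenizer()] result.
#' @param space named list of candidate vectors.
#' @param budget number of configurations to evaluate (>= 1).
#' @param epochs training epochs per trial.
#' @param seed integer seed.
#' @param sampler optional sampling function.
#' @return list with `best` (config), `best_auprc` and `trials`
#'   (a `data.table` ledger of every evaluated configuration).
#' @export
search_hyperparameters <- function(samples, tokenizer, space, budget,
                                   epochs = 3L, seed = 1L, sampler = NULL) {
  if (budget < 1) stop_config("search budget must be >= 1")
  if (!length(space)) stop_config("empty search space")
  sampler <- sampler %||% function(space, n, seed) {
    with_seed(seed, lapply(seq_len(n), function(i)
      lapply(space, function(v) v[[sample.int(length(v), 1L)]])))
  }
  configs <- sampler(space, budget, seed)
  trials <- list()
  best <- NULL
  best_auprc <- -Inf
  for (i in seq_along(configs)) {
    cf <- configs[[i]]
    spec <- model_spec_for(samples, tokenizer,
                           hidden = cf$hidden %||% 8L,
                           alpha = cf$alpha %||% 1,
                           cell = cf$cell %||% "GRU")
    fit <- train_model(samples, spec, epochs = epochs,
                       batch_size = cf$batch_size %||% 256L,
                       lr = cf$lr %||% 1e-3, seed = seed + i)
    au <- fit$history$val_auprc[fit$best_epoch]
    trials[[i]] <- data.table::data.table(
      trial = i, config = jsonlite::toJSON(cf, auto_unbox = TRUE),
      val_auprc = au, best_epoch = fit$best_epoch)
    if (is.finite(au) && au > best_auprc) {
      best_auprc <- au
      best <- cf
    }
  }
  list(best = best, best_auprc = best_auprc,
       trials = data.table::rbindlist(trials))
}

#' Save / load a fitted model
#'
#' Checkpoints are RDS files holding parameters, spec and history.
#'
#' @param model a `wardflow_model`.
#' @param path file path.
#' @return `path` (save) or the model (load).
#' @export
save_model <- function(model, path) {
  saveRDS(model, path)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) readRDS(path)
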
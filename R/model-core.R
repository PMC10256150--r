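# The ensemble network: one submodel per data domain (entity embedding ->
# recurrent layer (GRU or LSTM) -> additive attention pooling), pooled
# outputs concatenated with the static features and mapped to a risk in
# (0,1) by a linear layer with logistic activation. Forward and backward
# passes are written directly in matrix code; gradients are verified against
# finite differences in the test suite.
#
# Conventions: token ids are 0-based with PAD=0/UNK=1 (embedding row =
# id + 1); per-domain inputs are (batch x pad) integer matrices; masked
# positions never influence the output (embeddings are zeroed, the recurrent
# state carries through, and attention assigns them exactly zero weight).

#' Embedding dimension from vocabulary size
#'
#' `round(6 * alpha * V^exponent)`, at least 1, with the fourth root as the
#' default exponent — the entity-embedding sizing rule for categorical EHR
#' vocabularies. `alpha` is the tunable embedding coefficient.
#'
#' @param V vocabulary size (>= 1).
#' @param alpha positive embedding coefficient.
#' @param exponent exponent on `V` (default 1/4).
#' @return integer embedding dimension.
#' @export
embedding_size <- function(V, alpha = 1, exponent = 0.25) {
  if (any(V < 1)) stop_config("vocabulary size must be >= 1")
  if (alpha <= 0) stop_config("embedding coefficient alpha must be positive")
  pmax(1L, as.integer(round(6 * alpha * V^exponent)))
}

#' Additive attention pooling over one sequence
#'
#' Scores `e_t = v . tanh(W h_t + b)`, weights by softmax over the unmasked
#' positions (masked positions get weight exactly 0), and pools
#' `sum_t a_t h_t`.
#'
#' @param H numeric `T x d` matrix of per-position hidden states.
#' @param mask 0/1 vector of length `T`; at least one position unmasked.
#' @param W `d x k` score matrix, `b` length-`k` bias, `v` length-`k` score
#'   vector.
#' @return list with `pooled` (length `d`) and `weights` (length `T`,
#'   summing to 1).
#' @export
attention_pool <- function(H, mask, W, b, v) {
  if (!any(mask > 0)) stop("attention_pool: all positions are masked",
                           call. = FALSE)
  A <- tanh(sweep(H %*% W, 2, b, "+"))
  e <- drop(A %*% v)
  e[mask == 0] <- -Inf
  e <- e - max(e)
  a <- exp(e)
  a <- a / sum(a)
  list(pooled = drop(crossprod(H, a)), weights = a)
}

#' Specification of the recurrent ensemble
#'
#' @param vocab_sizes named integer vector/list of per-domain vocabulary
#'   sizes (including PAD and UNK).
#' @param pad_sizes named per-domain sequence lengths.
#' @param n_static number of static features (default 3: age, sex, prior
#'   admissions).
#' @param hidden recurrent hidden units, scalar or named per domain.
#' @param alpha embedding coefficient, scalar or named per domain.
#' @param cell `"GRU"` or `"LSTM"`.
#' @param att_dim attention score dimension (defaults to `hidden`).
#' @param emb_exponent exponent of the embedding-size rule.
#' @return an `ensemble_spec` object.
#' @export
ensemble_spec <- function(vocab_sizes, pad_sizes, n_static = 3L, hidden = 8L,
                          alpha = 1, cell = c("GRU", "LSTM"), att_dim = NULL,
                          emb_exponent = 0.25) {
  cell <- match.arg(cell)
  doms <- names(vocab_sizes)
  if (is.null(doms)) stop_config("vocab_sizes must be named by domain")
  get1 <- function(x, d, default = NULL) {
    if (length(x) > 1L || !is.null(names(x))) x[[d]] else x
  }
  domains <- lapply(doms, function(d) {
    V <- as.integer(vocab_sizes[[d]])
    if (V < 2L) stop_config("domain '%s': vocabulary must include PAD and UNK", d)
    H <- as.integer(get1(hidden, d))
    a <- get1(alpha, d)
    list(domain = d, V = V, pad = as.integer(get1(pad_sizes, d)),
         m = embedding_size(V, a, emb_exponent), H = H, alpha = a,
         A = as.integer(get1(att_dim, d) %||% H), cell = cell)
  })
  names(domains) <- doms
  structure(list(domains = domains, n_static = as.integer(n_static),
                 cell = cell),
            class = "ensemble_spec")
}

.runif_mat <- function(nr, nc, k) matrix(stats::runif(nr * nc, -k, k), nr, nc)

#' Initialize ensemble parameters
#'
#' Uniform initialization scaled by `1/sqrt(hidden)` for recurrent weights;
#' the PAD embedding row starts at zero.
#'
#' @param spec an [ensemble_spec()].
#' @param seed integer seed.
#' @return nested parameter list.
#' @export
init_ensemble <- function(spec, seed = 1L) {
  with_seed(seed, {
    params <- list(domains = list())
    total_H <- 0L
    for (d in names(spec$domains)) {
      sd_ <- spec$domains[[d]]
      k <- 1 / sqrt(sd_$H)
      E <- matrix(stats::rnorm(sd_$V * sd_$m, 0, 0.1), sd_$V, sd_$m)
      E[1L, ] <- 0  # PAD row
      gates <- if (sd_$cell == "GRU") 3L else 4L
      p <- list(
        E = E,
        W = .runif_mat(sd_$m, gates * sd_$H, k),
        U = .runif_mat(sd_$H, gates * sd_$H, k),
        b = numeric(gates * sd_$H),
        Wa = .runif_mat(sd_$H, sd_$A, k),
        ba = numeric(sd_$A),
        va = stats::runif(sd_$A, -k, k)
      )
      if (sd_$cell == "LSTM") {
        p$b[sd_$H + seq_len(sd_$H)] <- 1  # forget-gate bias
      }
      params$domains[[d]] <- p
      total_H <- total_H + sd_$H
    }
    params$head <- list(
      w = stats::runif(total_H + spec$n_static, -0.1, 0.1),
      b = 0
    )
    params
  })
}

.sigmoid <- function(x) 1 / (1 + exp(-x))

# effective mask: all-PAD sequences get position 1 unmasked so pooling is
# defined (doorstep samples); the input embedding there is still zeroed.
.mask_eff <- function(mask) {
  allpad <- rowSums(mask) == 0
  if (any(allpad)) mask[allpad, 1L] <- 1L
  mask
}

.domain_forward <- function(p, sd_, ids, mask, X_in = NULL) {
  B <- nrow(ids); Tn <- ncol(ids); H <- sd_$H; m <- sd_$m
  me <- .mask_eff(mask)
  if (is.null(X_in)) {
    Xcat <- p$E[as.integer(ids) + 1L, , drop = FALSE] *
      as.numeric(as.integer(mask))
  } else {
    Xcat <- X_in * as.numeric(as.integer(mask))
  }
  # Xcat rows: t-major blocks of B (column-major unrolling of B x T)
  PX <- Xcat %*% p$W
  Hs <- vector("list", Tn)
  cache <- list(Z = vector("list", Tn), R = vector("list", Tn),
                Nn = vector("list", Tn), C = vector("list", Tn),
                I = vector("list", Tn), F = vector("list", Tn),
                G = vector("list", Tn), O = vector("list", Tn),
                TC = vector("list", Tn))
  hp <- matrix(0, B, H)
  cp <- matrix(0, B, H)  # LSTM cell state
  i1 <- seq_len(H)
  for (t in seq_len(Tn)) {
    rows <- (t - 1L) * B + seq_len(B)
    mt <- me[, t]
    if (sd_$cell == "GRU") {
      z <- .sigmoid(PX[rows, i1, drop = FALSE] + hp %*% p$U[, i1] +
                      rep(p$b[i1], each = B))
      r <- .sigmoid(PX[rows, H + i1, drop = FALSE] + hp %*% p$U[, H + i1] +
                      rep(p$b[H + i1], each = B))
      n <- tanh(PX[rows, 2L * H + i1, drop = FALSE] +
                  (r * hp) %*% p$U[, 2L * H + i1] + rep(p$b[2L * H + i1],
                                                        each = B))
      hc <- (1 - z) * n + z * hp
      h <- mt * hc + (1 - mt) * hp
      cache$Z[[t]] <- z; cache$R[[t]] <- r; cache$Nn[[t]] <- n
    } else {
      ig <- .sigmoid(PX[rows, i1, drop = FALSE] + hp %*% p$U[, i1] +
                       rep(p$b[i1], each = B))
      fg <- .sigmoid(PX[rows, H + i1, drop = FALSE] + hp %*% p$U[, H + i1] +
                       rep(p$b[H + i1], each = B))
      gg <- tanh(PX[rows, 2L * H + i1, drop = FALSE] +
                   hp %*% p$U[, 2L * H + i1] + rep(p$b[2L * H + i1], each = B))
      og <- .sigmoid(PX[rows, 3L * H + i1, drop = FALSE] +
                       hp %*% p$U[, 3L * H + i1] + rep(p$b[3L * H + i1],
                                                       each = B))
      cc <- fg * cp + ig * gg
      tc <- tanh(cc)
      hcand <- og * tc
      h <- mt * hcand + (1 - mt) * hp
      cnew <- mt * cc + (1 - mt) * cp
      cache$I[[t]] <- ig; cache$F[[t]] <- fg; cache$G[[t]] <- gg
      cache$O[[t]] <- og; cache$C[[t]] <- cnew; cache$TC[[t]] <- tc
      cp <- cnew
    }
    Hs[[t]] <- h
    hp <- h
  }
  Hcat <- do.call(rbind, Hs)
  Aact <- tanh(Hcat %*% p$Wa + rep(p$ba, each = B * Tn))
  e <- matrix(Aact %*% p$va, B, Tn)
  e[me == 0] <- -1e30
  e <- e - apply(e, 1, max)
  a <- exp(e)
  a <- a / rowSums(a)
  pooled <- matrix(0, B, H)
  for (t in seq_len(Tn)) pooled <- pooled + a[, t] * Hs[[t]]
  list(pooled = pooled, Hs = Hs, Hcat = Hcat, Aact = Aact, a = a,
       Xcat = Xcat, ids = ids, mask = mask, me = me, cache = cache,
       B = B, Tn = Tn)
}

#' Forward pass of the ensemble
#'
#' @param params parameters from [init_ensemble()].
#' @param spec the matching [ensemble_spec()].
#' @param batch list with `domains` (per domain: `ids`, `mask` matrices) and
#'   `static` matrix.
#' @param embeddings optional named list of pre-computed embedding inputs
#'   (`(B*T) x m` matrices in position-major blocks), as produced by
#'   [embed_batch()]; used by the attribution module.
#' @param keep_cache keep intermediate activations for a backward pass.
#' @return list with `prob`, `logit` and (if requested) `cache`.
#' @export
ensemble_forward <- function(params, spec, batch, embeddings = NULL,
                             keep_cache = FALSE) {
  doms <- names(spec$domains)
  fwd <- list()
  pooled_list <- list()
  for (d in doms) {
    fd <- .domain_forward(params$domains[[d]], spec$domains[[d]],
                          batch$domains[[d]]$ids, batch$domains[[d]]$mask,
                          X_in = embeddings[[d]])
    fwd[[d]] <- fd
    pooled_list[[d]] <- fd$pooled
  }
  concat <- do.call(cbind, c(pooled_list, list(batch$static)))
  logit <- drop(concat %*% params$head$w) + params$head$b
  out <- list(prob = .sigmoid(logit), logit = logit)
  if (keep_cache) out$cache <- list(fwd = fwd, concat = concat, batch = batch)
  out
}

.domain_backward <- function(p, sd_, fd, dpooled) {
  B <- fd$B; Tn <- fd$Tn; H <- sd_$H
  a <- fd$a; Hs <- fd$Hs
  # attention backward
  da <- matrix(0, B, Tn)
  dH <- vector("list", Tn)
  for (t in seq_len(Tn)) {
    da[, t] <- rowSums(dpooled * Hs[[t]])
    dH[[t]] <- a[, t] * dpooled
  }
  de <- a * (da - rowSums(a * da))
  decat <- as.numeric(de)
  dA <- outer(decat, p$va)
  dva <- colSums(fd$Aact * decat)
  dpreA <- dA * (1 - fd$Aact^2)
  dWa <- crossprod(fd$Hcat, dpreA)
  dba <- colSums(dpreA)
  dH_att <- dpreA %*% t(p$Wa)
  for (t in seq_len(Tn)) {
    dH[[t]] <- dH[[t]] + dH_att[(t - 1L) * B + seq_len(B), , drop = FALSE]
  }
  # recurrent backward through time
  i1 <- seq_len(H)
  gates <- if (sd_$cell == "GRU") 3L else 4L
  dPre <- matrix(0, B * Tn, gates * H)
  dU <- matrix(0, H, gates * H)
  dh_next <- matrix(0, B, H)
  dc_next <- matrix(0, B, H)
  cch <- fd$cache
  for (t in rev(seq_len(Tn))) {
    rows <- (t - 1L) * B + seq_len(B)
    mt <- fd$me[, t]
    hp <- if (t > 1L) Hs[[t - 1L]] else matrix(0, B, H)
    dh <- dH[[t]] + dh_next
    if (sd_$cell == "GRU") {
      z <- cch$Z[[t]]; r <- cch$R[[t]]; n <- cch$Nn[[t]]
      dhc <- mt * dh
      dhp <- (1 - mt) * dh
      dz <- dhc * (hp - n)
      dn <- dhc * (1 - z)
      dhp <- dhp + dhc * z
      dn_pre <- dn * (1 - n^2)
      drh <- dn_pre %*% t(p$U[, 2L * H + i1])
      dr <- drh * hp
      dhp <- dhp + drh * r
      dz_pre <- dz * z * (1 - z)
      dr_pre <- dr * r * (1 - r)
      dhp <- dhp + dz_pre %*% t(p$U[, i1]) + dr_pre %*% t(p$U[, H + i1])
      dPre[rows, i1] <- dz_pre
      dPre[rows, H + i1] <- dr_pre
      dPre[rows, 2L * H + i1] <- dn_pre
      dU[, i1] <- dU[, i1] + crossprod(hp, dz_pre)
      dU[, H + i1] <- dU[, H + i1] + crossprod(hp, dr_pre)
      dU[, 2L * H + i1] <- dU[, 2L * H + i1] + crossprod(r * hp, dn_pre)
      dh_next <- dhp
    } else {
      ig <- cch$I[[t]]; fg <- cch$F[[t]]; gg <- cch$G[[t]]; og <- cch$O[[t]]
      tc <- cch$TC[[t]]
      cp <- if (t > 1L) cch$C[[t - 1L]] else matrix(0, B, H)
      cc_pre <- fg * cp + ig * gg  # pre-mask cell state
      dhcand <- mt * dh
      dhp <- (1 - mt) * dh
      dc <- mt * dc_next + dhcand * og * (1 - tc^2)
      dcp <- (1 - mt) * dc_next + dc * fg
      do_ <- dhcand * tc
      di <- dc * gg
      df <- dc * cp
      dg <- dc * ig
      di_pre <- di * ig * (1 - ig)
      df_pre <- df * fg * (1 - fg)
      dg_pre <- dg * (1 - gg^2)
      do_pre <- do_ * og * (1 - og)
      dPre[rows, i1] <- di_pre
      dPre[rows, H + i1] <- df_pre
      dPre[rows, 2L * H + i1] <- dg_pre
      dPre[rows, 3L * H + i1] <- do_pre
      dU[, i1] <- dU[, i1] + crossprod(hp, di_pre)
      dU[, H + i1] <- dU[, H + i1] + crossprod(hp, df_pre)
      dU[, 2L * H + i1] <- dU[, 2L * H + i1] + crossprod(hp, dg_pre)
      dU[, 3L * H + i1] <- dU[, 3L * H + i1] + crossprod(hp, do_pre)
      dhp <- dhp + di_pre %*% t(p$U[, i1]) + df_pre %*% t(p$U[, H + i1]) +
        dg_pre %*% t(p$U[, 2L * H + i1]) + do_pre %*% t(p$U[, 3L * H + i1])
      dh_next <- dhp
      dc_next <- dcp
    }
  }
  dW <- crossprod(fd$Xcat, dPre)
  db <- colSums(dPre)
  dXcat <- dPre %*% t(p$W)
  dXcat <- dXcat * as.numeric(as.integer(fd$mask))  # masked inputs: zero grad
  dE <- matrix(0, nrow(p$E), ncol(p$E))
  idx <- as.integer(fd$ids) + 1L
  agg <- rowsum(dXcat, idx)
  dE[as.integer(rownames(agg)), ] <- dE[as.integer(rownames(agg)), ] + agg
  list(grads = list(E = dE, W = dW, U = dU, b = db, Wa = dWa, ba = dba,
                    va = dva),
       dX = dXcat)
}

#' Backward pass: gradients of a scalar objective
#'
#' @param params,spec as in [ensemble_forward()].
#' @param out forward result with `cache` (from
#'   `ensemble_forward(..., keep_cache = TRUE)`).
#' @param dlogit gradient of the objective with respect to each sample's
#'   logit (length B). For mean binary cross-entropy this is
#'   `(prob - label) / B`.
#' @return list with `grads` (same shape as `params`), `dX` (per-domain
#'   gradient w.r.t. embedding inputs, `(B*T) x m`) and `dstatic`.
#' @export
ensemble_backward <- function(params, spec, out, dlogit) {
  cache <- out$cache
  doms <- names(spec$domains)
  dconcat <- outer(dlogit, params$head$w)
  grads <- list(domains = list(),
                head = list(w = drop(crossprod(cache$concat, dlogit)),
                            b = sum(dlogit)))
  dX <- list()
  off <- 0L
  for (d in doms) {
    H <- spec$domains[[d]]$H
    dpooled <- dconcat[, off + seq_len(H), drop = FALSE]
    off <- off + H
    bk <- .domain_backward(params$domains[[d]], spec$domains[[d]],
                           cache$fwd[[d]], dpooled)
    grads$domains[[d]] <- bk$grads
    dX[[d]] <- bk$dX
  }
  dstatic <- dconcat[, off + seq_len(spec$n_static), drop = FALSE]
  list(grads = grads, dX = dX, dstatic = dstatic)
}

#' Embedding inputs of a batch
#'
#' Looks up (and mask-zeroes) the embedding vectors of every position, in the
#' `(B*T) x m` position-major layout used by [ensemble_forward()]'s
#' `embeddings` argument.
#'
#' @param params,spec,batch as in [ensemble_forward()].
#' @return named list of embedding matrices.
#' @export
embed_batch <- function(params, spec, batch) {
  out <- list()
  for (d in names(spec$domains)) {
    ids <- batch$domains[[d]]$ids
    mask <- batch$domains[[d]]$mask
    out[[d]] <- params$domains[[d]]$E[as.integer(ids) + 1L, , drop = FALSE] *
      as.numeric(as.integer(mask))
  }
  out
}

# ---- structure-walking helpers (used by the optimizer) ----

nn_map <- function(f, x) {
  if (is.list(x)) lapply(x, function(xi) nn_map(f, xi)) else f(x)
}

nn_map2 <- function(f, x, y) {
  if (is.list(x)) {
    out <- vector("list", length(x))
    names(out) <- names(x)
    for (i in seq_along(x)) out[[i]] <- nn_map2(f, x[[i]], y[[i]])
    out
  } else f(x, y)
}

#' Adam optimizer state
#' @param params parameter list.
#' @return optimizer state.
#' @export
adam_init <- function(params) {
  list(m = nn_map(function(p) p * 0, params),
       v = nn_map(function(p) p * 0, params),
       t = 0L)
}

#' One Adam update
#' @param params,grads parameter and gradient lists of identical shape.
#' @param state state from [adam_init()].
#' @param lr learning rate.
#' @param beta1,beta2,eps Adam constants.
#' @return list with updated `params` and `state`.
#' @export
adam_step <- function(params, grads, state, lr = 1e-3, beta1 = 0.9,
                      beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  state$m <- nn_map2(function(m, g) beta1 * m + (1 - beta1) * g,
                     state$m, grads)
  state$v <- nn_map2(function(v, g) beta2 * v + (1 - beta2) * g^2,
                     state$v, grads)
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  mh <- nn_map(function(m) m / bc1, state$m)
  vh <- nn_map(function(v) v / bc2, state$v)
  upd <- nn_map2(function(m, v) lr * m / (sqrt(v) + eps), mh, vh)
  params <- nn_map2(`-`, params, upd)
  list(params = params, state = state)
}

#' Mean binary cross-entropy
#' @param prob predicted probabilities.
#' @param label 0/1 labels.
#' @return scalar loss.
#' @export
bce_loss <- function(prob, label) {
  p <- pmin(pmax(prob, 1e-12), 1 - 1e-12)
  -mean(label * log(p) + (1 - label) * log(1 - p))
}
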
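test_that("embedding sizes follow the fourth-root rule", {
  expect_equal(embedding_size(4096, 1), 48L)
  expect_equal(embedding_size(1, 1), 6L)
  # oracle: direct numeric evaluation of 6 * 2583^0.25
  expect_equal(embedding_size(2583, 1), as.integer(round(6 * 2583^0.25)))
  expect_equal(embedding_size(2583, 1), 43L)
  expect_equal(embedding_size(2, 0.01), 1L)  # floor at 1
  expect_error(embedding_size(0), ">= 1")
  expect_error(embedding_size(10, alpha = 0), "positive")
})

test_that("attention pooling is a masked convex combination", {
  set.seed(1)
  H <- matrix(rnorm(12), 4, 3)
  W <- matrix(rnorm(9), 3, 3); b <- rnorm(3); v <- rnorm(3)
  one <- attention_pool(H[1, , drop = FALSE], 1, W, b, v)
  expect_equal(one$weights, 1)
  expect_equal(one$pooled, H[1, ])
  same <- attention_pool(H[c(1, 1, 1), ], c(1, 1, 1), W, b, v)
  expect_equal(same$weights, rep(1 / 3, 3))
  expect_equal(same$pooled, H[1, ])
  r <- attention_pool(H, c(1, 0, 1, 1), W, b, v)
  expect_equal(sum(r$weights), 1)
  expect_equal(r$weights[2], 0)
  expect_equal(r$pooled, drop(crossprod(H, r$weights)))
  expect_true(all(r$weights >= 0))
  expect_error(attention_pool(H, c(0, 0, 0, 0), W, b, v), "masked")
})

test_that("zero parameters give risk one half for any input", {
  spec <- tiny_spec()
  params <- init_ensemble(spec, seed = 1)
  params <- wardflow:::nn_map(function(p) p * 0, params)
  batch <- tiny_batch(spec, B = 6)
  out <- ensemble_forward(params, spec, batch)
  expect_equal(out$prob, rep(0.5, 6))
})

test_that("the forward pass is batch-equivariant and mask-invariant", {
  for (cell in c("GRU", "LSTM")) {
    spec <- tiny_spec(cell)
    params <- init_ensemble(spec, seed = 2)
    batch <- tiny_batch(spec, B = 6, seed = 3)
    out <- ensemble_forward(params, spec, batch)
    perm <- c(4, 1, 6, 2, 5, 3)
    bp <- list(domains = lapply(batch$domains, function(d)
      list(ids = d$ids[perm, ], mask = d$mask[perm, ])),
      static = batch$static[perm, ])
    expect_equal(ensemble_forward(params, spec, bp)$prob, out$prob[perm])
    # changing ids at masked positions never changes the output
    b2 <- batch
    msk <- b2$domains$a$mask
    set.seed(9)
    b2$domains$a$ids[msk == 0] <- sample(0:6, sum(msk == 0), TRUE)
    expect_equal(ensemble_forward(params, spec, b2)$prob, out$prob)
  }
})

test_that("all-PAD sequences contribute one shared pooled representation", {
  spec <- tiny_spec()
  params <- init_ensemble(spec, seed = 4)
  batch <- tiny_batch(spec, B = 2, seed = 5)
  for (i in 1:2) {
    batch$domains$a$ids[i, ] <- 0L
    batch$domains$a$mask[i, ] <- 0L
  }
  batch$static[2, ] <- batch$static[1, ]
  batch$domains$b$ids[2, ] <- batch$domains$b$ids[1, ]
  batch$domains$b$mask[2, ] <- batch$domains$b$mask[1, ]
  out <- ensemble_forward(params, spec, batch)
  expect_equal(out$prob[1], out$prob[2])
})

test_that("zeroed attention scoring yields uniform weights over real tokens", {
  spec <- tiny_spec()
  params <- init_ensemble(spec, seed = 6)
  params$domains$a$Wa[] <- 0
  params$domains$a$va[] <- 0
  batch <- tiny_batch(spec, B = 4, seed = 7)
  fd <- wardflow:::.domain_forward(params$domains$a, spec$domains$a,
                                   batch$domains$a$ids, batch$domains$a$mask)
  me <- wardflow:::.mask_eff(batch$domains$a$mask)
  expect_equal(fd$a, me / rowSums(me), ignore_attr = TRUE)
})

test_that("analytic gradients match finite differences", {
  for (cell in c("GRU", "LSTM")) {
    spec <- tiny_spec(cell)
    params <- init_ensemble(spec, seed = 3)
    batch <- tiny_batch(spec, B = 5, seed = 11)
    set.seed(12)
    y <- sample(0:1, 5, TRUE)
    loss_fn <- function(pp)
      bce_loss(ensemble_forward(pp, spec, batch)$prob, y)
    out <- ensemble_forward(params, spec, batch, keep_cache = TRUE)
    bk <- ensemble_backward(params, spec, out, (out$prob - y) / 5)
    eps <- 1e-6
    paths <- list(c("domains", "a", "E"), c("domains", "a", "W"),
                  c("domains", "a", "U"), c("domains", "a", "b"),
                  c("domains", "a", "Wa"), c("domains", "a", "ba"),
                  c("domains", "a", "va"), c("domains", "b", "E"),
                  c("domains", "b", "U"), c("head", "w"), c("head", "b"))
    for (pth in paths) {
      g <- bk$grads[[pth]]
      n <- length(params[[pth]])
      for (j in sample(n, min(4, n))) {
        p2 <- params
        p2[[pth]][j] <- p2[[pth]][j] + eps
        lp <- loss_fn(p2)
        p2[[pth]][j] <- p2[[pth]][j] - 2 * eps
        lm <- loss_fn(p2)
        num <- (lp - lm) / (2 * eps)
        expect_lt(abs(num - g[j]) / max(1e-6, abs(num), abs(g[j])), 1e-3)
      }
    }
    # gradients finite everywhere
    expect_true(all(is.finite(unlist(bk$grads))))
    expect_true(all(out$prob > 0 & out$prob < 1))
  }
})
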
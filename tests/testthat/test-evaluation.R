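test_that("AUROC equals pairwise concordance and known limits", {
  expect_equal(auroc(c(0.1, 0.4, 0.35, 0.8), c(0, 0, 1, 1)), 0.75)
  expect_equal(auroc(c(1, 2, 3, 4), c(0, 0, 1, 1)), 1.0)
  expect_equal(auroc(c(0.5, 0.5), c(0, 1)), 0.5)  # tie counts one half
  set.seed(1)
  for (i in 1:100) {
    n <- sample(4:60, 1)
    s <- round(runif(n), 2)  # rounded so ties occur
    y <- c(0, 1, sample(0:1, n - 2, TRUE))
    expect_equal(auroc(s, y), brute_auroc(s, y), tolerance = 1e-12)
  }
  expect_error(auroc(runif(5), rep(1, 5)), "one outcome class")
  # null behavior at scale
  set.seed(2)
  s <- runif(10000); y <- rbinom(10000, 1, 0.3)
  expect_lt(abs(auroc(s, y) - 0.5), 0.02)
})

test_that("AUROC agrees with an independent ROC implementation", {
  skip_if_not_installed("pROC")
  set.seed(3)
  s <- runif(500); y <- rbinom(500, 1, plogis(3 * s - 2))
  ref <- as.numeric(suppressMessages(pROC::auc(y, s)))
  expect_equal(auroc(s, y), ref, tolerance = 1e-10)
})

test_that("AUPRC is step-wise average precision", {
  expect_equal(auprc(c(0.1, 0.4, 0.35, 0.8), c(0, 0, 1, 1)), 5 / 6)
  expect_equal(auprc(c(1, 2, 3), c(0, 1, 1)), 1.0)
  set.seed(4)
  for (i in 1:100) {
    n <- sample(3:20, 1)
    s <- round(runif(n), 1)
    y <- c(1, sample(0:1, n - 1, TRUE))
    expect_equal(auprc(s, y), brute_auprc(s, y), tolerance = 1e-12)
  }
  expect_error(auprc(runif(4), rep(0, 4)), "no positive")
  # null AP approximates the prevalence
  set.seed(5)
  s <- runif(10000); y <- rbinom(10000, 1, 0.02)
  expect_lt(abs(auprc(s, y) - mean(y)), 0.01)
})

test_that("threshold metrics match a brute-force confusion matrix", {
  expect_equal(threshold_metrics(c(0.2, 0.6, 0.8), c(0, 1, 1),
                                 thresholds = 0)$recall, 1)
  expect_equal(threshold_metrics(c(0.2, 0.6, 0.8), c(0, 1, 1),
                                 thresholds = 0)$specificity, 0)
  high <- threshold_metrics(c(0.2, 0.6), c(0, 1), thresholds = 0.9)
  expect_equal(high$recall, 0)
  expect_equal(high$specificity, 1)
  expect_true(is.na(high$precision))
  set.seed(6)
  s <- runif(300); y <- rbinom(300, 1, 0.3)
  tab <- threshold_metrics(s, y)
  for (i in seq_len(nrow(tab))) {
    th <- tab$threshold[i]
    tp <- sum(s >= th & y == 1); fp <- sum(s >= th & y == 0)
    fn <- sum(s < th & y == 1); tn <- sum(s < th & y == 0)
    expect_equal(tab$precision[i], tp / (tp + fp))
    expect_equal(tab$recall[i], tp / (tp + fn))
    expect_equal(tab$specificity[i], tn / (tn + fp))
  }
})

test_that("bootstrap intervals are ordered, reproducible and degenerate-safe", {
  set.seed(7)
  s <- runif(300); y <- rbinom(300, 1, 0.2)
  b1 <- bootstrap_ci(auroc, s, y, B = 100, seed = 11)
  b2 <- bootstrap_ci(auroc, s, y, B = 100, seed = 11)
  expect_identical(b1, b2)
  expect_lte(b1[["lo"]], b1[["median"]])
  expect_lte(b1[["median"]], b1[["hi"]])
  const <- bootstrap_ci(function(s, y) 0.42, s, y, B = 50, seed = 1)
  expect_equal(unname(const), rep(0.42, 3))
  expect_error(bootstrap_ci(auroc, s, y, B = 0), ">= 1")
})

test_that("stratified evaluation reduces to the pooled metrics for one stratum", {
  set.seed(8)
  s <- runif(600); y <- rbinom(600, 1, plogis(4 * s - 3))
  whole <- stratified_eval(rep("all", 600), s, y, B = 50, seed = 2)
  expect_equal(whole$auroc, auroc(s, y))
  expect_equal(whole$auprc, auprc(s, y))
  # identically distributed strata have overlapping intervals
  g <- rep(c("m", "f"), 300)
  two <- stratified_eval(g, s, y, B = 100, seed = 3)
  expect_true(two$auprc_lo[1] <= two$auprc_hi[2] &&
                two$auprc_lo[2] <= two$auprc_hi[1])
  # strata below the positive floor are flagged, not reported
  few <- stratified_eval(rep(c("a", "b"), c(590, 10)), s,
                         c(y[1:590], rep(0, 9), 1), B = 10, seed = 4)
  expect_false(few$evaluable[few$stratum == "b"])
})

test_that("age strata carry the planted age-risk gradient", {
  w <- fixture_world()
  meta <- w$samples$meta
  grp <- cut(meta$age, age_breaks(), include.lowest = TRUE)
  prev <- tapply(meta$label, grp, mean)
  expect_true(all(diff(prev) > -0.002))  # prevalence rises with age
})

test_that("the metric time course reports shrinking per-time counts", {
  w <- fixture_world()
  idx <- which(w$samples$meta$split == "test")
  p <- predict_risk(w$model, w$samples, idx)
  tc <- time_course_eval(w$samples$meta$t[idx], p,
                         w$samples$meta$label[idx], B = 30, seed = 5)
  expect_true(all(diff(tc$n) <= 0))
  expect_equal(sum(tc$n), length(idx))
  one <- time_course_eval(rep(0, 100), runif(100),
                          rbinom(100, 1, 0.3), B = 10, seed = 6)
  expect_equal(nrow(one), 1L)
})
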
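# Post-hoc isotonic recalibration (pool-adjacent-violators on validation
# scores) and calibration slope/intercept diagnostics.

# weighted pool-adjacent-violators: least-squares monotone fit
.pava <- function(y, w = rep(1, length(y))) {
  n <- length(y)
  val <- numeric(n)
  wt <- numeric(n)
  len <- integer(n)
  j <- 0L
  for (i in seq_len(n)) {
    j <- j + 1L
    val[j] <- y[i]
    wt[j] <- w[i]
    len[j] <- 1L
    while (j > 1L && val[j - 1L] > val[j]) {
      val[j - 1L] <- (wt[j - 1L] * val[j - 1L] + wt[j] * val[j]) /
        (wt[j - 1L] + wt[j])
      wt[j - 1L] <- wt[j - 1L] + wt[j]
      len[j - 1L] <- len[j - 1L] + len[j]
      j <- j - 1L
    }
  }
  rep(val[seq_len(j)], len[seq_len(j)])
}

#' Fit an isotonic recalibration map
#'
#' Pool-adjacent-violators solution minimizing squared error between scores
#' and labels subject to monotonicity. Tied scores are pooled before
#' fitting, so the map is a function of the score. Fit this on the
#' validation split only and keep the test set untouched.
#'
#' @param scores raw model risks in `[0, 1]`.
#' @param labels 0/1 outcome labels.
#' @return an `isotonic_map`: step function defined by `breakpoints`
#'   (`score`, `fitted`, `n`).
#' @export
fit_isotonic <- function(scores, labels) {
  if (any(scores < 0 | scores > 1)) stop_data("scores must lie in [0, 1]")
  if (length(unique(labels)) < 2L) {
    stop_data("both outcome classes are required to fit a calibration map")
  }
  ord <- order(scores)
  s <- scores[ord]
  y <- as.numeric(labels[ord])
  # pool tied scores
  grp <- cumsum(c(TRUE, diff(s) != 0))
  w <- as.numeric(tabulate(grp))
  ybar <- as.numeric(rowsum(y, grp)) / w
  su <- s[!duplicated(grp)]
  fitted <- .pava(ybar, w)
  structure(list(breakpoints = data.table::data.table(score = su,
                                                      fitted = fitted,
                                                      n = w)),
            class = "isotonic_map")
}

#' Apply an isotonic map to scores
#'
#' Right-continuous step interpolation: a score maps to the fitted value of
#' the largest breakpoint not exceeding it; scores outside the fitted range
#' clamp to the end values.
#'
#' @param map an [fit_isotonic()] result.
#' @param scores numeric scores.
#' @return calibrated probabilities.
#' @export
apply_calibration <- function(map, scores) {
  stopifnot(inherits(map, "isotonic_map"))
  bp <- map$breakpoints
  idx <- findInterval(scores, bp$score)
  idx[idx == 0L] <- 1L
  bp$fitted[idx]
}

#' Binned calibration slope and intercept
#'
#' Weighted least-squares line through (mean predicted risk, observed event
#' rate) over `n_bins` equal-count score bins, weights equal to bin sizes.
#' A perfectly calibrated model has slope 1 and intercept 0 on the
#' probability scale.
#'
#' @param scores predicted probabilities.
#' @param labels 0/1 labels.
#' @param n_bins number of equal-count bins (default 10).
#' @return named vector `c(slope, intercept)`.
#' @export
calibration_slope_intercept <- function(scores, labels, n_bins = 10) {
  if (length(unique(labels)) < 2L) {
    stop_data("both outcome classes are required for calibration diagnostics")
  }
  br <- unique(stats::quantile(scores, probs = seq(0, 1, length.out = n_bins + 1),
                               type = 7, names = FALSE))
  if (length(br) < 3L) {
    stop_data("fewer than 2 distinct score bins; calibration slope undefined")
  }
  bin <- cut(scores, br, include.lowest = TRUE)
  pred <- tapply(scores, bin, mean)
  obs <- tapply(labels, bin, mean)
  n <- tapply(rep(1, length(scores)), bin, sum)
  keep <- !is.na(pred)
  pred <- pred[keep]; obs <- obs[keep]; n <- n[keep]
  if (length(pred) < 2L || stats::sd(pred) < 1e-12) {
    stop_data("calibration slope undefined: predictions are constant %s",
              "across bins")
  }
  fit <- stats::lm(obs ~ pred, weights = n)
  c(slope = unname(stats::coef(fit)[2L]),
    intercept = unname(stats::coef(fit)[1L]))
}

#' Logit-scale calibration slope (secondary diagnostic)
#'
#' Slope of a logistic recalibration `label ~ logit(score)`; 1 for a
#' perfectly calibrated model.
#'
#' @param scores predicted probabilities.
#' @param labels 0/1 labels.
#' @return named vector `c(slope, intercept)` on the logit scale.
#' @export
calibration_slope_logit <- function(scores, labels) {
  if (length(unique(labels)) < 2L) {
    stop_data("both outcome classes are required for calibration diagnostics")
  }
  lp <- stats::qlogis(pmin(pmax(scores, 1e-8), 1 - 1e-8))
  fit <- stats::glm(labels ~ lp, family = stats::binomial())
  c(slope = unname(stats::coef(fit)[2L]),
    intercept = unname(stats::coef(fit)[1L]))
}

#' Write an isotonic map to JSON
#' @param map an `isotonic_map`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_calibration <- function(map, path) {
  jsonlite::write_json(map$breakpoints, path, digits = NA)
  invisible(path)
}
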
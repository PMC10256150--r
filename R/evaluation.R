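# Discrimination and threshold metrics with percentile-bootstrap confidence
# intervals, stratified by sex, age group and time into the admission.

#' Area under the ROC curve
#'
#' Probability that a random positive outscores a random negative, with ties
#' counted 1/2 (rank/Mann-Whitney formulation).
#'
#' @param scores numeric scores.
#' @param labels 0/1 labels, both classes present.
#' @return AUROC in `[0, 1]`.
#' @export
auroc <- function(scores, labels) {
  y <- as.integer(labels)
  n1 <- sum(y == 1L)
  n0 <- sum(y == 0L)
  if (n1 == 0L || n0 == 0L) {
    stop_data("AUROC undefined: only one outcome class present")
  }
  r <- rank(scores)
  (sum(r[y == 1L]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Area under the precision-recall curve (average precision)
#'
#' Step-wise average precision: the sum of precision at each unique score
#' threshold weighted by the recall increment there. No trapezoidal
#' interpolation is applied.
#'
#' @param scores numeric scores.
#' @param labels 0/1 labels with at least one positive.
#' @return AUPRC in `[0, 1]`; its chance level equals the outcome prevalence.
#' @export
auprc <- function(scores, labels) {
  y <- as.integer(labels)
  n1 <- sum(y == 1L)
  if (n1 == 0L) stop_data("AUPRC undefined: no positive labels")
  ord <- order(scores, decreasing = TRUE)
  y <- y[ord]
  s <- scores[ord]
  tp <- cumsum(y)
  fp <- cumsum(1L - y)
  last <- c(diff(s) != 0, TRUE)  # last index of each unique threshold
  tp <- tp[last]
  fp <- fp[last]
  prec <- tp / (tp + fp)
  dtp <- diff(c(0L, tp))
  sum(prec * dtp) / n1
}

#' Precision, recall and specificity at fixed risk thresholds
#'
#' Classifies positive iff `score >= threshold`. When no sample is predicted
#' positive, precision is undefined and reported as `NA`.
#'
#' @param scores predicted probabilities.
#' @param labels 0/1 labels.
#' @param thresholds risk thresholds (default 1%, 5%, 10%, 20%, 50%).
#' @return `data.table` with one row per threshold.
#' @export
threshold_metrics <- function(scores, labels,
                              thresholds = c(0.01, 0.05, 0.10, 0.20, 0.50)) {
  y <- as.integer(labels)
  out <- lapply(thresholds, function(th) {
    pred <- scores >= th
    tp <- sum(pred & y == 1L)
    fp <- sum(pred & y == 0L)
    fn <- sum(!pred & y == 1L)
    tn <- sum(!pred & y == 0L)
    data.table::data.table(
      threshold = th,
      precision = if (tp + fp == 0L) NA_real_ else tp / (tp + fp),
      recall = if (tp + fn == 0L) NA_real_ else tp / (tp + fn),
      specificity = if (tn + fp == 0L) NA_real_ else tn / (tn + fp))
  })
  data.table::rbindlist(out)
}

#' Percentile bootstrap confidence interval of a metric
#'
#' Resamples sample indices with replacement `B` times; resamples missing an
#' outcome class are redrawn (at most 10 times each before erroring) and the
#' 2.5/50/97.5 percentiles of the metric are reported. Bit-reproducible
#' given `seed`.
#'
#' @param metric function `(scores, labels) -> scalar`.
#' @param scores,labels the evaluation data.
#' @param B number of bootstrap resamples (default 200).
#' @param seed integer seed.
#' @return named vector `c(median, lo, hi)` (2.5% and 97.5% percentiles).
#' @export
bootstrap_ci <- function(metric, scores, labels, B = 200L, seed = 1L) {
  if (B < 1) stop_config("B must be >= 1")
  n <- length(scores)
  vals <- with_seed(seed, {
    vapply(seq_len(B), function(b) {
      for (try in seq_len(10L)) {
        idx <- sample.int(n, n, replace = TRUE)
        if (length(unique(labels[idx])) == 2L) {
          return(metric(scores[idx], labels[idx]))
        }
      }
      stop_data("bootstrap resampling produced single-class resamples %s",
                "10 times in a row")
    }, numeric(1))
  })
  q <- stats::quantile(vals, c(0.5, 0.025, 0.975), names = FALSE, type = 7)
  c(median = q[1], lo = q[2], hi = q[3])
}

# all four report metrics on shared resamples; returns a one-row data.table
.report_row <- function(scores, labels, B = 200L, seed = 1L, n_bins = 10) {
  point <- list(
    auroc = auroc(scores, labels),
    auprc = auprc(scores, labels),
    slope = NA_real_, intercept = NA_real_)
  sl <- tryCatch(calibration_slope_intercept(scores, labels, n_bins),
                 error = function(e) c(slope = NA_real_, intercept = NA_real_))
  point$slope <- sl[["slope"]]
  point$intercept <- sl[["intercept"]]
  n <- length(scores)
  boots <- with_seed(seed, {
    res <- matrix(NA_real_, B, 4L)
    for (b in seq_len(B)) {
      idx <- NULL
      for (try in seq_len(10L)) {
        cand <- sample.int(n, n, replace = TRUE)
        if (length(unique(labels[cand])) == 2L) { idx <- cand; break }
      }
      if (is.null(idx)) {
        stop_data("bootstrap resampling produced single-class resamples %s",
                  "10 times in a row")
      }
      sb <- scores[idx]; yb <- labels[idx]
      res[b, 1L] <- auroc(sb, yb)
      res[b, 2L] <- auprc(sb, yb)
      slb <- tryCatch(calibration_slope_intercept(sb, yb, n_bins),
                      error = function(e) c(NA_real_, NA_real_))
      res[b, 3L] <- slb[[1L]]
      res[b, 4L] <- slb[[2L]]
    }
    res
  })
  qs <- apply(boots, 2, stats::quantile, probs = c(0.5, 0.025, 0.975),
              names = FALSE, na.rm = TRUE, type = 7)
  data.table::data.table(
    n = n, n_pos = sum(labels == 1L),
    auroc = point$auroc, auroc_med = qs[1, 1], auroc_lo = qs[2, 1],
    auroc_hi = qs[3, 1],
    auprc = point$auprc, auprc_med = qs[1, 2], auprc_lo = qs[2, 2],
    auprc_hi = qs[3, 2],
    slope = point$slope, slope_med = qs[1, 3], slope_lo = qs[2, 3],
    slope_hi = qs[3, 3],
    intercept = point$intercept, intercept_med = qs[1, 4],
    intercept_lo = qs[2, 4], intercept_hi = qs[3, 4])
}

#' Evaluate scores with bootstrap confidence intervals
#'
#' AUROC, AUPRC and binned calibration slope/intercept, each with the
#' percentile interval over `B` shared bootstrap resamples of the assessment
#' samples.
#'
#' @param scores predicted (calibrated) probabilities.
#' @param labels 0/1 labels.
#' @param B bootstrap resamples.
#' @param seed integer seed.
#' @param n_bins calibration bins.
#' @return one-row `data.table` with point estimates and
#'   `(median, 2.5%, 97.5%)` columns per metric.
#' @export
evaluate_scores <- function(scores, labels, B = 200L, seed = 1L,
                            n_bins = 10) {
  .report_row(scores, labels, B = B, seed = seed, n_bins = n_bins)
}

#' Default age strata boundaries (years)
#' @return numeric vector of bin edges.
#' @export
age_breaks <- function() c(16, 37, 58, 79, 100)

#' Stratified evaluation
#'
#' Computes the metric report within each stratum; strata with fewer than
#' `min_pos` positive samples are flagged not evaluable rather than
#' reported.
#'
#' @param strata character/factor vector, one value per sample.
#' @param scores,labels evaluation data.
#' @param B,seed bootstrap settings.
#' @param min_pos minimum positives per evaluable stratum.
#' @return `data.table` with one row per stratum (`evaluable` flags strata
#'   below the positive-count floor).
#' @export
stratified_eval <- function(strata, scores, labels, B = 200L, seed = 1L,
                            min_pos = 5L) {
  if (length(strata) != length(scores)) {
    stop_data("strata must assign one value per sample")
  }
  out <- lapply(sort(unique(as.character(strata))), function(g) {
    idx <- which(strata == g)
    n_pos <- sum(labels[idx] == 1L)
    if (n_pos < min_pos || n_pos == length(idx)) {
      return(data.table::data.table(stratum = g, evaluable = FALSE,
                                    n = length(idx), n_pos = n_pos))
    }
    row <- .report_row(scores[idx], labels[idx], B = B, seed = seed)
    cbind(data.table::data.table(stratum = g, evaluable = TRUE), row)
  })
  data.table::rbindlist(out, fill = TRUE)
}

#' Metric time course over the admission
#'
#' AUROC/AUPRC per assessment time with bootstrap intervals and the sample
#' counts per time of prediction (which decrease as stays end).
#'
#' @param t numeric vector of assessment offsets (hours), one per sample.
#' @param scores,labels evaluation data.
#' @param B,seed bootstrap settings.
#' @param min_pos minimum positives for an evaluable time point.
#' @param max_t optional cap: times above it are pooled into the last row.
#' @return `data.table` with one row per assessment time.
#' @export
time_course_eval <- function(t, scores, labels, B = 200L, seed = 1L,
                             min_pos = 5L, max_t = NULL) {
  tt <- t
  if (!is.null(max_t)) tt <- pmin(tt, max_t)
  out <- lapply(sort(unique(tt)), function(ti) {
    idx <- which(tt == ti)
    n_pos <- sum(labels[idx] == 1L)
    base <- data.table::data.table(t = ti, n = length(idx), n_pos = n_pos)
    if (n_pos < min_pos || n_pos == length(idx)) {
      base$evaluable <- FALSE
      return(base)
    }
    row <- .report_row(scores[idx], labels[idx], B = B, seed = seed)
    cbind(base, evaluable = TRUE,
          row[, c("auroc", "auroc_lo", "auroc_hi", "auprc", "auprc_lo",
                  "auprc_hi")])
  })
  data.table::rbindlist(out, fill = TRUE)
}
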
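#' Area under the ROC curve
#'
#' Rank-based (Mann-Whitney) AUC: the probability that a random positive
#' scores above a random negative, with ties counted half. Equivalent to the
#' trapezoidal area under the empirical ROC curve.
#'
#' @param scores Numeric scores or probabilities (higher = more positive).
#' @param labels Binary 0/1 labels; both classes must be present.
#' @return AUC in \[0, 1\].
#' @export
auc <- function(scores, labels) {
  labels <- as.integer(labels)
  stopifnot(length(scores) == length(labels),
            all(labels %in% c(0L, 1L)))
  n1 <- sum(labels == 1L); n0 <- sum(labels == 0L)
  if (n1 == 0 || n0 == 0) stop("both classes must be present")
  r <- rank(scores, ties.method = "average")
  (sum(r[labels == 1L]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Youden-optimal classification threshold
#'
#' Scans all observed score values as candidate thresholds (classification:
#' score >= threshold is positive) and returns the one maximizing the Youden
#' index (sensitivity + specificity - 1). Ties favour the lowest threshold.
#'
#' @inheritParams auc
#' @return The chosen threshold.
#' @export
youden_threshold <- function(scores, labels) {
  labels <- as.integer(labels)
  cand <- sort(unique(scores))
  j <- vapply(cand, function(t) {
    pred <- scores >= t
    sens <- sum(pred & labels == 1L) / sum(labels == 1L)
    spec <- sum(!pred & labels == 0L) / sum(labels == 0L)
    sens + spec - 1
  }, numeric(1))
  cand[which.max(j)]
}

#' Operating-point classification metrics
#'
#' Confusion-matrix metrics at a fixed threshold (score >= threshold is
#' called positive). The threshold is typically chosen on training data by
#' [youden_threshold()] and then frozen for test/validation sets. PPV/NPV
#' with a zero denominator are returned as `NA`.
#'
#' @inheritParams auc
#' @param threshold Classification threshold.
#' @return List with `sensitivity`, `specificity`, `accuracy`, `ppv`, `npv`,
#'   `threshold` and the confusion counts `tp`, `fp`, `tn`, `fn`.
#' @export
operating_metrics <- function(scores, labels, threshold) {
  labels <- as.integer(labels)
  stopifnot(all(labels %in% c(0L, 1L)), sum(labels) > 0, sum(!labels) > 0)
  pred <- scores >= threshold
  tp <- sum(pred & labels == 1L); fp <- sum(pred & labels == 0L)
  fn <- sum(!pred & labels == 1L); tn <- sum(!pred & labels == 0L)
  list(sensitivity = tp / (tp + fn),
       specificity = tn / (tn + fp),
       accuracy = (tp + tn) / length(labels),
       ppv = if (tp + fp > 0) tp / (tp + fp) else NA_real_,
       npv = if (tn + fn > 0) tn / (tn + fn) else NA_real_,
       threshold = threshold, tp = tp, fp = fp, tn = tn, fn = fn)
}

#' Calibration curve
#'
#' Bins predicted probabilities into `n_bins` equal-width bins on \[0, 1\]
#' and reports, per nonempty bin, the mean predicted probability, the
#' observed positive fraction and the count.
#'
#' @param probs Predicted probabilities in \[0, 1\].
#' @param labels Binary 0/1 outcomes.
#' @param n_bins Number of equal-width bins (default 10).
#' @return Data.frame with `bin`, `mean_predicted`, `observed_fraction`,
#'   `count`; empty bins are omitted.
#' @export
calibration_curve <- function(probs, labels, n_bins = 10) {
  stopifnot(all(probs >= 0 & probs <= 1), length(probs) == length(labels))
  labels <- as.integer(labels)
  bin <- pmin(floor(probs * n_bins) + 1L, n_bins)
  out <- do.call(rbind, lapply(sort(unique(bin)), function(b) {
    i <- bin == b
    data.frame(bin = b, mean_predicted = mean(probs[i]),
               observed_fraction = mean(labels[i]), count = sum(i))
  }))
  rownames(out) <- NULL
  out
}

#' Decision curve analysis
#'
#' Net benefit of acting on the model at each threshold probability `pt`:
#' `NB(pt) = TP/n - (FP/n) * pt / (1 - pt)`, classifying `prob >= pt` as
#' positive. Reference strategies: treat-all (everyone positive) and
#' treat-none (net benefit identically 0).
#'
#' @param probs Predicted probabilities.
#' @param labels Binary 0/1 outcomes.
#' @param thresholds Threshold-probability grid in (0, 1)
#'   (default `seq(0.01, 0.99, 0.01)`).
#' @return Data.frame (class `dca_result`) with `threshold`, `net_benefit`,
#'   `treat_all`, `treat_none`.
#' @export
decision_curve <- function(probs, labels, thresholds = seq(0.01, 0.99, 0.01)) {
  stopifnot(all(thresholds > 0 & thresholds < 1))
  labels <- as.integer(labels)
  n <- length(labels)
  prev <- mean(labels)
  nb <- vapply(thresholds, function(pt) {
    pred <- probs >= pt
    tp <- sum(pred & labels == 1L); fp <- sum(pred & labels == 0L)
    tp / n - (fp / n) * pt / (1 - pt)
  }, numeric(1))
  ta <- vapply(thresholds, function(pt) {
    prev - (1 - prev) * pt / (1 - pt)
  }, numeric(1))
  out <- data.frame(threshold = thresholds, net_benefit = nb,
                    treat_all = ta, treat_none = 0)
  class(out) <- c("dca_result", class(out))
  out
}

#' Intraclass correlation coefficient ICC(2,1)
#'
#' Two-way random-effects, absolute-agreement, single-measurement ICC
#' (McGraw & Wong ICC(A,1)) with an F-based 95% confidence interval, for
#' reliability of repeated segmentations. Agreement labels: <= 0.40 poor,
#' (0.40, 0.60] moderate, (0.60, 0.80] good, > 0.80 excellent.
#'
#' @param ratings Numeric matrix, subjects in rows (>= 5), raters in
#'   columns (>= 2).
#' @param conf_level Confidence level (default 0.95).
#' @return List of class `icc_result` with `icc`, `ci_lo`, `ci_hi`, `label`,
#'   `n`, `k`.
#' @export
icc_agreement <- function(ratings, conf_level = 0.95) {
  ratings <- as.matrix(ratings)
  n <- nrow(ratings); k <- ncol(ratings)
  if (k < 2 || n < 5) stop("need >= 2 raters and >= 5 subjects")
  if (anyNA(ratings)) stop("ratings must be complete")
  grand <- mean(ratings)
  row_m <- rowMeans(ratings); col_m <- colMeans(ratings)
  msr <- k * sum((row_m - grand)^2) / (n - 1)          # between subjects
  msc <- n * sum((col_m - grand)^2) / (k - 1)          # between raters
  sse <- sum((ratings - outer(row_m, rep(1, k)) -
                outer(rep(1, n), col_m) + grand)^2)
  mse <- sse / ((n - 1) * (k - 1))                      # residual
  if (msr <= 0 || (msr == mse && msc == mse && mse == 0))
    stop("zero between-subject variance: ICC undefined")
  icc <- (msr - mse) / (msr + (k - 1) * mse + k * (msc - mse) / n)

  # F-based CI (McGraw & Wong 1996, ICC(A,1))
  alpha <- 1 - conf_level
  a <- k * icc / (n * (1 - icc))
  b <- 1 + k * icc * (n - 1) / (n * (1 - icc))
  v <- (a * msc + b * mse)^2 /
    ((a * msc)^2 / (k - 1) + (b * mse)^2 / ((n - 1) * (k - 1)))
  f_l <- stats::qf(1 - alpha / 2, n - 1, v)
  f_u <- stats::qf(1 - alpha / 2, v, n - 1)
  ci_lo <- n * (msr - f_l * mse) /
    (f_l * (k * msc + (k * n - k - n) * mse) + n * msr)
  ci_hi <- n * (f_u * msr - mse) /
    (k * msc + (k * n - k - n) * mse + n * f_u * msr)

  label <- if (icc <= 0.40) "poor" else if (icc <= 0.60) "moderate"
           else if (icc <= 0.80) "good" else "excellent"
  structure(list(icc = icc, ci_lo = ci_lo, ci_hi = ci_hi, label = label,
                 n = n, k = k),
            class = "icc_result")
}

#' @export
print.icc_result <- function(x, ...) {
  cat(sprintf("<icc_result> ICC %.3f (95%% CI %.3f-%.3f), %s agreement (n=%d, k=%d)\n",
              x$icc, x$ci_lo, x$ci_hi, x$label, x$n, x$k))
  invisible(x)
}

#' Full evaluation of a fitted model on one data set
#'
#' @param fit A [fit_logistic()] model.
#' @param data Data.frame with the fit's predictors and outcome.
#' @param threshold Operating threshold; `NULL` chooses the Youden threshold
#'   on `data` (use the training set for that, then pass the frozen value to
#'   test/validation sets).
#' @return List with `auc`, the [operating_metrics()] fields, `threshold`
#'   and the vector of predicted probabilities.
#' @export
evaluate_model <- function(fit, data, threshold = NULL) {
  probs <- predict_prob(fit, data)
  y <- data[[fit$outcome]]
  if (is.null(threshold)) threshold <- youden_threshold(probs, y)
  om <- operating_metrics(probs, y, threshold)
  c(list(auc = auc(probs, y)), om, list(probs = probs))
}
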
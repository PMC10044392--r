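#' Per-pixel confusion counts between two binary masks
#'
#' Tallies true positives, false positives, false negatives and true negatives
#' between a predicted and a reference binary mask. Foreground (1) is the
#' positive class.
#'
#' @param pred,truth binary masks (0/1 matrices) of identical dimensions.
#' @return A list of class `confusion_counts` with integer fields `TP`, `FP`,
#'   `FN`, `TN`.
#' @export
#' @examples
#' p <- matrix(c(1, 0, 1, 0), 2, 2)
#' t <- matrix(c(1, 1, 0, 0), 2, 2)
#' confusion_counts(p, t)
confusion_counts <- function(pred, truth) {
  assert_mask(pred, "pred")
  assert_mask(truth, "truth")
  assert_same_shape(pred, truth)
  tp <- sum(pred == 1 & truth == 1)
  fp <- sum(pred == 1 & truth == 0)
  fn <- sum(pred == 0 & truth == 1)
  tn <- sum(pred == 0 & truth == 0)
  structure(list(TP = tp, FP = fp, FN = fn, TN = tn),
            class = "confusion_counts")
}

#' Segmentation metrics from confusion counts
#'
#' Computes precision = TP/(TP+FP), recall = TP/(TP+FN),
#' F1 = 2 * precision * recall / (precision + recall) and
#' IoU = TP/(TP+FN+FP). Any 0/0 ratio is defined as 0, except when both masks
#' are entirely empty (TP = FP = FN = 0), in which case every metric is 1:
#' an empty prediction of an empty reference is a perfect prediction.
#'
#' The algebraic identity F1 = 2*IoU/(1+IoU) holds whenever both are computed
#' from the same counts.
#'
#' @param counts a `confusion_counts` object, or a list with fields
#'   `TP`, `FP`, `FN` (and optionally `TN`).
#' @return A list of class `metric_report` with fields `precision`, `recall`,
#'   `f1`, `iou`, each in `[0, 1]`.
#' @export
metric_report <- function(counts) {
  tp <- counts$TP; fp <- counts$FP; fn <- counts$FN
  if (any(c(tp, fp, fn) < 0)) abort_wa("confusion counts must be non-negative")
  if (tp == 0 && fp == 0 && fn == 0) {
    out <- list(precision = 1, recall = 1, f1 = 1, iou = 1)
  } else {
    safe_div <- function(num, den) if (den == 0) 0 else num / den
    precision <- safe_div(tp, tp + fp)
    recall <- safe_div(tp, tp + fn)
    f1 <- safe_div(2 * precision * recall, precision + recall)
    iou <- safe_div(tp, tp + fn + fp)
    out <- list(precision = precision, recall = recall, f1 = f1, iou = iou)
  }
  structure(out, class = "metric_report")
}

#' Binary focal loss parameters
#'
#' `alpha` weights the foreground class, `gamma` is the focusing exponent that
#' down-weights easy pixels. `beta` is carried as an inert, documented
#' parameter for interface completeness; it plays no role in the loss.
#'
#' @param alpha foreground class weight in `(0, 1]`. Default 0.25.
#' @param gamma focusing exponent, >= 0. Default 2.
#' @param beta reserved, unused. Default 1.
#' @return A list of class `focal_loss_params`.
#' @export
focal_loss_params <- function(alpha = 0.25, gamma = 2, beta = 1) {
  if (!is.numeric(alpha) || length(alpha) != 1 || alpha <= 0 || alpha > 1)
    abort_wa("alpha must be in (0, 1]")
  if (!is.numeric(gamma) || length(gamma) != 1 || gamma < 0)
    abort_wa("gamma must be >= 0")
  structure(list(alpha = alpha, gamma = gamma, beta = beta),
            class = "focal_loss_params")
}

#' Binary focal loss
#'
#' Mean over pixels of the standard binary focal loss
#' \deqn{-\alpha \, y (1-p)^\gamma \log p \;-\; (1-\alpha)(1-y)\, p^\gamma \log(1-p)}
#' where `y` is the ground-truth label and `p` the predicted foreground
#' probability. Probabilities are clipped to `[1e-7, 1 - 1e-7]` before the
#' logarithm. With `gamma = 0` and `alpha = 0.5` the loss reduces to half the
#' binary cross-entropy. Mean (not sum) reduction makes the value
#' resolution-independent.
#'
#' @param truth binary mask (0/1 matrix).
#' @param pred probability map: numeric matrix with values in `[0, 1]`, same
#'   dimensions as `truth`.
#' @param params a [focal_loss_params()] object.
#' @return A non-negative scalar.
#' @export
binary_focal_loss <- function(truth, pred, params = focal_loss_params()) {
  assert_mask(truth, "truth")
  if (!is.matrix(pred) || anyNA(pred) || any(pred < 0) || any(pred > 1))
    abort_wa("pred must be a matrix of probabilities in [0, 1]")
  assert_same_shape(pred, truth)
  if (!inherits(params, "focal_loss_params"))
    params <- do.call(focal_loss_params, params)
  eps <- 1e-7
  p <- pmin(pmax(pred, eps), 1 - eps)
  a <- params$alpha; g <- params$gamma
  l <- -a * truth * (1 - p)^g * log(p) -
    (1 - a) * (1 - truth) * p^g * log(1 - p)
  mean(l)
}

#' Binarize a probability map
#'
#' Pixels with probability greater than or equal to `threshold` become
#' foreground.
#'
#' @param pred probability map (numeric matrix in `[0, 1]`).
#' @param threshold scalar in `(0, 1)`. Default 0.5.
#' @return A 0/1 integer matrix of the same dimensions.
#' @export
binarize <- function(pred, threshold = 0.5) {
  if (!is.numeric(threshold) || length(threshold) != 1 ||
      threshold <= 0 || threshold >= 1)
    abort_wa("threshold must be in (0, 1)")
  if (!is.matrix(pred)) abort_wa("pred must be a matrix")
  out <- matrix(as.integer(pred >= threshold), nrow(pred), ncol(pred))
  out
}

#' Neutral binarization threshold implied by a focal loss
#'
#' A model trained with an asymmetric loss is not calibrated around 0.5: at a
#' pixel whose true foreground posterior is `q`, the loss-minimising
#' prediction solves
#' \deqn{\min_p \; \alpha q (1-p)^\gamma (-\log p) + (1-\alpha)(1-q) p^\gamma (-\log(1-p)).}
#' The neutral decision threshold is that equilibrium at `q = 0.5`: pixels the
#' model scores above it carry more than even evidence of foreground. For
#' `gamma = 0` this reduces to `alpha` exactly; for the default
#' `alpha = 0.25, gamma = 2` it is about 0.40. Binarizing at a flat 0.5
#' instead systematically under-segments.
#'
#' @param params a [focal_loss_params()].
#' @param q posterior at which to balance the decision. Default 0.5.
#' @return Scalar threshold in `(0, 1)`.
#' @export
focal_neutral_threshold <- function(params = focal_loss_params(), q = 0.5) {
  if (!inherits(params, "focal_loss_params"))
    params <- do.call(focal_loss_params, params)
  a <- params$alpha; g <- params$gamma
  f <- function(p) a * q * (1 - p)^g * (-log(p)) +
    (1 - a) * (1 - q) * p^g * (-log(1 - p))
  stats::optimize(f, c(1e-6, 1 - 1e-6))$minimum
}

#' Evaluate per-image segmentation metrics over a set of mask pairs
#'
#' @param preds,truths lists of binary masks of equal length.
#' @param pooled if `TRUE`, confusion counts are pooled over all pixels of all
#'   images before computing metrics; otherwise (default) metrics are computed
#'   per image and averaged.
#' @return A `metric_report`.
#' @export
evaluate_masks <- function(preds, truths, pooled = FALSE) {
  if (length(preds) != length(truths))
    abort_wa("preds and truths must have equal length")
  if (length(preds) == 0) abort_wa("no masks to evaluate")
  if (pooled) {
    tot <- list(TP = 0, FP = 0, FN = 0, TN = 0)
    for (i in seq_along(preds)) {
      cc <- confusion_counts(preds[[i]], truths[[i]])
      tot$TP <- tot$TP + cc$TP; tot$FP <- tot$FP + cc$FP
      tot$FN <- tot$FN + cc$FN; tot$TN <- tot$TN + cc$TN
    }
    metric_report(tot)
  } else {
    reps <- lapply(seq_along(preds), function(i)
      metric_report(confusion_counts(preds[[i]], truths[[i]])))
    structure(list(
      precision = mean(vapply(reps, `[[`, 0, "precision")),
      recall = mean(vapply(reps, `[[`, 0, "recall")),
      f1 = mean(vapply(reps, `[[`, 0, "f1")),
      iou = mean(vapply(reps, `[[`, 0, "iou"))
    ), class = "metric_report")
  }
}
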
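# Evaluation metrics: Dice overlap for segmentation, confusion-based accuracy
# and F1 for pair matching, and a ROC/EER sweep used to calibrate the
# distance threshold of the Siamese verifier.

#' Dice coefficient between a prediction and a binary mask
#'
#' `2|P intersect Y| / (|P| + |Y|)`, in `[0, 1]`: 0 = no overlap, 1 = complete
#' overlap. `P` may be a soft probability map, in which case the intersection
#' is the elementwise product. Both masks empty returns 1 by convention.
#'
#' @param p predicted mask (binary or soft, same dims as `y`).
#' @param y true binary mask.
#' @return Numeric scalar in `[0, 1]`.
#' @export
dice_coefficient <- function(p, y) {
  if (!identical(dim(p), dim(y))) stop("mask dimensions differ")
  s <- sum(p) + sum(y)
  if (s == 0) return(1)
  2 * sum(p * y) / s
}

#' Dice loss: `1 - dice_coefficient`
#'
#' Zero iff the overlap is perfect; differentiable in a soft prediction.
#' @inheritParams dice_coefficient
#' @export
dice_loss <- function(p, y) 1 - dice_coefficient(p, y)

#' Confusion counts for binary decisions
#'
#' @param predicted logical/0-1 vector of predicted positives.
#' @param actual logical/0-1 vector of true positives.
#' @return list with TP, FP, FN, TN.
#' @export
confusion_counts <- function(predicted, actual) {
  if (length(predicted) != length(actual)) stop("length mismatch")
  p <- as.logical(predicted); a <- as.logical(actual)
  list(TP = sum(p & a), FP = sum(p & !a), FN = sum(!p & a), TN = sum(!p & !a))
}

#' F1 score from confusion counts
#'
#' `2 TP / (2 TP + FP + FN)`; equals the harmonic mean of precision and
#' recall wherever both are defined. With no true or predicted positives at
#' all the score is undefined and reported as 0 with a warning.
#'
#' @param c list with TP, FP, FN (as from [confusion_counts()]).
#' @return Numeric scalar in `[0, 1]`.
#' @export
f1_score <- function(c) {
  if (any(unlist(c[c("TP", "FP", "FN")]) < 0)) stop("negative counts")
  den <- 2 * c$TP + c$FP + c$FN
  if (den == 0) {
    warning("F1 undefined (no positives anywhere); reporting 0")
    return(0)
  }
  2 * c$TP / den
}

#' Binary accuracy: fraction of correct predictions
#'
#' Serves both pixelwise segmentation accuracy and pair-matching accuracy.
#'
#' @param predictions,labels equal-length 0/1 or logical vectors (matrices are
#'   flattened).
#' @return Fraction correct in `[0, 1]`.
#' @export
binary_accuracy <- function(predictions, labels) {
  if (length(predictions) != length(labels)) stop("length mismatch")
  mean(as.logical(predictions) == as.logical(labels))
}

#' ROC sweep and equal error rate over match distances
#'
#' Sweeps the acceptance threshold over the observed distances (accept iff
#' `d <= tau`). FAR = fraction of impostor pairs accepted, FRR = fraction of
#' genuine pairs rejected. The EER is the rate at the crossing FAR = FRR,
#' linearly interpolated between bracketing sweep points.
#'
#' @param distances non-negative match distances.
#' @param genuine logical, TRUE for genuine pairs.
#' @return list with `roc` (data.frame tau/far/frr), `eer`, `tau_eer`.
#' @export
roc_and_eer <- function(distances, genuine) {
  genuine <- as.logical(genuine)
  if (!any(genuine) || all(genuine))
    stop("need at least one genuine and one impostor distance")
  taus <- sort(unique(c(0, distances)))
  far <- vapply(taus, function(t) mean(distances[!genuine] <= t), numeric(1))
  frr <- vapply(taus, function(t) mean(distances[genuine] > t), numeric(1))
  d <- far - frr
  i <- which(d >= 0)[1]  # far is nondecreasing, frr nonincreasing
  if (is.na(i)) i <- length(taus)
  if (i == 1 || d[i] == 0) {
    eer <- (far[i] + frr[i]) / 2
    tau <- taus[i]
  } else {
    w <- d[i] / (d[i] - d[i - 1])  # interpolate to the crossing
    eer <- (1 - w) * (far[i] + frr[i]) / 2 + w * (far[i - 1] + frr[i - 1]) / 2
    tau <- (1 - w) * taus[i] + w * taus[i - 1]
  }
  list(roc = data.frame(tau = taus, far = far, frr = frr), eer = eer, tau_eer = tau)
}

#' Calibrate a distance threshold to maximise F1 on validation pairs
#'
#' @param distances non-negative match distances.
#' @param genuine logical, TRUE for genuine pairs.
#' @return The threshold tau maximising F1 (accept iff `d <= tau`).
#' @export
calibrate_threshold <- function(distances, genuine) {
  genuine <- as.logical(genuine)
  taus <- sort(unique(distances))
  f1 <- vapply(taus, function(t)
    f1_score(confusion_counts(distances <= t, genuine)), numeric(1))
  taus[which.max(f1)]
}
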
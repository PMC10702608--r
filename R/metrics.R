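# Pixel-level evaluation: fixed-threshold binarisation, confusion counts,
# accuracy / Dice / sensitivity / specificity, and the ROC area (as the
# Mann-Whitney rank statistic, which equals the trapezoidal area under the
# ROC traced over all score thresholds).

#' Binarise a probability map
#'
#' Pixels strictly exceeding the threshold become 1, the rest 0.
#'
#' @param prob Numeric array of vessel probabilities in `[0, 1]`.
#' @param threshold Decision threshold in `(0, 1)` (default 0.5).
#' @return Integer array of the same shape with values in `{0, 1}`.
#' @export
binarize <- function(prob, threshold = 0.5) {
  out <- array(as.integer(prob > threshold), dim = dim(prob) %||%
                 length(prob))
  out
}

#' Pixel confusion counts
#'
#' @param pred,truth Binary masks (same shape), vessel = 1.
#' @param domain Optional logical/binary mask restricting the evaluation
#'   domain (e.g. the field of view); `NULL` evaluates every pixel.
#' @return Object of class `confusion_counts`: list with `tp`, `fp`, `tn`,
#'   `fn` and `n`.
#' @examples
#' confusion_counts(c(1, 0, 1, 1), c(1, 1, 0, 1))
#' @export
confusion_counts <- function(pred, truth, domain = NULL) {
  if (!identical(as.integer(dim(pred) %||% length(pred)),
                 as.integer(dim(truth) %||% length(truth))))
    stop("pred and truth dimensions differ")
  p <- as.vector(pred) > 0
  y <- as.vector(truth) > 0
  if (!is.null(domain)) {
    keep <- as.vector(domain) > 0
    p <- p[keep]
    y <- y[keep]
  }
  out <- list(tp = sum(p & y), fp = sum(p & !y),
              tn = sum(!p & !y), fn = sum(!p & y))
  out$n <- out$tp + out$fp + out$tn + out$fn
  class(out) <- "confusion_counts"
  out
}

#' Segmentation metrics from confusion counts
#'
#' Accuracy `(TP+TN)/N`, Dice `2TP/(2TP+FP+FN)`, sensitivity `TP/(TP+FN)`
#' and specificity `TN/(TN+FP)`. Zero denominators yield 0 and set the
#' `degenerate` flag.
#'
#' @param counts A [confusion_counts()] object.
#' @return List with `acc`, `dsc`, `se`, `sp` and a `degenerate` flag.
#' @export
compute_metrics <- function(counts) {
  stopifnot(inherits(counts, "confusion_counts"))
  if (counts$n == 0) stop("no pixels in the evaluation domain")
  safe <- function(num, den) if (den == 0) 0 else num / den
  degen <- (counts$tp + counts$fn) == 0 || (counts$tn + counts$fp) == 0 ||
    (2 * counts$tp + counts$fp + counts$fn) == 0
  list(acc = (counts$tp + counts$tn) / counts$n,
       dsc = safe(2 * counts$tp, 2 * counts$tp + counts$fp + counts$fn),
       se = safe(counts$tp, counts$tp + counts$fn),
       sp = safe(counts$tn, counts$tn + counts$fp),
       degenerate = degen)
}

#' Area under the ROC curve
#'
#' Rank (Mann-Whitney) form of the AUC: the probability that a randomly
#' chosen vessel pixel outscores a randomly chosen background pixel, ties
#' counted one half. Identical to the trapezoidal area under the ROC over all
#' distinct score thresholds.
#'
#' @param prob Numeric scores (any strictly monotone transform of vessel
#'   probability gives the same value).
#' @param truth Binary ground truth, same shape.
#' @param domain Optional evaluation-domain mask.
#' @return AUC in `[0, 1]`; `NA` with a warning if the truth is single-class.
#' @export
roc_auc <- function(prob, truth, domain = NULL) {
  s <- as.vector(prob)
  y <- as.vector(truth) > 0
  if (!is.null(domain)) {
    keep <- as.vector(domain) > 0
    s <- s[keep]
    y <- y[keep]
  }
  n1 <- as.numeric(sum(y))
  n0 <- as.numeric(sum(!y))
  if (n1 == 0 || n0 == 0) {
    warning("truth contains a single class; AUC undefined")
    return(NA_real_)
  }
  r <- rank(s, ties.method = "average")
  (sum(r[y]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Full metrics report for one probability map
#'
#' @param prob Probability map.
#' @param truth Binary ground-truth mask.
#' @param threshold Binarisation threshold.
#' @param domain Optional evaluation-domain mask (`NULL` = full image).
#' @return List with the five metrics (`acc`, `dsc`, `se`, `sp`, `auc`), the
#'   confusion counts, the threshold, and the evaluation domain used.
#' @export
segmentation_metrics <- function(prob, truth, threshold = 0.5,
                                 domain = NULL) {
  counts <- confusion_counts(binarize(prob, threshold), truth, domain)
  m <- compute_metrics(counts)
  m$auc <- suppressWarnings(roc_auc(prob, truth, domain))
  m$counts <- counts
  m$threshold <- threshold
  m$domain <- if (is.null(domain)) "full" else "restricted"
  m
}
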
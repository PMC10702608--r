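# Segmentation losses: binary cross-entropy, soft Dice, and the
# deep-supervision aggregate used by the multi-branch head. All three accept
# plain numeric arrays (returning a number) or autodiff nodes (returning a
# node), so the same code serves evaluation and training.

as_ad <- function(x) if (inherits(x, "ad_node")) x else ad_const(x)

unwrap <- function(node, was_node) if (was_node) node else node$value

check_same_shape <- function(p, y) {
  dp <- dim(p) %||% length(p)
  dy <- dim(y) %||% length(y)
  if (!identical(as.integer(dp), as.integer(dy)))
    stop("prediction and ground truth shapes differ")
}

#' Binary cross-entropy loss
#'
#' Mean negative log-likelihood of the ground truth under the predicted
#' vessel probabilities, with probabilities clipped to `[eps, 1 - eps]` so
#' the loss and its gradient stay finite at 0 and 1. The two-class
#' cross-entropy collapses to this binary form for a single-channel
#' (foreground) probability map.
#'
#' @param p Predicted probabilities in `[0, 1]` (array or autodiff node).
#' @param y Ground-truth labels in `{0, 1}`, same shape.
#' @param eps Clipping constant.
#' @return Non-negative scalar (or scalar node).
#' @examples
#' bce_loss(rep(0.5, 4), rep(1, 4)) # log(2)
#' @export
bce_loss <- function(p, y, eps = 1e-7) {
  was <- inherits(p, "ad_node")
  yv <- if (inherits(y, "ad_node")) y$value else y
  pv <- if (was) p$value else p
  check_same_shape(pv, yv)
  unwrap(ad_bce(as_ad(p), yv, eps), was)
}

#' Soft Dice loss
#'
#' `1 - (2 * sum(y p) + s) / (sum(y^2 + p^2) + s)` over the foreground
#' channel; zero when the prediction equals a binary ground truth, bounded in
#' `[0, 1]`. The smoothing constant `s` keeps empty masks well-defined.
#'
#' @inheritParams bce_loss
#' @param smooth Smoothing constant (default 1).
#' @return Scalar in `[0, 1]` (or scalar node).
#' @examples
#' dice_loss(rep(0, 4), rep(1, 4)) # (1 - 1/5) = 0.8
#' @export
dice_loss <- function(p, y, smooth = 1) {
  was <- inherits(p, "ad_node")
  yv <- if (inherits(y, "ad_node")) y$value else y
  pv <- if (was) p$value else p
  check_same_shape(pv, yv)
  unwrap(ad_dice(as_ad(p), yv, smooth), was)
}

#' Deep-supervision loss for the multi-branch head
#'
#' Total loss `bce(branch1) + dice(branch2) + [bce(fusion) + dice(fusion)]`,
#' every branch supervised by the same ground truth. With the multi-branch
#' head disabled (only a `fusion` output present) this reduces to the mixed
#' `bce + dice` loss on the single output.
#'
#' @param outs Named list of branch logits (`branch1`, `branch2`, `fusion`,
#'   or `fusion` alone), as arrays or autodiff nodes.
#' @param y Ground-truth mask, same shape as each output.
#' @param weights Length-3 weights for the branch1 / branch2 / fusion terms.
#' @param eps,smooth Passed to [bce_loss()] and [dice_loss()].
#' @return Scalar total loss (or scalar node).
#' @export
deep_supervision_loss <- function(outs, y, weights = c(1, 1, 1),
                                  eps = 1e-7, smooth = 1) {
  if (is.null(outs$fusion)) stop("missing fusion branch output")
  was <- inherits(outs$fusion, "ad_node")
  sig <- function(o) ad_sigmoid(as_ad(o))
  yv <- if (inherits(y, "ad_node")) y$value else y
  pf <- sig(outs$fusion)
  total <- ad_smul(ad_add(ad_bce(pf, yv, eps), ad_dice(pf, yv, smooth)),
                   weights[3])
  if (!is.null(outs$branch1) || !is.null(outs$branch2)) {
    if (is.null(outs$branch1) || is.null(outs$branch2))
      stop("missing branch output")
    total <- ad_add(total,
                    ad_add(ad_smul(ad_bce(sig(outs$branch1), yv, eps),
                                   weights[1]),
                           ad_smul(ad_dice(sig(outs$branch2), yv, smooth),
                                   weights[2])))
  }
  unwrap(total, was)
}
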
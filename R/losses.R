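#' Weights of the joint segmentation loss
#'
#' The network is optimized with `L = w1 * L_Dice + w2 * L_CE`. The default
#' weighting (0.8, 0.2) favors the overlap term, which produces smoother
#' FAZ boundaries, while the cross-entropy term keeps per-pixel
#' classification sharp.
#'
#' @param w1 Dice-loss weight (>= 0).
#' @param w2 cross-entropy weight (>= 0); `w1 + w2` must be positive.
#' @return an object of class `loss_weights`.
#' @export
loss_weights <- function(w1 = 0.8, w2 = 0.2) {
  if (!is.numeric(w1) || !is.numeric(w2) || is.na(w1) || is.na(w2) ||
      w1 < 0 || w2 < 0)
    stop("configuration error: loss weights must be nonnegative numbers")
  if (w1 + w2 <= 0) stop("configuration error: w1 + w2 must be positive")
  structure(list(w1 = w1, w2 = w2), class = "loss_weights")
}

# Accepts either the positive-class probability directly (matrix or
# (N, H, W) array) or the full softmax output (N, K, H, W); returns a list
# of per-image probability matrices.
pos_prob_list <- function(probabilities) {
  d <- dim(probabilities)
  if (is.matrix(probabilities)) return(list(probabilities))
  if (length(d) == 3L)
    return(lapply(seq_len(d[1]), function(n)
      matrix(probabilities[n, , ], d[2], d[3])))
  if (length(d) == 4L)
    return(lapply(seq_len(d[1]), function(n)
      matrix(probabilities[n, 2, , ], d[3], d[4])))
  stop("probabilities must be a matrix or a 3-D/4-D array")
}

mask_list <- function(truth) {
  if (is.matrix(truth)) return(list(truth))
  d <- dim(truth)
  if (length(d) == 3L)
    return(lapply(seq_len(d[1]), function(n) matrix(truth[n, , ], d[2], d[3])))
  stop("truth must be a matrix or an (N, H, W) array")
}

check_pair <- function(p, y) {
  if (!identical(dim(p), dim(y)))
    stop("shape mismatch: probabilities are ", paste(dim(p), collapse = "x"),
         " but truth is ", paste(dim(y), collapse = "x"))
  if (!all(y %in% c(0, 1))) stop("truth labels must be 0 or 1")
}

#' Binary cross-entropy loss
#'
#' Mean over pixels (and images) of `-[y log p + (1-y) log(1-p)]`, where `p`
#' is the predicted FAZ-class probability. Probabilities are clamped to
#' `[eps, 1-eps]` so the value stays finite at hard 0/1 predictions.
#'
#' @param probabilities FAZ-class probabilities: a matrix, an (N, H, W)
#'   array, or a full (N, K, H, W) softmax output (class 2 = FAZ is used).
#' @param truth binary ground-truth mask(s), matching spatial shape.
#' @param eps clamping constant (default 1e-7).
#' @return nonnegative scalar.
#' @examples
#' ce_loss(matrix(0.5, 2, 2), matrix(c(0, 1, 0, 1), 2, 2))  # log(2)
#' @export
ce_loss <- function(probabilities, truth, eps = 1e-7) {
  ps <- pos_prob_list(probabilities)
  ys <- mask_list(truth)
  if (length(ps) != length(ys)) stop("batch size mismatch")
  tot <- 0; npx <- 0
  for (n in seq_along(ps)) {
    p <- ps[[n]]; y <- ys[[n]]
    check_pair(p, y)
    p <- pmin(pmax(p, eps), 1 - eps)
    tot <- tot + sum(-(y * log(p) + (1 - y) * log(1 - p)))
    npx <- npx + length(p)
  }
  tot / npx
}

#' Soft Dice loss
#'
#' `1 - (2 * sum(p*y) + s) / (sum(p) + sum(y) + s)` per image, averaged over
#' the batch; `s` is a smoothing constant that keeps the loss defined (and
#' near 0) when both prediction and truth are empty. With hard masks and
#' `smooth = 0` this equals one minus the Dice coefficient.
#'
#' @inheritParams ce_loss
#' @param smooth smoothing constant `s` (default 1; use 0 for the exact
#'   set form).
#' @return value in `[0, 1)` for `smooth > 0`.
#' @export
dice_loss <- function(probabilities, truth, smooth = 1) {
  ps <- pos_prob_list(probabilities)
  ys <- mask_list(truth)
  if (length(ps) != length(ys)) stop("batch size mismatch")
  val <- vapply(seq_along(ps), function(n) {
    p <- ps[[n]]; y <- ys[[n]]
    check_pair(p, y)
    1 - (2 * sum(p * y) + smooth) / (sum(p) + sum(y) + smooth)
  }, numeric(1))
  mean(val)
}

#' Joint Dice + cross-entropy loss
#'
#' `w1 * dice_loss + w2 * ce_loss`, the training objective.
#'
#' @inheritParams ce_loss
#' @param weights a [loss_weights()] object (default 0.8 / 0.2).
#' @param smooth Dice smoothing constant.
#' @return scalar loss.
#' @export
joint_loss <- function(probabilities, truth, weights = loss_weights(),
                       smooth = 1, eps = 1e-7) {
  if (!inherits(weights, "loss_weights")) weights <- do.call(loss_weights, as.list(weights))
  weights$w1 * dice_loss(probabilities, truth, smooth) +
    weights$w2 * ce_loss(probabilities, truth, eps)
}

#' Analytic gradient of the joint loss w.r.t. the probability map
#'
#' Gradient of [joint_loss()] with respect to each entry of a single-image
#' FAZ-probability matrix, used for finite-difference verification.
#'
#' @param p FAZ-class probability matrix for one image.
#' @param truth binary mask matrix.
#' @param weights a [loss_weights()] object.
#' @param smooth Dice smoothing constant.
#' @param eps CE clamping constant.
#' @return matrix of partial derivatives, same shape as `p`.
#' @export
joint_loss_grad <- function(p, truth, weights = loss_weights(), smooth = 1,
                            eps = 1e-7) {
  stopifnot(is.matrix(p))
  check_pair(p, truth)
  n <- length(p)
  pc <- pmin(pmax(p, eps), 1 - eps)
  g_ce <- (-(truth / pc) + (1 - truth) / (1 - pc)) / n
  S <- sum(p) + sum(truth) + smooth
  I2 <- 2 * sum(p * truth) + smooth
  g_dice <- -(2 * truth * S - I2) / S^2
  weights$w1 * g_dice + weights$w2 * g_ce
}
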
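#' Loss configuration for the combined training objective
#'
#' @param lambda mixing weight in `[0, 1]`: `lambda * BCE + (1 - lambda) *
#'   Dice loss`. Default 0.5.
#' @param eps smoothing constant of the soft Dice term (> 0).
#' @param clip probability clamp applied inside the BCE for numerical
#'   stability.
#' @return an object of class `loss_config`.
#' @export
loss_config <- function(lambda = 0.5, eps = 1e-6, clip = 1e-7) {
  if (lambda < 0 || lambda > 1) stop("lambda must lie in [0, 1]")
  stopifnot(eps > 0, clip > 0)
  structure(list(lambda = lambda, eps = eps, clip = clip),
            class = "loss_config")
}

check_same_shape <- function(pred, target) {
  if (!identical(dim1(pred), dim1(target))) {
    stop("pred and target shapes disagree")
  }
}

dim1 <- function(x) if (is.null(dim(x))) length(x) else dim(x)

#' Binary cross-entropy loss
#'
#' Mean over all elements of `-(y log p + (1 - y) log(1 - p))`, with
#' probabilities clamped to `[clip, 1 - clip]`.
#'
#' @param pred probabilities in `(0, 1)` (any array shape).
#' @param target binary targets of the same shape.
#' @param clip clamp constant.
#' @return non-negative scalar.
#' @export
bce_loss <- function(pred, target, clip = 1e-7) {
  check_same_shape(pred, target)
  p <- pmin(pmax(pred, clip), 1 - clip)
  -mean(target * log(p) + (1 - target) * log(1 - p))
}

# gradient of bce_loss w.r.t. pred (same clamping convention)
bce_grad <- function(pred, target, clip = 1e-7) {
  p <- pmin(pmax(pred, clip), 1 - clip)
  (-(target / p) + (1 - target) / (1 - p)) / length(pred)
}

#' Soft Dice loss
#'
#' One minus the smoothed Dice coefficient
#' `(2 * sum(p * y) + eps) / (sum(p) + sum(y) + eps)` computed on raw
#' probabilities without thresholding.
#'
#' @param pred probabilities in `[0, 1]`.
#' @param target binary targets of the same shape.
#' @param eps smoothing constant.
#' @return scalar in `[0, 1]`.
#' @export
dice_loss <- function(pred, target, eps = 1e-6) {
  check_same_shape(pred, target)
  1 - (2 * sum(pred * target) + eps) / (sum(pred) + sum(target) + eps)
}

dice_loss_grad <- function(pred, target, eps = 1e-6) {
  den <- sum(pred) + sum(target) + eps
  num <- 2 * sum(pred * target) + eps
  -(2 * target * den - num) / den^2
}

#' Combined BCE + Dice objective
#'
#' `lambda * BCE + (1 - lambda) * soft Dice loss`; linear in `lambda`
#' between its endpoint values.
#'
#' @param pred probabilities.
#' @param target binary targets of the same shape.
#' @param cfg a [loss_config()].
#' @return scalar loss.
#' @export
combined_loss <- function(pred, target, cfg = loss_config()) {
  stopifnot(inherits(cfg, "loss_config"))
  cfg$lambda * bce_loss(pred, target, cfg$clip) +
    (1 - cfg$lambda) * dice_loss(pred, target, cfg$eps)
}

combined_loss_grad <- function(pred, target, cfg = loss_config()) {
  cfg$lambda * bce_grad(pred, target, cfg$clip) +
    (1 - cfg$lambda) * dice_loss_grad(pred, target, cfg$eps)
}
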
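#' Parameters of the cascaded channel-spatial attention block
#'
#' The block recalibrates channels with a squeeze-excitation bottleneck
#' (global average pooling, a two-layer fully connected bottleneck with
#' reduction ratio `r`, sigmoid gates) and then gates pixels with a spatial
#' saliency map (channelwise mean and max maps, concatenated and passed
#' through a 7 x 7 convolution and a sigmoid). No bias terms are used
#' anywhere, so the weight count is exactly `2 C^2 / r + 98`.
#'
#' @param channels number of feature channels `C` (>= 1).
#' @param reduction channel reduction ratio `r`; must divide `channels`.
#' @param init `"he"` for Kaiming-normal initialization, `"zero"` for
#'   all-zero weights (both gates then equal 0.5 everywhere).
#' @param rng generator for random initialization (required for `"he"`).
#' @return an object of class `attention_params` with fields `W1`
#'   (`C/r x C`), `W2` (`C x C/r`), `spatial_kernel` (`7 x 7 x 2`) and `r`.
#' @export
attention_params <- function(channels, reduction = 16, init = c("he", "zero"),
                             rng = NULL) {
  init <- match.arg(init)
  channels <- as.integer(channels)
  reduction <- as.integer(reduction)
  if (channels < 1) stop("channels must be >= 1")
  if (channels %% reduction != 0) {
    stop(sprintf("reduction ratio %d does not divide channel count %d",
                 reduction, channels))
  }
  cr <- channels %/% reduction
  if (init == "zero") {
    w1 <- matrix(0, cr, channels)
    w2 <- matrix(0, channels, cr)
    sk <- array(0, c(7, 7, 2))
  } else {
    if (is.null(rng)) stop("rng required for random initialization")
    w1 <- matrix(with_rng(rng, rnorm(cr * channels, 0, sqrt(2 / channels))),
                 cr, channels)
    w2 <- matrix(with_rng(rng, rnorm(channels * cr, 0, sqrt(2 / cr))),
                 channels, cr)
    sk <- array(with_rng(rng, rnorm(98, 0, sqrt(2 / 98))), c(7, 7, 2))
  }
  structure(list(W1 = w1, W2 = w2, spatial_kernel = sk, r = reduction),
            class = "attention_params")
}

#' Channel attention: squeeze-excitation recalibration
#'
#' Global average pooling yields the channel descriptor `z`; the gate vector
#' is `s = sigmoid(W2 %*% relu(W1 %*% z))` and every channel is scaled by its
#' gate.
#'
#' @param f `H x W x C` feature array.
#' @param params an [attention_params()] with matching `C`.
#' @return list with `s` (the C gates, each in `(0, 1)`) and `out`
#'   (`H x W x C`, `out[i,j,c] = s[c] * f[i,j,c]`).
#' @export
channel_attention <- function(f, params) {
  d <- dim(f)
  stopifnot(length(d) == 3, ncol(params$W1) == d[3])
  hw <- d[1] * d[2]
  fm <- matrix(f, hw, d[3])
  z <- colMeans(fm)
  h1 <- pmax(as.vector(params$W1 %*% z), 0)
  s <- 1 / (1 + exp(-as.vector(params$W2 %*% h1)))
  out <- fm * rep(s, each = hw)
  list(s = s, out = array(out, d))
}

#' Spatial attention: channel-pooled saliency gating
#'
#' Mean and max maps along the channel dimension are concatenated and passed
#' through a bias-free 7 x 7 convolution (zero padding 3, same-size output)
#' and a sigmoid; every channel is then scaled pixelwise by the resulting
#' map.
#'
#' @param f `H x W x C` feature array (typically the channel-attention
#'   output).
#' @param params an [attention_params()].
#' @return list with `P` (`H x W` map, values in `(0, 1)`) and `out`
#'   (`H x W x C`).
#' @export
spatial_attention <- function(f, params) {
  d <- dim(f)
  stopifnot(length(d) == 3)
  hw <- d[1] * d[2]
  fm <- matrix(f, hw, d[3])
  a <- rowMeans(fm)
  m <- fm[, 1]
  if (d[3] > 1) for (cc in 2:d[3]) m <- pmax(m, fm[, cc])
  am <- array(c(a, m), c(d[1], d[2], 2))
  cols <- im2col_cpp(am, 7L, 3L)
  q <- as.vector(cols %*% as.vector(params$spatial_kernel))
  p <- 1 / (1 + exp(-q))
  out <- fm * p
  list(P = matrix(p, d[1], d[2]), out = array(out, d))
}

#' Cascaded channel-then-spatial attention block
#'
#' Applies [channel_attention()] followed by [spatial_attention()]; the
#' output has the shape of the input and is elementwise bounded by it in
#' magnitude (both gates lie strictly inside `(0, 1)`).
#'
#' @inheritParams channel_attention
#' @return `H x W x C` gated feature array.
#' @export
#' @examples
#' r <- rng_new(1)
#' p <- attention_params(16, reduction = 4, rng = r)
#' f <- array(runif(8 * 8 * 16), c(8, 8, 16))
#' g <- attention_block(f, p)
#' all(abs(g) <= abs(f))
attention_block <- function(f, params) {
  ca <- channel_attention(f, params)
  spatial_attention(ca$out, params)$out
}

#' Count the learnable weights of an attention block
#'
#' @param params an [attention_params()].
#' @return named list: `channel` (the two bottleneck matrices), `spatial`
#'   (the 7 x 7 x 2 kernel, always 98), `total`, and `closed_form`
#'   (`2 C^2 / r + 98`) for cross-checking.
#' @export
attention_weight_count <- function(params) {
  ch <- length(params$W1) + length(params$W2)
  sp <- length(params$spatial_kernel)
  cc <- ncol(params$W1)
  list(channel = ch, spatial = sp, total = ch + sp,
       closed_form = 2 * cc^2 / params$r + 98)
}

#' Registry of attention modules sharing one call contract
#'
#' Each entry provides `make(channels, reduction, rng)` returning a parameter
#' object and `apply(f, params)` returning the gated feature map. Available
#' modules: `"channel_spatial"` (the cascaded block of this package, the
#' default), `"se"` (channel recalibration only) and `"none"` (identity).
#'
#' @return named list of module entries.
#' @export
attention_modules <- function() {
  list(
    channel_spatial = list(
      make = function(channels, reduction, rng)
        attention_params(channels, reduction, rng = rng),
      apply = function(f, params) attention_block(f, params)
    ),
    se = list(
      make = function(channels, reduction, rng) {
        p <- attention_params(channels, reduction, rng = rng)
        p$spatial_kernel <- NULL
        p
      },
      apply = function(f, params) channel_attention(f, params)$out
    ),
    none = list(
      make = function(channels, reduction, rng) NULL,
      apply = function(f, params) f
    )
  )
}
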
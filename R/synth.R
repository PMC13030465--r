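#' Configuration for the synthetic tissue generator
#'
#' Describes one synthetic cross-section image of bamboo culm tissue:
#' densely packed polygonal parenchyma cells, a fraction of larger
#' vessel-like cells, thin shared walls, local overexposure blobs, and
#' acquisition-style noise and blur.
#'
#' @param height,width canvas size in pixels (>= 32).
#' @param n_cells number of cell instances (>= 1).
#' @param vessel_fraction proportion of cells rendered as large-lumen
#'   vessel cells (class 2); the rest are parenchyma (class 1).
#' @param wall_width width in pixels of the wall band separating adjacent
#'   cells (>= 1).
#' @param overexposure_blobs number of elliptical saturated regions.
#' @param noise_sigma standard deviation of additive Gaussian intensity noise.
#' @param blur_sigma Gaussian blur sigma in pixels (0 disables).
#' @param seed integer seed; the generator is fully deterministic given the
#'   configuration.
#' @return an object of class `synth_config`.
#' @export
synth_config <- function(height = 256, width = 256, n_cells = 150,
                         vessel_fraction = 0.05, wall_width = 2,
                         overexposure_blobs = 2, noise_sigma = 0.02,
                         blur_sigma = 0.5, seed = 1) {
  stopifnot(height >= 32, width >= 32, n_cells >= 1,
            vessel_fraction >= 0, vessel_fraction <= 1,
            wall_width >= 1, overexposure_blobs >= 0,
            noise_sigma >= 0, blur_sigma >= 0)
  cfg <- list(height = as.integer(height), width = as.integer(width),
              n_cells = as.integer(n_cells),
              vessel_fraction = vessel_fraction,
              wall_width = wall_width,
              overexposure_blobs = as.integer(overexposure_blobs),
              noise_sigma = noise_sigma, blur_sigma = blur_sigma,
              seed = as.integer(seed))
  class(cfg) <- "synth_config"
  cfg
}

#' Construct and validate an image sample
#'
#' The unit of all pipelines: an RGB image in `[0, 1]`, a per-pixel class
#' mask (0 = background/wall, 1 = parenchyma, 2 = vascular/vessel), and an
#' instance label map with consecutive labels `1..K` (0 = background/wall).
#'
#' @param image `H x W x 3` numeric array in `[0, 1]`.
#' @param class_mask `H x W` integer matrix with values in `{0, 1, 2}`.
#' @param instance_map `H x W` non-negative integer matrix.
#' @param meta provenance list (seed, configuration, parent image, ...).
#' @return an object of class `image_sample`.
#' @export
image_sample <- function(image, class_mask, instance_map, meta = list()) {
  stopifnot(length(dim(image)) == 3, dim(image)[3] == 3,
            is.matrix(class_mask), is.matrix(instance_map))
  if (!all(dim(image)[1:2] == dim(class_mask)) ||
      !all(dim(class_mask) == dim(instance_map))) {
    stop("image, class_mask and instance_map shapes disagree")
  }
  if (min(image) < 0 || max(image) > 1) stop("image values must lie in [0, 1]")
  if (!all(class_mask %in% 0:2)) stop("class_mask values must be in {0, 1, 2}")
  if (any(instance_map < 0)) stop("instance_map must be non-negative")
  if (any(instance_map > 0 & class_mask == 0)) {
    stop("instance pixels must carry a positive class")
  }
  pos <- sort(unique(instance_map[instance_map > 0]))
  if (length(pos) && !identical(as.integer(pos), seq_along(pos))) {
    stop("instance labels must be consecutive 1..K")
  }
  structure(list(image = image,
                 class_mask = matrix(as.integer(class_mask), nrow(class_mask)),
                 instance_map = matrix(as.integer(instance_map), nrow(instance_map)),
                 meta = meta),
            class = "image_sample")
}

#' @export
print.image_sample <- function(x, ...) {
  k <- max(x$instance_map)
  cat(sprintf("<image_sample> %d x %d, %d instances, classes: %s\n",
              nrow(x$class_mask), ncol(x$class_mask), k,
              paste(sort(unique(as.vector(x$class_mask))), collapse = ",")))
  invisible(x)
}

# Dart-throwing site sampler with minimum separation; errors out when the
# canvas cannot host n sites at the required spacing instead of silently
# dropping cells.
sample_sites <- function(h, w, n, min_sep, rng) {
  sy <- numeric(n)
  sx <- numeric(n)
  placed <- 0L
  tries <- 0L
  max_tries <- 300L * n
  while (placed < n) {
    if (tries >= max_tries) {
      stop(sprintf(paste0("cannot place %d cells on a %d x %d canvas with ",
                          "minimum site separation %.1f px; reduce n_cells ",
                          "or wall_width"), n, h, w, min_sep))
    }
    tries <- tries + 1L
    cand <- with_rng(rng, runif(2))
    cy <- 1 + cand[1] * (h - 1)
    cx <- 1 + cand[2] * (w - 1)
    if (placed > 0L) {
      d2 <- (sy[seq_len(placed)] - cy)^2 + (sx[seq_len(placed)] - cx)^2
      if (min(d2) < min_sep^2) next
    }
    placed <- placed + 1L
    sy[placed] <- cy
    sx[placed] <- cx
  }
  cbind(y = sy, x = sx)
}

# Chebyshev dilation of a logical matrix by 1 pixel.
dilate1 <- function(m) {
  h <- nrow(m); w <- ncol(m)
  p <- matrix(FALSE, h + 2, w + 2)
  p[2:(h + 1), 2:(w + 1)] <- m
  out <- matrix(FALSE, h, w)
  for (di in -1:1) for (dj in -1:1) {
    out <- out | p[(2 + di):(h + 1 + di), (2 + dj):(w + 1 + dj)]
  }
  out
}

#' Generate a synthetic bamboo-tissue image with exact ground truth
#'
#' Tessellates the canvas by a seeded Voronoi partition of uniformly sampled
#' sites; pixels whose two nearest sites are nearly equidistant form the
#' shared cell walls, the remaining pixels take the label of their nearest
#' site. The largest cells are re-rendered as vessel cells (class 2) with
#' lumens dilated by 2 px into the surrounding wall. Overexposure blobs
#' saturate the image to 1.0 inside random ellipses; Gaussian blur and noise
#' emulate acquisition artifacts.
#'
#' @param config a [synth_config()].
#' @return an [image_sample()] with exact instance, class and wall ground
#'   truth. Deterministic given the configuration (including its seed).
#' @export
#' @examples
#' s <- generate_tissue(synth_config(64, 64, n_cells = 8, seed = 3))
#' max(s$instance_map)
generate_tissue <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  h <- config$height; w <- config$width; n <- config$n_cells
  rng <- rng_new(config$seed)

  min_sep <- max(0.55 * sqrt(h * w / n), 2 * config$wall_width + 3)
  sites <- sample_sites(h, w, n, min_sep, rng)

  gi <- rep(seq_len(h), times = w)
  gj <- rep(seq_len(w), each = h)
  d1 <- rep(Inf, h * w)
  d2 <- rep(Inf, h * w)
  near <- integer(h * w)
  for (s in seq_len(n)) {
    ds <- (gi - sites[s, "y"])^2 + (gj - sites[s, "x"])^2
    closer1 <- ds < d1
    d2 <- pmin(d2, ifelse(closer1, d1, ds))
    d1[closer1] <- ds[closer1]
    near[closer1] <- s
  }
  wall <- (sqrt(d2) - sqrt(d1)) <= config$wall_width
  inst <- near
  inst[wall] <- 0L
  inst <- matrix(as.integer(inst), h, w)

  areas <- tabulate(inst[inst > 0], nbins = n)
  if (any(areas == 0)) {
    stop("degenerate tessellation: some cells have no interior pixels; ",
         "reduce n_cells or wall_width")
  }

  n_vessels <- round(config$vessel_fraction * n)
  vessel_ids <- if (n_vessels > 0) order(areas, decreasing = TRUE)[seq_len(n_vessels)] else integer(0)

  # vessels are drawn larger: dilate their lumens 2 px into the wall, never
  # into or against another instance (walls must keep instances separated)
  for (iter in 1:2) {
    for (v in vessel_ids) {
      mv <- inst == v
      others <- inst > 0 & inst != v
      cand <- dilate1(mv) & inst == 0L & !dilate1(others)
      inst[cand] <- as.integer(v)
    }
  }

  class_mask <- matrix(0L, h, w)
  class_mask[inst > 0] <- 1L
  class_mask[inst %in% vessel_ids & inst > 0] <- 2L

  # render: bright walls, mid-gray parenchyma lumens with per-cell jitter,
  # dark vessel lumens; base intensities bounded strictly below 1
  cell_jit <- with_rng(rng, runif(n, -0.08, 0.08))
  base <- matrix(0.82, h, w)
  lum <- ifelse(class_mask == 2L, 0.22, 0.48)
  pos <- inst > 0
  base[pos] <- lum[pos] + cell_jit[inst[pos]]
  tex <- with_rng(rng, runif(h * w, -0.03, 0.03))
  base[pos] <- base[pos] + tex[which(pos)]
  tint <- c(1, 0.97, 0.92)
  img <- array(0, c(h, w, 3))
  for (ch in 1:3) img[, , ch] <- base * tint[ch]

  if (config$blur_sigma > 0) {
    for (ch in 1:3) {
      img[, , ch] <- as.matrix(EBImage::imageData(
        EBImage::gblur(img[, , ch], sigma = config$blur_sigma)))
    }
  }

  if (config$overexposure_blobs > 0) {
    for (b in seq_len(config$overexposure_blobs)) {
      prm <- with_rng(rng, runif(5))
      cy <- 1 + prm[1] * (h - 1)
      cx <- 1 + prm[2] * (w - 1)
      a <- (0.03 + 0.07 * prm[3]) * min(h, w)
      bb <- (0.03 + 0.07 * prm[4]) * min(h, w)
      th <- prm[5] * pi
      dy <- gi - cy; dx <- gj - cx
      u <- dy * cos(th) + dx * sin(th)
      v <- -dy * sin(th) + dx * cos(th)
      inside <- (u / a)^2 + (v / bb)^2 <= 1
      for (ch in 1:3) {
        plane <- img[, , ch]
        plane[inside] <- 1.0
        img[, , ch] <- plane
      }
    }
  }

  if (config$noise_sigma > 0) {
    img <- img + array(with_rng(rng, rnorm(h * w * 3, 0, config$noise_sigma)),
                       c(h, w, 3))
  }
  img[img < 0] <- 0
  img[img > 1] <- 1

  image_sample(img, class_mask, inst,
               meta = list(seed = config$seed, config = unclass(config),
                           generator = "voronoi"))
}

#' Derive training targets from instance ground truth
#'
#' A pixel of an instance is boundary when any pixel within `boundary_width`
#' in Chebyshev (8-neighbor) distance belongs to a different instance or to
#' the background; pixels beyond the image border count as background.
#' The interior is each instance eroded by the same band, so
#' `interior = instance - boundary` holds exactly. The class mask is one-hot
#' encoded into three channels.
#'
#' @param x an [image_sample()], or an instance label matrix.
#' @param class_mask required when `x` is a bare matrix.
#' @param boundary_width band half-width in pixels (>= 1).
#' @return an object of class `training_targets` with fields `onehot`
#'   (`H x W x 3`), `boundary` and `interior` (binary `H x W` matrices).
#' @export
derive_targets <- function(x, class_mask = NULL, boundary_width = 1) {
  if (inherits(x, "image_sample")) {
    inst <- x$instance_map
    class_mask <- x$class_mask
  } else {
    inst <- x
    if (is.null(class_mask)) stop("class_mask required")
  }
  stopifnot(boundary_width >= 1)
  wdt <- as.integer(boundary_width)
  h <- nrow(inst); w <- ncol(inst)
  pad <- matrix(0L, h + 2 * wdt, w + 2 * wdt)
  pad[(wdt + 1):(wdt + h), (wdt + 1):(wdt + w)] <- inst
  bnd <- matrix(FALSE, h, w)
  for (di in -wdt:wdt) {
    for (dj in -wdt:wdt) {
      if (di == 0 && dj == 0) next
      nb <- pad[(wdt + 1 + di):(wdt + h + di), (wdt + 1 + dj):(wdt + w + dj)]
      bnd <- bnd | (inst > 0L & nb != inst)
    }
  }
  interior <- inst > 0L & !bnd
  structure(list(onehot = one_hot(class_mask, 3L),
                 boundary = matrix(as.numeric(bnd), h, w),
                 interior = matrix(as.numeric(interior), h, w)),
            class = "training_targets")
}

#' Build idealized probability maps from ground truth
#'
#' Produces the prediction triplet (semantic, boundary, interior probability
#' maps) a perfectly trained network would emit, with probability `p_hi` on
#' positive pixels and `p_lo` elsewhere. Used to exercise the instance
#' extraction and evaluation stages independently of training.
#'
#' @param sample an [image_sample()].
#' @param p_hi,p_lo probabilities assigned to positive / negative pixels.
#' @param boundary_width band width passed to [derive_targets()].
#' @return an object of class `predictions` with fields `semantic`
#'   (`H x W x 3`), `boundary` and `interior` (`H x W`).
#' @export
predictions_from_truth <- function(sample, p_hi = 0.95, p_lo = 0.05,
                                   boundary_width = 1) {
  stopifnot(inherits(sample, "image_sample"), p_hi > p_lo)
  tg <- derive_targets(sample, boundary_width = boundary_width)
  soften <- function(b) p_lo + (p_hi - p_lo) * b
  structure(list(semantic = soften(tg$onehot),
                 boundary = soften(tg$boundary),
                 interior = soften(tg$interior)),
            class = "predictions")
}
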
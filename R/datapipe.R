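#' Partition an image sample into a grid of patches
#'
#' Splits a sample into `rows x cols` equal, non-overlapping patches of size
#' `floor(H/rows) x floor(W/cols)`, anchored at the top-left corner; any
#' remainder rows/columns outside the largest divisible crop are dropped.
#' The class and instance maps are partitioned identically; instances cut by
#' patch borders are relabeled consecutively within each patch.
#'
#' @param sample an [image_sample()].
#' @param rows,cols grid dimensions (defaults 3 x 3).
#' @return a list of `rows * cols` [image_sample()] patches in row-major
#'   order; each patch's `meta` records its grid position and parent.
#' @export
partition_patches <- function(sample, rows = 3, cols = 3) {
  stopifnot(inherits(sample, "image_sample"))
  if (rows < 1 || cols < 1) stop("rows and cols must be >= 1")
  h <- nrow(sample$class_mask); w <- ncol(sample$class_mask)
  ph <- h %/% rows; pw <- w %/% cols
  if (ph < 1 || pw < 1) stop("image smaller than the requested grid")
  out <- vector("list", rows * cols)
  idx <- 1L
  for (r in seq_len(rows)) {
    for (cc in seq_len(cols)) {
      ri <- ((r - 1L) * ph + 1L):(r * ph)
      ci <- ((cc - 1L) * pw + 1L):(cc * pw)
      inst <- sample$instance_map[ri, ci, drop = FALSE]
      inst <- relabel_consecutive(inst)
      out[[idx]] <- image_sample(
        sample$image[ri, ci, , drop = FALSE],
        sample$class_mask[ri, ci, drop = FALSE],
        inst,
        meta = c(sample$meta, list(patch_row = r, patch_col = cc)))
      idx <- idx + 1L
    }
  }
  out
}

# Map positive labels to consecutive 1..K preserving numeric order.
relabel_consecutive <- function(m) {
  pos <- sort(unique(m[m > 0L]))
  if (!length(pos)) return(m)
  lut <- integer(max(pos))
  lut[pos] <- seq_along(pos)
  out <- m
  out[m > 0L] <- lut[m[m > 0L]]
  out
}

#' Reassemble grid patches into one image
#'
#' Inverse of [partition_patches()] on the cropped region: stitching the
#' patches back reproduces the top-left anchored crop bit-exactly for the
#' image and class mask (instance labels are per-patch and not merged).
#'
#' @param patches list returned by [partition_patches()].
#' @param rows,cols the grid used to create them.
#' @return a list with `image` and `class_mask` of the stitched crop.
#' @export
reassemble_patches <- function(patches, rows = 3, cols = 3) {
  stopifnot(length(patches) == rows * cols)
  ph <- nrow(patches[[1]]$class_mask); pw <- ncol(patches[[1]]$class_mask)
  img <- array(0, c(rows * ph, cols * pw, 3))
  cm <- matrix(0L, rows * ph, cols * pw)
  idx <- 1L
  for (r in seq_len(rows)) {
    for (cc in seq_len(cols)) {
      ri <- ((r - 1L) * ph + 1L):(r * ph)
      ci <- ((cc - 1L) * pw + 1L):(cc * pw)
      img[ri, ci, ] <- patches[[idx]]$image
      cm[ri, ci] <- patches[[idx]]$class_mask
      idx <- idx + 1L
    }
  }
  list(image = img, class_mask = cm)
}

#' Split ids into training and validation subsets
#'
#' Random split at `ratio` (train share), deterministic given the seed, with
#' optional stratification that keeps per-class counts as balanced as
#' possible across the two subsets.
#'
#' @param ids vector of sample identifiers.
#' @param ratio train proportion in `(0, 1]`; `|train| = round(ratio * n)`.
#' @param seed integer seed.
#' @param stratify_by optional vector of labels, parallel to `ids`.
#' @return an object of class `split_plan` with `train_ids`, `val_ids`,
#'   `ratio`, `seed` and a `folds` slot (`NULL` here; see [kfold_splits()]).
#' @export
split_dataset <- function(ids, ratio = 0.8, seed = 1, stratify_by = NULL) {
  n <- length(ids)
  if (n == 0) stop("empty id list")
  if (ratio <= 0 || ratio > 1) stop("ratio must lie in (0, 1]")
  rng <- rng_new(seed)
  n_train <- round(ratio * n)
  if (is.null(stratify_by)) {
    perm <- with_rng(rng, sample.int(n))
    train <- ids[perm[seq_len(n_train)]]
  } else {
    stopifnot(length(stratify_by) == n)
    lev <- unique(stratify_by)
    quota <- vapply(lev, function(l) ratio * sum(stratify_by == l), numeric(1))
    take <- floor(quota)
    rem <- n_train - sum(take)
    if (rem > 0) {
      ord <- order(quota - take, decreasing = TRUE)
      take[ord[seq_len(rem)]] <- take[ord[seq_len(rem)]] + 1
    } else if (rem < 0) {
      ord <- order(quota - take)
      k <- 0L
      for (i in ord) {
        if (k == -rem) break
        if (take[i] > 0) { take[i] <- take[i] - 1; k <- k + 1L }
      }
    }
    train <- unlist(lapply(seq_along(lev), function(i) {
      pool <- ids[stratify_by == lev[i]]
      perm <- with_rng(rng, sample.int(length(pool)))
      pool[perm[seq_len(take[i])]]
    }))
  }
  structure(list(train_ids = train, val_ids = setdiff(ids, train),
                 ratio = ratio, seed = as.integer(seed), folds = NULL),
            class = "split_plan")
}

#' K-fold cross-validation splitter
#'
#' Randomly partitions ids into `k` folds whose sizes differ by at most one;
#' each id appears in exactly one fold's validation set.
#'
#' @param ids vector of sample identifiers.
#' @param k number of folds (default 5).
#' @param seed integer seed.
#' @return a `split_plan` whose `folds` field is a list of `k` id vectors
#'   (the validation set of each fold); `train_ids`/`val_ids` give fold 1's
#'   split for convenience.
#' @export
kfold_splits <- function(ids, k = 5, seed = 1) {
  n <- length(ids)
  if (k < 2) stop("k must be >= 2")
  if (k > n) stop("k exceeds the number of ids")
  rng <- rng_new(seed)
  perm <- with_rng(rng, sample.int(n))
  sizes <- rep(n %/% k, k)
  extra <- n %% k
  if (extra > 0) sizes[seq_len(extra)] <- sizes[seq_len(extra)] + 1L
  ends <- cumsum(sizes)
  starts <- c(1L, head(ends, -1L) + 1L)
  folds <- lapply(seq_len(k), function(i) ids[perm[starts[i]:ends[i]]])
  structure(list(train_ids = setdiff(ids, folds[[1]]), val_ids = folds[[1]],
                 ratio = 1 - 1 / k, seed = as.integer(seed), folds = folds),
            class = "split_plan")
}

#' One-hot encode a class mask
#'
#' @param class_mask `H x W` integer matrix with values in
#'   `0..(num_classes - 1)`.
#' @param num_classes number of channels (default 3).
#' @return `H x W x num_classes` array of 0/1 with per-pixel channel sum 1.
#' @export
one_hot <- function(class_mask, num_classes = 3) {
  stopifnot(is.matrix(class_mask), num_classes >= 1)
  bad <- class_mask < 0 | class_mask >= num_classes | class_mask != round(class_mask)
  if (any(bad)) {
    stop(sprintf("label value %s outside 0..%d",
                 class_mask[which(bad)[1]], num_classes - 1))
  }
  h <- nrow(class_mask); w <- ncol(class_mask)
  oh <- array(0, c(h, w, num_classes))
  for (k in seq_len(num_classes)) oh[, , k] <- as.numeric(class_mask == k - 1L)
  oh
}

#' Augmentation configuration
#'
#' Defaults follow the training protocol: a rotation is applied with 25%
#' probability; a single uniform draw `u` decides flips (`u < flip_low`
#' vertical, `u > flip_high` horizontal, i.e. ~25% each at the defaults);
#' brightness and hue deltas are drawn uniformly within `+/- brightness_max`
#' (0.1) and `+/- hue_max` (0.5) and applied to the image only.
#'
#' @param p_rotate rotation probability.
#' @param flip_low,flip_high thresholds of the single flip draw.
#' @param brightness_max maximum additive brightness delta.
#' @param hue_max maximum hue delta (hue in `[0, 1]`, wrapped).
#' @param seed optional seed recorded for provenance.
#' @return an object of class `augment_config`.
#' @export
augment_config <- function(p_rotate = 0.25, flip_low = 0.25, flip_high = 0.75,
                           brightness_max = 0.1, hue_max = 0.5, seed = NULL) {
  stopifnot(p_rotate >= 0, p_rotate <= 1,
            flip_low >= 0, flip_low <= flip_high, flip_high <= 1,
            brightness_max >= 0, hue_max >= 0)
  structure(list(p_rotate = p_rotate, flip_low = flip_low,
                 flip_high = flip_high, brightness_max = brightness_max,
                 hue_max = hue_max, seed = seed),
            class = "augment_config")
}

#' Draw one augmentation plan
#'
#' Consumes the generator in a fixed, documented order -- (1) rotation
#' gate, (2) rotation angle (only when rotating), (3) flip draw,
#' (4) brightness delta, (5) hue delta -- so identical generator states give
#' identical plans. The plan fully determines [apply_augmentation()].
#'
#' @param cfg an [augment_config()].
#' @param rng a [rng_new()] generator.
#' @return list with `rotate`, `angle` (degrees), `vflip`, `hflip`,
#'   `d_brightness`, `d_hue`.
#' @export
sample_augmentation <- function(cfg, rng) {
  stopifnot(inherits(cfg, "augment_config"))
  u_rot <- with_rng(rng, runif(1))
  rotate <- u_rot < cfg$p_rotate
  angle <- if (rotate) with_rng(rng, runif(1, 0, 360)) else 0
  u_flip <- with_rng(rng, runif(1))
  vflip <- u_flip < cfg$flip_low
  hflip <- u_flip > cfg$flip_high
  d_b <- with_rng(rng, runif(1, -cfg$brightness_max, cfg$brightness_max))
  d_h <- with_rng(rng, runif(1, -cfg$hue_max, cfg$hue_max))
  list(rotate = rotate, angle = angle, vflip = vflip, hflip = hflip,
       d_brightness = d_b, d_hue = d_h)
}

# Nearest-neighbor rotation index map about the image center; returns the
# linear source index per destination pixel, NA outside the canvas.
rotation_index <- function(h, w, angle) {
  th <- angle * pi / 180
  ci <- (h + 1) / 2; cj <- (w + 1) / 2
  i <- rep(seq_len(h), times = w)
  j <- rep(seq_len(w), each = h)
  # inverse map: rotate destination coords by -angle about the center
  si <- round(cos(th) * (i - ci) + sin(th) * (j - cj) + ci)
  sj <- round(-sin(th) * (i - ci) + cos(th) * (j - cj) + cj)
  ok <- si >= 1 & si <= h & sj >= 1 & sj <= w
  idx <- rep(NA_integer_, h * w)
  idx[ok] <- (sj[ok] - 1L) * h + si[ok]
  idx
}

rotate_plane <- function(m, idx, fill = 0) {
  out <- rep(fill, length(m))
  ok <- !is.na(idx)
  out[ok] <- m[idx[ok]]
  matrix(out, nrow(m), ncol(m))
}

# Vectorized HSV -> RGB (all components in [0, 1]); exact 6-sector formula.
hsv_to_rgb <- function(h, s, v) {
  h6 <- (h %% 1) * 6
  i <- floor(h6) %% 6
  f <- h6 - floor(h6)
  p <- v * (1 - s)
  q <- v * (1 - f * s)
  t <- v * (1 - (1 - f) * s)
  r <- ifelse(i == 0, v, ifelse(i == 1, q, ifelse(i == 2, p,
       ifelse(i == 3, p, ifelse(i == 4, t, v)))))
  g <- ifelse(i == 0, t, ifelse(i == 1, v, ifelse(i == 2, v,
       ifelse(i == 3, q, ifelse(i == 4, p, p)))))
  b <- ifelse(i == 0, p, ifelse(i == 1, p, ifelse(i == 2, t,
       ifelse(i == 3, v, ifelse(i == 4, v, q)))))
  cbind(r, g, b)
}

#' Apply an augmentation plan to an image and its targets
#'
#' Geometric operations (rotation with nearest-neighbor resampling, flips)
#' are applied identically to the image and every target map; out-of-canvas
#' pixels become background (intensity 0, one-hot background channel,
#' zero boundary/interior). Photometric operations (brightness, hue) touch
#' the image only; the image is clipped to `[0, 1]` afterwards.
#'
#' @param image `H x W x 3` array in `[0, 1]`.
#' @param targets a `training_targets` object (or `NULL` for image-only use).
#' @param plan a [sample_augmentation()] plan.
#' @return list with transformed `image` and `targets`.
#' @export
apply_augmentation <- function(image, targets, plan) {
  h <- dim(image)[1]; w <- dim(image)[2]
  img <- image
  tg <- targets
  if (plan$rotate && plan$angle %% 360 != 0) {
    idx <- rotation_index(h, w, plan$angle)
    for (ch in 1:3) img[, , ch] <- rotate_plane(img[, , ch], idx, fill = 0)
    if (!is.null(tg)) {
      oh <- tg$onehot
      nc <- dim(oh)[3]
      oh[, , 1] <- rotate_plane(oh[, , 1], idx, fill = 1) # background fill
      for (k in 2:nc) oh[, , k] <- rotate_plane(oh[, , k], idx, fill = 0)
      tg$onehot <- oh
      tg$boundary <- rotate_plane(tg$boundary, idx, fill = 0)
      tg$interior <- rotate_plane(tg$interior, idx, fill = 0)
    }
  }
  flip_all <- function(f) {
    for (ch in 1:3) img[, , ch] <<- f(img[, , ch])
    if (!is.null(tg)) {
      for (k in seq_len(dim(tg$onehot)[3])) tg$onehot[, , k] <<- f(tg$onehot[, , k])
      tg$boundary <<- f(tg$boundary)
      tg$interior <<- f(tg$interior)
    }
  }
  if (plan$vflip) flip_all(function(m) m[rev(seq_len(nrow(m))), , drop = FALSE])
  if (plan$hflip) flip_all(function(m) m[, rev(seq_len(ncol(m))), drop = FALSE])

  if (plan$d_brightness != 0) img <- img + plan$d_brightness
  if (plan$d_hue != 0) {
    rgb <- rbind(as.vector(pmin(pmax(img[, , 1], 0), 1)),
                 as.vector(pmin(pmax(img[, , 2], 0), 1)),
                 as.vector(pmin(pmax(img[, , 3], 0), 1)))
    hsvm <- grDevices::rgb2hsv(rgb, maxColorValue = 1)
    out <- hsv_to_rgb(hsvm[1, ] + plan$d_hue, hsvm[2, ], hsvm[3, ])
    img <- array(out, c(h, w, 3))
  }
  img[img < 0] <- 0
  img[img > 1] <- 1
  list(image = img, targets = tg)
}

#' Synchronized stochastic augmentation of an image-target pair
#'
#' Draws one augmentation plan from the generator and applies it to the pair.
#' Validation data must bypass this function entirely (no augmentation on
#' the validation pathway).
#'
#' @inheritParams apply_augmentation
#' @param cfg an [augment_config()].
#' @param rng a [rng_new()] generator (advanced by the call).
#' @return list with `image`, `targets` and the sampled `plan`.
#' @export
augment_pair <- function(image, targets, cfg, rng) {
  plan <- sample_augmentation(cfg, rng)
  out <- apply_augmentation(image, targets, plan)
  out$plan <- plan
  out
}
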
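# Shared fixtures, all built in code.

tiny_tissue <- function(seed = 7, n_cells = 12, side = 64, ...) {
  generate_tissue(synth_config(side, side, n_cells = n_cells, seed = seed, ...))
}

# A minimal hand-made sample: one 4x4 square instance on an 8x8 canvas.
square_sample <- function() {
  inst <- matrix(0L, 8, 8)
  inst[3:6, 3:6] <- 1L
  cls <- matrix(0L, 8, 8)
  cls[inst > 0] <- 1L
  img <- array(0.5, c(8, 8, 3))
  image_sample(img, cls, inst)
}

# Two rectangles sharing a vertical edge on a 6x3 canvas (rows 1:3 / 4:6).
touching_sample <- function() {
  inst <- matrix(0L, 6, 3)
  inst[1:3, ] <- 1L
  inst[4:6, ] <- 2L
  cls <- matrix(1L, 6, 3)
  image_sample(array(0.5, c(6, 3, 3)), cls, inst)
}

# Cheap image_sample for arithmetic-only tests (no tessellation).
stub_sample <- function(h = 9, w = 9, seed = 1) {
  r <- rng_new(seed)
  img <- array(with_rng(r, runif(h * w * 3)), c(h, w, 3))
  inst <- matrix(0L, h, w)
  inst[2:(h - 1), 2:(w - 1)] <- 1L
  cls <- matrix(0L, h, w)
  cls[inst > 0] <- 1L
  image_sample(img, cls, inst)
}

# Build an instance_set from a label map plus explicit confidences/classes.
inst_from <- function(label_map, confidence = NULL, class = NULL) {
  k <- max(label_map)
  if (is.null(confidence)) confidence <- rep(1, k)
  if (is.null(class)) class <- rep(1L, k)
  instance_set(label_map,
               records = data.frame(id = seq_len(k), class = class,
                                    confidence = confidence,
                                    area = tabulate(label_map[label_map > 0],
                                                    nbins = k)))
}

# Independent flood-fill component counter (R implementation, queue-based),
# used as an oracle against the C++ labeler.
flood_count <- function(mask, connectivity = 4) {
  h <- nrow(mask); w <- ncol(mask)
  seen <- matrix(FALSE, h, w)
  offs <- if (connectivity == 8) {
    list(c(-1,0),c(1,0),c(0,-1),c(0,1),c(-1,-1),c(-1,1),c(1,-1),c(1,1))
  } else list(c(-1,0),c(1,0),c(0,-1),c(0,1))
  k <- 0L
  for (j in seq_len(w)) for (i in seq_len(h)) {
    if (!mask[i, j] || seen[i, j]) next
    k <- k + 1L
    queue <- list(c(i, j)); seen[i, j] <- TRUE
    while (length(queue)) {
      p <- queue[[1]]; queue <- queue[-1]
      for (o in offs) {
        ni <- p[1] + o[1]; nj <- p[2] + o[2]
        if (ni >= 1 && ni <= h && nj >= 1 && nj <= w &&
            mask[ni, nj] && !seen[ni, nj]) {
          seen[ni, nj] <- TRUE
          queue[[length(queue) + 1L]] <- c(ni, nj)
        }
      }
    }
  }
  k
}
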
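#' Network configuration
#'
#' A triple-branch encoder-decoder: three structurally identical but
#' parameter-independent branches predict, respectively, a 3-channel
#' semantic map (background / parenchyma / vascular), a boundary map and an
#' interior map, each through a per-channel sigmoid. Every encoder stage is
#' two 3 x 3 convolutions (ReLU) followed by an attention block and 2 x 2
#' max pooling; every decoder stage is a 2 x 2 transposed-convolution
#' upsample, skip concatenation, two 3 x 3 convolutions and an attention
#' block after the fusion. With `depth` stages there are `2 * depth`
#' attention blocks per branch.
#'
#' @param depth number of downsampling stages (default 4).
#' @param base_channels channels at full resolution (default 32).
#' @param reduction channel reduction ratio of the attention blocks; must
#'   divide every stage's channel count.
#' @param in_channels input image channels (default 3, RGB).
#' @param lambda loss mixing weight in `[0, 1]` (BCE share).
#' @param attention one of the [attention_modules()] keys:
#'   `"channel_spatial"` (default), `"se"`, or `"none"` (plain U-Net twin).
#' @return an object of class `network_config`.
#' @export
network_config <- function(depth = 4, base_channels = 32, reduction = 16,
                           in_channels = 3, lambda = 0.5,
                           attention = "channel_spatial") {
  stopifnot(depth >= 1, base_channels >= 1, lambda >= 0, lambda <= 1)
  if (!attention %in% names(attention_modules())) {
    stop("unknown attention module: ", attention)
  }
  stage_ch <- base_channels * 2^(seq_len(depth) - 1)
  if (attention != "none" && any(stage_ch %% reduction != 0)) {
    stop(sprintf("reduction ratio %d does not divide all stage channel counts (%s)",
                 reduction, paste(stage_ch, collapse = ", ")))
  }
  structure(list(depth = as.integer(depth),
                 base_channels = as.integer(base_channels),
                 reduction = as.integer(reduction),
                 in_channels = as.integer(in_channels),
                 lambda = lambda, attention = attention,
                 branch_roles = c(semantic = 3L, boundary = 1L, interior = 1L)),
            class = "network_config")
}

he_mat <- function(nr, nc, fan_in, rng) {
  matrix(with_rng(rng, rnorm(nr * nc, 0, sqrt(2 / fan_in))), nr, nc)
}

# Build the flat tensor list of one branch. Convolutions carry biases; the
# attention blocks are bias-free so their counted weights match the closed
# form 2 C^2 / r + 98.
make_branch <- function(cfg, n_out, rng) {
  d <- cfg$depth
  b <- cfg$base_channels
  tn <- list()
  add_conv <- function(name, k, cin, cout) {
    tn[[paste0(name, "_W")]] <<- he_mat(k * k * cin, cout, k * k * cin, rng)
    tn[[paste0(name, "_b")]] <<- numeric(cout)
  }
  add_attn <- function(name, ch) {
    if (cfg$attention == "none") return(invisible())
    p <- attention_params(ch, cfg$reduction, rng = rng)
    tn[[paste0(name, "_W1")]] <<- p$W1
    tn[[paste0(name, "_W2")]] <<- p$W2
    if (cfg$attention == "channel_spatial") {
      tn[[paste0(name, "_K")]] <<- p$spatial_kernel
    }
  }
  for (s in seq_len(d)) {
    cin <- if (s == 1) cfg$in_channels else b * 2^(s - 2)
    cs <- b * 2^(s - 1)
    add_conv(sprintf("e%d_c1", s), 3, cin, cs)
    add_conv(sprintf("e%d_c2", s), 3, cs, cs)
    add_attn(sprintf("e%d_at", s), cs)
  }
  cb <- b * 2^d
  add_conv("bt_c1", 3, b * 2^(d - 1), cb)
  add_conv("bt_c2", 3, cb, cb)
  for (s in d:1) {
    cs <- b * 2^(s - 1)
    cin_up <- 2 * cs
    tn[[sprintf("d%d_up_W", s)]] <- he_mat(cin_up, 4 * cs, cin_up, rng)
    tn[[sprintf("d%d_up_b", s)]] <- numeric(cs)
    add_conv(sprintf("d%d_c1", s), 3, 2 * cs, cs)
    add_conv(sprintf("d%d_c2", s), 3, cs, cs)
    add_attn(sprintf("d%d_at", s), cs)
  }
  add_conv("hd", 1, b, n_out)
  tn
}

#' Build the triple-branch segmentation model
#'
#' @param config a [network_config()].
#' @param seed integer seed for weight initialization.
#' @return an object of class `seg_model`: the configuration plus three
#'   independent parameter sets (`semantic`, `boundary`, `interior`).
#' @export
#' @examples
#' m <- build_model(network_config(depth = 2, base_channels = 8,
#'                                 reduction = 4), seed = 1)
#' model_param_count(m)
build_model <- function(config, seed = 1) {
  stopifnot(inherits(config, "network_config"))
  rng <- rng_new(seed)
  branches <- lapply(config$branch_roles, function(nch)
    make_branch(config, nch, rng))
  structure(list(config = config, branches = branches, opt = NULL),
            class = "seg_model")
}

#' Total learnable parameter count
#'
#' @param model a [build_model()] model.
#' @param per_branch return the per-branch breakdown instead of the total.
#' @return integer count(s).
#' @export
model_param_count <- function(model, per_branch = FALSE) {
  counts <- vapply(model$branches,
                   function(br) sum(vapply(br, length, integer(1))),
                   integer(1))
  if (per_branch) counts else sum(counts)
}

#' Number of attention blocks in the model
#'
#' @param model a `seg_model`.
#' @return integer: total attention-block instances across the branches.
#' @export
count_attention_blocks <- function(model) {
  sum(vapply(model$branches, function(br)
    sum(grepl("_at_W1$", names(br))), integer(1)))
}

# ---- forward primitives (with optional caches for backprop) --------------

conv_fw <- function(x, w, bias, k, pad) {
  d <- dim(x)
  cols <- im2col_cpp(x, as.integer(k), as.integer(pad))
  hw <- d[1] * d[2]
  y <- cols %*% w
  y <- y + rep(bias, each = hw)
  list(out = array(y, c(d[1], d[2], ncol(w))), cols = cols, in_dim = d)
}

conv_bw <- function(dout, cache, w, k, pad) {
  d <- dim(dout)
  hw <- d[1] * d[2]
  dy <- matrix(dout, hw, d[3])
  dw <- crossprod(cache$cols, dy)
  db <- colSums(dy)
  dcols <- dy %*% t(w)
  dx <- col2im_cpp(dcols, cache$in_dim[1], cache$in_dim[2], cache$in_dim[3],
                   as.integer(k), as.integer(pad))
  list(dx = dx, dW = dw, db = db)
}

pool_fw <- function(x) {
  d <- dim(x)
  i1 <- seq(1, d[1], 2); i2 <- i1 + 1
  j1 <- seq(1, d[2], 2); j2 <- j1 + 1
  s11 <- x[i1, j1, , drop = FALSE]; s21 <- x[i2, j1, , drop = FALSE]
  s12 <- x[i1, j2, , drop = FALSE]; s22 <- x[i2, j2, , drop = FALSE]
  code <- array(1L, dim(s11))
  m <- s11
  upd <- s21 > m; code[upd] <- 2L; m <- pmax(m, s21)
  upd <- s12 > m; code[upd] <- 3L; m <- pmax(m, s12)
  upd <- s22 > m; code[upd] <- 4L; m <- pmax(m, s22)
  list(out = m, code = code, in_dim = d)
}

pool_bw <- function(dout, cache) {
  d <- cache$in_dim
  dx <- array(0, d)
  i1 <- seq(1, d[1], 2); j1 <- seq(1, d[2], 2)
  offs <- list(c(0L, 0L), c(1L, 0L), c(0L, 1L), c(1L, 1L))
  for (pos in 1:4) {
    sel <- cache$code == pos
    if (!any(sel)) next
    dsub <- array(0, dim(dout))
    dsub[sel] <- dout[sel]
    dx[i1 + offs[[pos]][1], j1 + offs[[pos]][2], ] <- dsub
  }
  dx
}

tconv_fw <- function(x, w, bias) {
  d <- dim(x)
  hw <- d[1] * d[2]
  cout <- length(bias)
  y <- matrix(x, hw, d[3]) %*% w
  out <- array(0, c(2 * d[1], 2 * d[2], cout))
  for (pos in 1:4) {
    oi <- seq(1, 2 * d[1], 2) + (pos - 1) %% 2
    oj <- seq(1, 2 * d[2], 2) + (pos - 1) %/% 2
    out[oi, oj, ] <- array(y[, pos + 4 * (0:(cout - 1)), drop = FALSE],
                           c(d[1], d[2], cout))
  }
  out <- out + rep(bias, each = 4 * hw)
  list(out = out, x_mat = matrix(x, hw, d[3]), in_dim = d)
}

tconv_bw <- function(dout, cache, w) {
  d <- cache$in_dim
  hw <- d[1] * d[2]
  cout <- dim(dout)[3]
  dy <- matrix(0, hw, 4 * cout)
  for (pos in 1:4) {
    oi <- seq(1, 2 * d[1], 2) + (pos - 1) %% 2
    oj <- seq(1, 2 * d[2], 2) + (pos - 1) %/% 2
    dy[, pos + 4 * (0:(cout - 1))] <- matrix(dout[oi, oj, , drop = FALSE],
                                             hw, cout)
  }
  db <- colSums(matrix(dout, 4 * hw, cout))
  list(dx = array(dy %*% t(w), d), dW = t(cache$x_mat) %*% dy, db = db)
}

attn_fw <- function(f, w1, w2, kern) {
  d <- dim(f)
  hw <- d[1] * d[2]
  fm <- matrix(f, hw, d[3])
  z <- colMeans(fm)
  a1 <- as.vector(w1 %*% z)
  h1 <- pmax(a1, 0)
  s <- 1 / (1 + exp(-as.vector(w2 %*% h1)))
  fca <- fm * rep(s, each = hw)
  if (is.null(kern)) {
    return(list(out = array(fca, d),
                cache = list(fm = fm, z = z, a1 = a1, h1 = h1, s = s,
                             spatial = FALSE, d = d)))
  }
  a <- rowMeans(fca)
  m <- fca[, 1]
  arg <- rep(1L, hw)
  if (d[3] > 1) {
    for (cc in 2:d[3]) {
      upd <- fca[, cc] > m
      arg[upd] <- cc
      m <- pmax(m, fca[, cc])
    }
  }
  am <- array(c(a, m), c(d[1], d[2], 2))
  cols <- im2col_cpp(am, 7L, 3L)
  q <- as.vector(cols %*% as.vector(kern))
  p <- 1 / (1 + exp(-q))
  out <- fca * p
  list(out = array(out, d),
       cache = list(fm = fm, z = z, a1 = a1, h1 = h1, s = s, fca = fca,
                    arg = arg, cols = cols, p = p, spatial = TRUE, d = d))
}

attn_bw <- function(dout, cache, w1, w2, kern) {
  d <- cache$d
  hw <- d[1] * d[2]
  cc <- d[3]
  dout_m <- matrix(dout, hw, cc)
  if (cache$spatial) {
    dp <- rowSums(dout_m * cache$fca)
    dfca <- dout_m * cache$p
    dq <- dp * cache$p * (1 - cache$p)
    dK <- crossprod(cache$cols, dq)
    dcols <- tcrossprod(dq, as.vector(kern))
    dam <- col2im_cpp(dcols, d[1], d[2], 2L, 7L, 3L)
    da <- as.vector(dam[, , 1])
    dm <- as.vector(dam[, , 2])
    dfca <- dfca + da / cc
    idx <- cbind(seq_len(hw), cache$arg)
    dfca[idx] <- dfca[idx] + dm
  } else {
    dfca <- dout_m
    dK <- NULL
  }
  ds <- colSums(dfca * cache$fm)
  dfm <- dfca * rep(cache$s, each = hw)
  da2 <- ds * cache$s * (1 - cache$s)
  dW2 <- da2 %o% cache$h1
  dh1 <- as.vector(t(w2) %*% da2)
  da1 <- dh1 * (cache$a1 > 0)
  dW1 <- da1 %o% cache$z
  dz <- as.vector(t(w1) %*% da1)
  dfm <- dfm + rep(dz / hw, each = hw)
  list(dx = array(dfm, d), dW1 = dW1, dW2 = dW2,
       dK = if (is.null(dK)) NULL else array(dK, c(7, 7, 2)))
}

# ---- one branch: forward with cache, backward producing gradients --------

branch_forward <- function(tn, cfg, x, keep = FALSE) {
  d <- cfg$depth
  use_at <- cfg$attention != "none"
  spatial <- cfg$attention == "channel_spatial"
  ck <- list(enc = vector("list", d), dec = vector("list", d))
  skips <- vector("list", d)
  h <- x
  for (s in seq_len(d)) {
    n1 <- sprintf("e%d_c1", s); n2 <- sprintf("e%d_c2", s)
    f1 <- conv_fw(h, tn[[paste0(n1, "_W")]], tn[[paste0(n1, "_b")]], 3, 1)
    r1 <- pmax(f1$out, 0)
    f2 <- conv_fw(r1, tn[[paste0(n2, "_W")]], tn[[paste0(n2, "_b")]], 3, 1)
    r2 <- pmax(f2$out, 0)
    if (use_at) {
      na <- sprintf("e%d_at", s)
      at <- attn_fw(r2, tn[[paste0(na, "_W1")]], tn[[paste0(na, "_W2")]],
                    if (spatial) tn[[paste0(na, "_K")]] else NULL)
      skips[[s]] <- at$out
    } else {
      at <- NULL
      skips[[s]] <- r2
    }
    pl <- pool_fw(skips[[s]])
    h <- pl$out
    if (keep) {
      ck$enc[[s]] <- list(f1 = f1, m1 = f1$out > 0, f2 = f2, m2 = f2$out > 0,
                          at = at, pl = pl)
      ck$enc[[s]]$f1$out <- NULL
      ck$enc[[s]]$f2$out <- NULL
    }
  }
  fb1 <- conv_fw(h, tn$bt_c1_W, tn$bt_c1_b, 3, 1)
  rb1 <- pmax(fb1$out, 0)
  fb2 <- conv_fw(rb1, tn$bt_c2_W, tn$bt_c2_b, 3, 1)
  h <- pmax(fb2$out, 0)
  if (keep) {
    ck$bt <- list(f1 = fb1, m1 = fb1$out > 0, f2 = fb2, m2 = fb2$out > 0)
    ck$bt$f1$out <- NULL
    ck$bt$f2$out <- NULL
  }
  for (s in d:1) {
    up <- tconv_fw(h, tn[[sprintf("d%d_up_W", s)]], tn[[sprintf("d%d_up_b", s)]])
    dd <- dim(up$out)
    cs <- dd[3]
    cat_ <- array(c(up$out, skips[[s]]), c(dd[1], dd[2], 2 * cs))
    n1 <- sprintf("d%d_c1", s); n2 <- sprintf("d%d_c2", s)
    f1 <- conv_fw(cat_, tn[[paste0(n1, "_W")]], tn[[paste0(n1, "_b")]], 3, 1)
    r1 <- pmax(f1$out, 0)
    f2 <- conv_fw(r1, tn[[paste0(n2, "_W")]], tn[[paste0(n2, "_b")]], 3, 1)
    r2 <- pmax(f2$out, 0)
    if (use_at) {
      na <- sprintf("d%d_at", s)
      at <- attn_fw(r2, tn[[paste0(na, "_W1")]], tn[[paste0(na, "_W2")]],
                    if (spatial) tn[[paste0(na, "_K")]] else NULL)
      h <- at$out
    } else {
      at <- NULL
      h <- r2
    }
    if (keep) {
      ck$dec[[s]] <- list(up = up, f1 = f1, m1 = f1$out > 0,
                          f2 = f2, m2 = f2$out > 0, at = at, cs = cs)
      ck$dec[[s]]$f1$out <- NULL
      ck$dec[[s]]$f2$out <- NULL
    }
  }
  fh <- conv_fw(h, tn$hd_W, tn$hd_b, 1, 0)
  p <- 1 / (1 + exp(-fh$out))
  if (keep) ck$hd <- fh
  list(p = p, cache = if (keep) ck else NULL)
}

branch_backward <- function(tn, cfg, cache, p, dP) {
  d <- cfg$depth
  use_at <- cfg$attention != "none"
  spatial <- cfg$attention == "channel_spatial"
  g <- list()
  dz <- dP * p * (1 - p)
  hb <- conv_bw(dz, cache$hd, tn$hd_W, 1, 0)
  g$hd_W <- hb$dW; g$hd_b <- hb$db
  dh <- hb$dx
  dskips <- vector("list", d)
  for (s in seq_len(d)) {
    st <- cache$dec[[s]]
    if (use_at) {
      na <- sprintf("d%d_at", s)
      ab <- attn_bw(dh, st$at$cache, tn[[paste0(na, "_W1")]],
                    tn[[paste0(na, "_W2")]],
                    if (spatial) tn[[paste0(na, "_K")]] else NULL)
      g[[paste0(na, "_W1")]] <- ab$dW1
      g[[paste0(na, "_W2")]] <- ab$dW2
      if (spatial) g[[paste0(na, "_K")]] <- ab$dK
      dh <- ab$dx
    }
    n1 <- sprintf("d%d_c1", s); n2 <- sprintf("d%d_c2", s)
    b2 <- conv_bw(dh * st$m2, st$f2, tn[[paste0(n2, "_W")]], 3, 1)
    g[[paste0(n2, "_W")]] <- b2$dW; g[[paste0(n2, "_b")]] <- b2$db
    b1 <- conv_bw(b2$dx * st$m1, st$f1, tn[[paste0(n1, "_W")]], 3, 1)
    g[[paste0(n1, "_W")]] <- b1$dW; g[[paste0(n1, "_b")]] <- b1$db
    cs <- st$cs
    dcat <- b1$dx
    dup <- dcat[, , seq_len(cs), drop = FALSE]
    dskips[[s]] <- dcat[, , cs + seq_len(cs), drop = FALSE]
    ub <- tconv_bw(dup, st$up, tn[[sprintf("d%d_up_W", s)]])
    g[[sprintf("d%d_up_W", s)]] <- ub$dW
    g[[sprintf("d%d_up_b", s)]] <- ub$db
    dh <- ub$dx
  }
  bb2 <- conv_bw(dh * cache$bt$m2, cache$bt$f2, tn$bt_c2_W, 3, 1)
  g$bt_c2_W <- bb2$dW; g$bt_c2_b <- bb2$db
  bb1 <- conv_bw(bb2$dx * cache$bt$m1, cache$bt$f1, tn$bt_c1_W, 3, 1)
  g$bt_c1_W <- bb1$dW; g$bt_c1_b <- bb1$db
  dh <- bb1$dx
  for (s in d:1) {
    st <- cache$enc[[s]]
    dat_out <- pool_bw(dh, st$pl) + dskips[[s]]
    if (use_at) {
      na <- sprintf("e%d_at", s)
      ab <- attn_bw(dat_out, st$at$cache, tn[[paste0(na, "_W1")]],
                    tn[[paste0(na, "_W2")]],
                    if (spatial) tn[[paste0(na, "_K")]] else NULL)
      g[[paste0(na, "_W1")]] <- ab$dW1
      g[[paste0(na, "_W2")]] <- ab$dW2
      if (spatial) g[[paste0(na, "_K")]] <- ab$dK
      dat_out <- ab$dx
    }
    n1 <- sprintf("e%d_c1", s); n2 <- sprintf("e%d_c2", s)
    b2 <- conv_bw(dat_out * st$m2, st$f2, tn[[paste0(n2, "_W")]], 3, 1)
    g[[paste0(n2, "_W")]] <- b2$dW; g[[paste0(n2, "_b")]] <- b2$db
    b1 <- conv_bw(b2$dx * st$m1, st$f1, tn[[paste0(n1, "_W")]], 3, 1)
    g[[paste0(n1, "_W")]] <- b1$dW; g[[paste0(n1, "_b")]] <- b1$db
    dh <- b1$dx
  }
  g
}

check_input_image <- function(model, image) {
  d <- dim(image)
  if (length(d) != 3 || d[3] != model$config$in_channels) {
    stop("expected an H x W x ", model$config$in_channels, " image array")
  }
  div <- 2^model$config$depth
  if (d[1] %% div != 0 || d[2] %% div != 0) {
    stop(sprintf(paste0("spatial dimensions %d x %d are not divisible by ",
                        "2^depth = %d; pad the image first"), d[1], d[2], div))
  }
  invisible(TRUE)
}

#' Run the model on one image (inference)
#'
#' Deterministic forward pass through the three branches.
#'
#' @param object a `seg_model`.
#' @param image `H x W x 3` array in `[0, 1]`; `H` and `W` must be divisible
#'   by `2^depth`.
#' @param ... unused.
#' @return an object of class `predictions`: `semantic` (`H x W x 3`),
#'   `boundary` and `interior` (`H x W`), all values strictly in `(0, 1)`.
#' @export
predict.seg_model <- function(object, image, ...) {
  check_input_image(object, image)
  out <- lapply(names(object$branches), function(nm) {
    branch_forward(object$branches[[nm]], object$config, image)$p
  })
  names(out) <- names(object$branches)
  structure(list(semantic = out$semantic,
                 boundary = out$boundary[, , 1],
                 interior = out$interior[, , 1]),
            class = "predictions")
}

branch_target <- function(role, targets) {
  switch(role,
         semantic = targets$onehot,
         boundary = array(targets$boundary, c(dim(targets$boundary), 1L)),
         interior = array(targets$interior, c(dim(targets$interior), 1L)))
}

#' One optimization step on a batch
#'
#' Runs forward and backward passes for the three branches on every sample,
#' averages gradients over the batch, and applies an RMSprop update
#' (gradient accumulator decay `rho`, the stated learning-rate decay applied
#' as weight decay). The loss is the sum over the three heads of the
#' combined BCE + Dice objective.
#'
#' @param model a `seg_model`.
#' @param batch list of samples, each a list with `image` and `targets`
#'   (a `training_targets`).
#' @param lr learning rate (default 1e-4).
#' @param rho RMSprop decay (default 0.9).
#' @param weight_decay decay term (default 1e-15, numerically inert).
#' @param loss_cfg a [loss_config()]; defaults to the model's `lambda`.
#' @return list with the updated `model`, scalar `loss`, and per-head
#'   `head_losses`.
#' @export
training_step <- function(model, batch, lr = 1e-4, rho = 0.9,
                          weight_decay = 1e-15, loss_cfg = NULL) {
  if (is.null(loss_cfg)) loss_cfg <- loss_config(lambda = model$config$lambda)
  n <- length(batch)
  stopifnot(n >= 1)
  roles <- names(model$branches)
  head_losses <- setNames(numeric(length(roles)), roles)
  grads <- setNames(vector("list", length(roles)), roles)
  for (smp in batch) {
    check_input_image(model, smp$image)
    for (role in roles) {
      fw <- branch_forward(model$branches[[role]], model$config, smp$image,
                           keep = TRUE)
      y <- branch_target(role, smp$targets)
      l <- combined_loss(fw$p, y, loss_cfg)
      if (!is.finite(l)) {
        stop(sprintf("non-finite loss in branch '%s' (loss = %s); inspect inputs",
                     role, format(l)))
      }
      head_losses[[role]] <- head_losses[[role]] + l / n
      dP <- combined_loss_grad(fw$p, y, loss_cfg)
      g <- branch_backward(model$branches[[role]], model$config, fw$cache,
                           fw$p, dP)
      if (is.null(grads[[role]])) {
        grads[[role]] <- lapply(g, function(x) x / n)
      } else {
        grads[[role]] <- mapply(function(a, b) a + b / n,
                                grads[[role]], g[names(grads[[role]])],
                                SIMPLIFY = FALSE)
      }
    }
  }
  if (is.null(model$opt)) {
    model$opt <- lapply(model$branches, function(br)
      lapply(br, function(t) array(0, dim1(t))))
  }
  for (role in roles) {
    br <- model$branches[[role]]
    for (nm in names(br)) {
      gt <- grads[[role]][[nm]] + weight_decay * br[[nm]]
      v <- rho * model$opt[[role]][[nm]] + (1 - rho) * gt^2
      model$opt[[role]][[nm]] <- v
      model$branches[[role]][[nm]] <- br[[nm]] - lr * gt / (sqrt(v) + 1e-8)
    }
  }
  list(model = model, loss = sum(head_losses), head_losses = head_losses)
}

#' Macro-averaged hard Dice of a semantic prediction
#'
#' Binarizes the semantic probabilities by per-pixel argmax and averages the
#' binary Dice coefficient over the channels.
#'
#' @param pred_sem `H x W x K` probability array.
#' @param onehot `H x W x K` one-hot ground truth.
#' @return scalar in `[0, 1]`.
#' @export
semantic_dice <- function(pred_sem, onehot) {
  k <- dim(pred_sem)[3]
  am <- apply(pred_sem, c(1, 2), which.max)
  mean(vapply(seq_len(k), function(cc) {
    dice_coef((onehot[, , cc] > 0.5) * 1, (am == cc) * 1)
  }, numeric(1)))
}

#' Train a model on a fixed set of samples
#'
#' Full-batch training loop around [training_step()], logging the loss and
#' (optionally) the training semantic Dice, with optional early stopping
#' when a target Dice is reached.
#'
#' @param model a `seg_model`.
#' @param samples list of `image_sample` objects, or of lists with `image`
#'   and `targets`.
#' @param steps maximum number of optimization steps.
#' @param lr learning rate.
#' @param boundary_width band width used when targets must be derived.
#' @param eval_every evaluate the semantic Dice every this many steps
#'   (0 disables evaluation and early stopping).
#' @param stop_dice stop once the training semantic Dice reaches this value.
#' @param verbose print progress lines.
#' @return list with the trained `model`, a `log` data frame
#'   (step, loss, per-head losses) and a `dice_log` data frame.
#' @export
train_model <- function(model, samples, steps = 200, lr = 1e-4,
                        boundary_width = 1, eval_every = 10,
                        stop_dice = NULL, verbose = FALSE) {
  batch <- lapply(samples, function(s) {
    if (inherits(s, "image_sample")) {
      list(image = s$image, targets = derive_targets(s, boundary_width = boundary_width))
    } else s
  })
  log <- data.frame(step = integer(0), loss = numeric(0),
                    semantic = numeric(0), boundary = numeric(0),
                    interior = numeric(0))
  dice_log <- data.frame(step = integer(0), dice = numeric(0))
  for (st in seq_len(steps)) {
    res <- training_step(model, batch, lr = lr)
    model <- res$model
    log[nrow(log) + 1L, ] <- c(st, res$loss, res$head_losses["semantic"],
                               res$head_losses["boundary"],
                               res$head_losses["interior"])
    do_eval <- eval_every > 0 && (st %% eval_every == 0 || st == steps)
    if (do_eval) {
      dc <- mean(vapply(batch, function(b) {
        p <- branch_forward(model$branches$semantic, model$config, b$image)$p
        semantic_dice(p, b$targets$onehot)
      }, numeric(1)))
      dice_log[nrow(dice_log) + 1L, ] <- c(st, dc)
      if (verbose) {
        message(sprintf("step %4d  loss %.4f  semantic dice %.4f",
                        st, res$loss, dc))
      }
      if (!is.null(stop_dice) && dc >= stop_dice) break
    } else if (verbose && st %% 10 == 0) {
      message(sprintf("step %4d  loss %.4f", st, res$loss))
    }
  }
  list(model = model, log = log, dice_log = dice_log)
}
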
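small_cfg <- function(attention = "channel_spatial") {
  network_config(depth = 2, base_channels = 8, reduction = 4,
                 attention = attention)
}

test_that("output shapes match the input for several sizes", {
  m <- build_model(small_cfg(), seed = 1)
  for (side in c(16, 24, 32)) {
    img <- array(runif(side * side * 3), c(side, side, 3))
    p <- predict(m, img)
    expect_equal(dim(p$semantic), c(side, side, 3))
    expect_equal(dim(p$boundary), c(side, side))
    expect_equal(dim(p$interior), c(side, side))
    expect_true(all(p$semantic > 0 & p$semantic < 1))
  }
  expect_error(predict(m, array(0.5, c(18, 16, 3))), "divisible")
})

test_that("attention blocks appear 2*depth times per branch", {
  m2 <- build_model(small_cfg(), seed = 1)
  expect_equal(count_attention_blocks(m2), 3 * 2 * 2)
  m3 <- build_model(network_config(depth = 3, base_channels = 8,
                                   reduction = 4), seed = 1)
  expect_equal(count_attention_blocks(m3), 3 * 2 * 3)
})

test_that("attention overhead equals the closed form, per insertion point", {
  cfg_at <- network_config(depth = 3, base_channels = 16, reduction = 16)
  cfg_no <- network_config(depth = 3, base_channels = 16, reduction = 16,
                           attention = "none")
  m_at <- build_model(cfg_at, seed = 2)
  m_no <- build_model(cfg_no, seed = 2)
  # encoder stages at C = 16, 32, 64 and decoder stages at the same channel
  # multiset; each block costs 2 C^2 / r + 98
  chans <- rep(16 * 2^(0:2), 2)
  overhead_branch <- sum(2 * chans^2 / 16 + 98)
  expect_equal(model_param_count(m_at) - model_param_count(m_no),
               3 * overhead_branch)
})

test_that("zeroed head weights force all probabilities to one half", {
  m <- build_model(small_cfg(), seed = 3)
  for (role in names(m$branches)) {
    m$branches[[role]]$hd_W[] <- 0
    m$branches[[role]]$hd_b[] <- 0
  }
  img <- array(runif(16 * 16 * 3), c(16, 16, 3))
  p <- predict(m, img)
  expect_equal(as.vector(p$semantic), rep(0.5, 16 * 16 * 3))
  expect_equal(as.vector(p$boundary), rep(0.5, 256))
})

test_that("inference is deterministic and branches are parameter-independent", {
  m <- build_model(small_cfg(), seed = 4)
  img <- array(runif(16 * 16 * 3), c(16, 16, 3))
  expect_identical(predict(m, img), predict(m, img))
  # perturbing the boundary branch leaves the semantic output unchanged
  p0 <- predict(m, img)
  m$branches$boundary$e1_c1_W <- m$branches$boundary$e1_c1_W + 0.3
  p1 <- predict(m, img)
  expect_identical(p1$semantic, p0$semantic)
  expect_false(identical(p1$boundary, p0$boundary))
})

test_that("branch gradients agree with finite differences", {
  cfg <- small_cfg()
  m <- build_model(cfg, seed = 5)
  r <- rng_new(6)
  img <- array(with_rng(r, runif(16 * 16 * 3)), c(16, 16, 3))
  inst <- matrix(0L, 16, 16); inst[3:7, 3:7] <- 1L; inst[10:14, 9:15] <- 2L
  cm <- matrix(0L, 16, 16); cm[inst > 0] <- 1L
  tg <- derive_targets(inst, cm)
  lc <- loss_config(0.5)
  tn <- m$branches$semantic
  lossfn <- function(tnx) {
    combined_loss(culmseg:::branch_forward(tnx, cfg, img)$p, tg$onehot, lc)
  }
  fw <- culmseg:::branch_forward(tn, cfg, img, keep = TRUE)
  g <- culmseg:::branch_backward(tn, cfg, fw$cache, fw$p,
                                 culmseg:::combined_loss_grad(fw$p, tg$onehot, lc))
  for (nm in c("e1_c1_W", "e2_c2_b", "e1_at_W1", "e2_at_K", "d1_up_W",
               "d2_c1_W", "d1_at_W2", "bt_c1_W", "hd_W")) {
    ii <- with_rng(r, sample(length(tn[[nm]]), 1))
    tp <- tn; tp[[nm]][ii] <- tp[[nm]][ii] + 1e-6
    tm <- tn; tm[[nm]][ii] <- tm[[nm]][ii] - 1e-6
    num <- (lossfn(tp) - lossfn(tm)) / 2e-6
    denom <- max(1e-6, abs(num), abs(g[[nm]][ii]))
    expect_lt(abs(num - g[[nm]][ii]) / denom, 1e-2)
  }
})

test_that("lambda endpoints reduce the objective to its components", {
  m <- build_model(small_cfg(), seed = 7)
  img <- array(runif(16 * 16 * 3), c(16, 16, 3))
  p <- predict(m, img)
  inst <- matrix(0L, 16, 16); inst[4:9, 4:9] <- 1L
  cm <- matrix(0L, 16, 16); cm[inst > 0] <- 1L
  tg <- derive_targets(inst, cm)
  expect_equal(combined_loss(p$semantic, tg$onehot, loss_config(lambda = 1)),
               bce_loss(p$semantic, tg$onehot))
  expect_equal(combined_loss(p$semantic, tg$onehot, loss_config(lambda = 0)),
               dice_loss(p$semantic, tg$onehot))
})

test_that("a training step lowers the loss and perfect predictions score ~0", {
  m <- build_model(small_cfg(), seed = 8)
  s <- tiny_tissue(seed = 2, n_cells = 4, side = 32)
  batch <- list(list(image = s$image, targets = derive_targets(s)))
  r1 <- training_step(m, batch, lr = 1e-3)
  r2 <- training_step(r1$model, batch, lr = 1e-3)
  expect_true(is.finite(r1$loss))
  expect_lt(r2$loss, r1$loss)

  tg <- derive_targets(s)
  clip <- 1e-7
  perfect <- pmin(pmax(tg$onehot, clip), 1 - clip)
  expect_lt(combined_loss(perfect, tg$onehot, loss_config()), 1e-4)
})
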
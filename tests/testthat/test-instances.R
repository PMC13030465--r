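test_that("discretize applies an inclusive threshold", {
  h <- 4; w <- 4
  pr <- structure(list(semantic = array(0.5, c(h, w, 3)),
                       boundary = matrix(0.5, h, w),
                       interior = matrix(0.5, h, w)), class = "predictions")
  dm <- discretize(pr, threshold = 0.5)
  expect_true(all(dm$region))  # inclusive >= at exactly 0.5
  expect_true(all(dm$boundary))

  pr$semantic[] <- 0.8; pr$boundary[] <- 0.8
  dm2 <- discretize(pr, threshold = 0.9)
  expect_false(any(dm2$region))
  expect_false(any(dm2$boundary))

  # random map round-trips against an elementwise comparison oracle
  r <- rng_new(5)
  pr$semantic <- array(with_rng(r, runif(h * w * 3)), c(h, w, 3))
  pr$boundary <- matrix(with_rng(r, runif(h * w)), h, w)
  dm3 <- discretize(pr, 0.5)
  expect_equal(dm3$region,
               pmax(pr$semantic[, , 2], pr$semantic[, , 3]) >= 0.5)
  expect_equal(dm3$boundary, pr$boundary >= 0.5)
})

test_that("boundary column separates two squares into two instances", {
  region <- matrix(TRUE, 3, 7)
  boundary <- matrix(FALSE, 3, 7)
  boundary[, 4] <- TRUE
  lab <- separate_and_label(region, boundary, 4)
  expect_equal(max(lab), 2)
  expect_equal(flood_count(region & !boundary, 4), 2)
  # without the boundary the region is one component (flood-fill oracle)
  lab1 <- separate_and_label(region, matrix(FALSE, 3, 7), 4)
  expect_equal(max(lab1), 1)
  expect_equal(max(separate_and_label(matrix(FALSE, 3, 3),
                                      matrix(FALSE, 3, 3))), 0)
})

test_that("labels follow raster discovery order and match the oracle count", {
  s <- tiny_tissue(seed = 19, n_cells = 15, side = 96)
  tg <- derive_targets(s)
  lab <- separate_and_label(s$class_mask > 0, tg$boundary == 1, 4)
  expect_equal(max(lab), flood_count(s$class_mask > 0 & tg$boundary == 0, 4))
  # cross-check against an independent labeler on the same interiors
  expect_equal(max(lab), max(EBImage::bwlabel(s$class_mask > 0 & tg$boundary == 0)))
  # first discovered label in column-major scan is 1
  firstpos <- which(lab > 0)[1]
  expect_equal(lab[firstpos], 1L)
})

test_that("4-connectivity does not leak across one-pixel diagonal walls", {
  region <- matrix(TRUE, 4, 4)
  boundary <- matrix(FALSE, 4, 4)
  boundary[cbind(c(1, 2, 3, 4), c(4, 3, 2, 1))] <- TRUE # anti-diagonal wall
  expect_equal(max(separate_and_label(region, boundary, 4)), 2)
  expect_equal(max(separate_and_label(region, boundary, 8)), 1)
})

test_that("reclaim_boundary fills walls to the nearest instance", {
  region <- matrix(TRUE, 3, 5)
  boundary <- matrix(FALSE, 3, 5)
  boundary[, 3] <- TRUE
  lab <- separate_and_label(region, boundary, 4)
  expect_identical(reclaim_boundary(lab, region, "off"), lab)
  full <- reclaim_boundary(lab, region, "nearest")
  expect_equal(sum(full == 0), 0)
  expect_setequal(unique(full[, 1:2]), 1L)
  expect_setequal(unique(full[, 4:5]), 2L)

  # single instance beside a wall: the wall joins it
  region2 <- matrix(FALSE, 3, 4); region2[, 1:3] <- TRUE
  b2 <- matrix(FALSE, 3, 4); b2[, 3] <- TRUE
  lab2 <- separate_and_label(region2, b2, 4)
  full2 <- reclaim_boundary(lab2, region2, "nearest")
  expect_true(all(full2[, 3] == 1L))
})

test_that("scoring and classification follow per-pixel accumulation", {
  lab <- matrix(0L, 4, 6)
  lab[2:3, 2:3] <- 1L
  lab[2:3, 5:6] <- 2L
  sem <- array(0.05, c(4, 6, 3))
  sem[, , 2][lab == 1L] <- 0.9          # parenchyma-dominant instance
  sem[, , 3][lab == 2L] <- 0.7          # vascular-dominant instance
  sem[, , 2][lab == 2L] <- 0.2
  pr <- structure(list(semantic = sem, boundary = matrix(0.1, 4, 6),
                       interior = matrix(0.5, 4, 6)), class = "predictions")
  inst <- score_and_class(lab, pr)
  expect_equal(inst$records$class, c(1L, 2L))
  expect_equal(inst$records$confidence[1], 0.9)
  expect_equal(inst$records$confidence[2], 0.7)
  # oracle: mean over pixels of max cell-class probability
  expect_equal(inst$records$confidence[2],
               mean(pmax(sem[, , 2], sem[, , 3])[lab == 2L]))
})

test_that("size filter drops small instances and compacts ids", {
  lab <- matrix(0L, 8, 8)
  lab[1, 1] <- 1L              # area 1
  lab[3:8, 2:8] <- 2L          # area 42
  inst <- inst_from(lab, confidence = c(0.5, 0.8))
  expect_identical(size_filter(inst, 0), inst)
  f <- size_filter(inst, 5)
  expect_equal(nrow(f$records), 1)
  expect_equal(f$records$id, 1L)
  expect_equal(f$records$area, 42L)
  expect_equal(sum(f$label_map > 0), 42)
  expect_equal(sort(unique(f$label_map[f$label_map > 0])), 1L)
})

test_that("noise-free predictions recover every generated instance", {
  s <- generate_tissue(synth_config(128, 128, n_cells = 30, seed = 12))
  pr <- predictions_from_truth(s, 0.95, 0.05)
  inst <- extract_instances(pr, threshold = 0.5, connectivity = 4)
  tg <- derive_targets(s)
  expect_equal(nrow(inst$records), 30)
  # per-instance IoU vs the boundary-excluded ground truth (interiors)
  gt_int <- s$instance_map * (tg$interior == 1)
  mr <- match_instances(inst, instance_set(gt_int), t = 0.9)
  expect_equal(nrow(mr$pairs), 30)
  expect_true(all(mr$pairs$iou >= 0.9))
})

test_that("weakening the boundary never splits instances (under-segmentation)", {
  # progressively weaker wall responses: the boundary band is eroded outward
  # from the cell interiors, exactly the thin-wall failure mode
  s <- generate_tissue(synth_config(96, 96, n_cells = 20, seed = 8))
  tg <- derive_targets(s)
  region <- matrix(TRUE, 96, 96) # tissue fills the canvas
  interior0 <- tg$interior == 1
  bnd0 <- !interior0
  ks <- integer(0)
  dil <- interior0
  for (w in 0:4) {
    if (w > 0) dil <- culmseg:::dilate1(dil)
    ks <- c(ks, max(separate_and_label(region, bnd0 & !dil, 4)))
  }
  expect_equal(ks[1], 20)
  expect_true(all(diff(ks) <= 0)) # K monotone non-increasing
  expect_lt(ks[length(ks)], 20)   # adjacent cells do merge once walls vanish
})
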
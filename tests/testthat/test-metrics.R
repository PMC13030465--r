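# brute-force pixel-count oracle
counts_oracle <- function(gt, pred) {
  list(tp = sum(gt == 1 & pred == 1), fp = sum(gt == 0 & pred == 1),
       fn = sum(gt == 1 & pred == 0), tn = sum(gt == 0 & pred == 0))
}

test_that("dice and iou match pixel-count oracles on constructed masks", {
  # TP = 3, FP = 1, FN = 1 on a 3x3 grid
  gt <- matrix(c(1, 1, 1, 1, 0, 0, 0, 0, 0), 3, 3)
  pr <- matrix(c(1, 1, 1, 0, 1, 0, 0, 0, 0), 3, 3)
  o <- counts_oracle(gt, pr)
  expect_equal(o$tp, 3); expect_equal(o$fp, 1); expect_equal(o$fn, 1)
  expect_equal(dice_coef(gt, pr, eps = 0), 0.75)
  expect_equal(iou(gt, pr, eps = 0), 0.6)
  expect_equal(dice_coef(gt, pr), dice_coef(pr, gt)) # symmetric
  expect_equal(dice_coef(gt, gt), 1, tolerance = 1e-6)
  expect_equal(iou(gt, gt), 1, tolerance = 1e-4)
  # both-empty convention: smoothed form gives 1
  z <- matrix(0, 2, 2)
  expect_equal(dice_coef(z, z), 1)
  expect_error(dice_coef(matrix(0.4, 2, 2), z), "binary")
})

test_that("the identity dice = 2 iou / (1 + iou) holds on random mask pairs", {
  r <- rng_new(50)
  for (i in 1:50) {
    a <- matrix(with_rng(r, rbinom(100, 1, 0.4)), 10, 10)
    b <- matrix(with_rng(r, rbinom(100, 1, 0.4)), 10, 10)
    if (sum(pmax(a, b)) == 0) next
    d <- dice_coef(a, b, eps = 0)
    j <- iou(a, b, eps = 0)
    expect_equal(d, 2 * j / (1 + j), tolerance = 1e-9)
    expect_gte(d, j)
  }
})

test_that("overall accuracy counts agreeing pixels", {
  a <- matrix(0:1, 10, 10)
  expect_equal(overall_accuracy(a, a), 1)
  b <- a; b[1:10] <- 1 - b[1:10]
  expect_equal(overall_accuracy(a, b), 0.9)
  expect_equal(overall_accuracy(a, 1 - a), 0)
})

test_that("greedy matching picks the higher-confidence prediction", {
  gt <- matrix(0L, 6, 6); gt[2:5, 2:5] <- 1L
  pm <- matrix(0L, 6, 6); pm[2:5, 2:5] <- 1L; pm[1, 1] <- 2L
  gts <- inst_from(gt)
  # pred 1 and pred 2 both overlap gt 1? only pred 1 does; single-pair case
  prs <- inst_from(pm, confidence = c(0.9, 0.8))
  mr <- match_instances(prs, gts, t = 0.5)
  expect_equal(nrow(mr$pairs), 1)
  expect_equal(mr$pairs$iou, 1)
  expect_equal(mr$unmatched_pred, 2)

  # two overlapping preds on one gt: higher confidence wins
  pm2 <- matrix(0L, 6, 6); pm2[2:5, 2:4] <- 1L; pm2[2:5, 5] <- 2L
  prs2 <- inst_from(pm2, confidence = c(0.4, 0.9))
  mr2 <- match_instances(prs2, gts, t = 0.2)
  expect_equal(mr2$pairs$pred_id, 2) # higher confidence matched first
  expect_equal(mr2$unmatched_pred, 1) # gt already taken
})

test_that("greedy equals exhaustive assignment on small fixtures", {
  # exhaustive oracle over permutations for <= 3 x 3 problems
  best_assignment <- function(m, t) {
    kp <- nrow(m); kg <- ncol(m)
    best <- 0
    for (perm in combinat_perms(kg)) {
      tot <- 0
      for (pi in seq_len(min(kp, kg))) {
        v <- m[pi, perm[pi]]
        if (v >= t) tot <- tot + 1
      }
      best <- max(best, tot)
    }
    best
  }
  combinat_perms <- function(n) {
    if (n == 1) return(list(1L))
    out <- list()
    for (i in seq_len(n)) {
      for (p in combinat_perms(n - 1L)) {
        out[[length(out) + 1L]] <- c(i, ifelse(p >= i, p + 1L, p))
      }
    }
    out
  }
  r <- rng_new(60)
  for (rep in 1:10) {
    lab_g <- matrix(0L, 9, 9)
    lab_g[2:4, 2:4] <- 1L; lab_g[6:8, 2:4] <- 2L; lab_g[2:4, 6:8] <- 3L
    lab_p <- matrix(0L, 9, 9)
    sh <- with_rng(r, sample(0:1, 3, TRUE))
    lab_p[(2:4) + sh[1], 2:4] <- 1L
    lab_p[(6:8) - sh[2], 2:4] <- 2L
    lab_p[2:4, (6:8) - sh[3]] <- 3L
    prs <- inst_from(lab_p, confidence = with_rng(r, runif(3)))
    gts <- inst_from(lab_g)
    m <- culmseg:::instance_iou_matrix(lab_p, lab_g)
    for (t in c(0.3, 0.5, 0.75)) {
      mr <- match_instances(prs, gts, t = t)
      expect_equal(nrow(mr$pairs), best_assignment(m, t))
      mh <- match_instances(prs, gts, t = t, method = "hungarian")
      expect_equal(nrow(mh$pairs), best_assignment(m, t))
    }
  }
})

test_that("mask mAP: perfect match gives 1; IoU 0.6 fixture gives exactly 0.3", {
  gt <- matrix(0L, 8, 8); gt[2:5, 2:5] <- 1L
  g <- inst_from(gt)
  mm <- mask_map(inst_from(gt, confidence = 0.9), g)
  expect_equal(unname(mm$per_threshold_ap), rep(1, 10))
  expect_equal(mm$map_50_95, 1)

  # one pred with IoU exactly 0.60: gt 4 px strip, pred 4 px strip, inter 3
  gt2 <- matrix(0L, 8, 8); gt2[1:4, 1] <- 1L
  pd2 <- matrix(0L, 8, 8); pd2[2:5, 1] <- 1L
  expect_equal(iou(gt2, pd2, eps = 0), 0.6)
  mm2 <- mask_map(inst_from(pd2, confidence = 0.8), inst_from(gt2))
  expect_equal(unname(mm2$per_threshold_ap), c(1, 1, 1, rep(0, 7)))
  expect_equal(mm2$map_50_95, 0.3)
  expect_equal(mm2$map_50_95, mean(mm2$per_threshold_ap))
})

test_that("mask mAP is invariant to relabeling and prediction order", {
  s <- tiny_tissue(seed = 33, n_cells = 6)
  tg <- derive_targets(s)
  lab <- separate_and_label(s$class_mask > 0, tg$boundary == 1)
  r <- rng_new(70)
  conf <- with_rng(r, runif(max(lab)))
  p1 <- inst_from(lab, confidence = conf)
  base <- mask_map(p1, inst_from(s$instance_map))$map_50_95
  # permute instance ids
  perm <- with_rng(r, sample(max(lab)))
  lab2 <- lab; lab2[lab > 0] <- perm[lab[lab > 0]]
  p2 <- inst_from(lab2, confidence = conf[order(perm)])
  expect_equal(mask_map(p2, inst_from(s$instance_map))$map_50_95, base)
})

test_that("empty ground truth with predictions scores zero", {
  pd <- matrix(0L, 4, 4); pd[1:2, 1:2] <- 1L
  mm <- mask_map(inst_from(pd, confidence = 0.7),
                 inst_from(matrix(0L, 4, 4)), class_aware = FALSE)
  expect_equal(unname(mm$per_threshold_ap), rep(0, 10))
})

test_that("evaluate_segmentation reports a full metrics block", {
  s <- tiny_tissue(seed = 44, n_cells = 6)
  rep_ <- evaluate_segmentation(s$class_mask, s$class_mask,
                                inst_from(s$instance_map),
                                inst_from(s$instance_map))
  expect_equal(rep_$dice, 1, tolerance = 1e-5)
  expect_equal(rep_$iou, 1, tolerance = 1e-4)
  expect_equal(rep_$overall_accuracy, 1)
  expect_equal(rep_$map_50_95, 1)
})
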
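#' Dice coefficient
#'
#' Smoothed overlap statistic
#' `(2 * sum(y * yhat) + eps) / (sum(y) + sum(yhat) + eps)`. On binary masks
#' this equals `2 TP / (2 TP + FP + FN + eps)`. With both masks empty the
#' smoothed form evaluates to 1 (perfect agreement convention).
#'
#' @param gt,pred binary masks of equal shape (values in `{0, 1}`).
#' @param eps smoothing constant (set to 0 for the exact unsmoothed value).
#' @return scalar in `[0, 1]`; symmetric in its mask arguments.
#' @export
dice_coef <- function(gt, pred, eps = 1e-6) {
  check_same_shape(gt, pred)
  if (!all(gt %in% c(0, 1)) || !all(pred %in% c(0, 1))) {
    stop("dice_coef expects binary masks")
  }
  (2 * sum(gt * pred) + eps) / (sum(gt) + sum(pred) + eps)
}

#' Intersection over union
#'
#' Soft min/max form `sum(pmin(y, yhat)) / (sum(pmax(y, yhat)) + eps)`,
#' which on binary masks reduces to `TP / (TP + FP + FN + eps)`. Values in
#' `[0, 1]` are accepted (soft masks allowed).
#'
#' @param gt,pred masks of equal shape with values in `[0, 1]`.
#' @param eps smoothing constant.
#' @return scalar in `[0, 1]`.
#' @export
iou <- function(gt, pred, eps = 1e-6) {
  check_same_shape(gt, pred)
  sum(pmin(gt, pred)) / (sum(pmax(gt, pred)) + eps)
}

#' Overall pixel accuracy
#'
#' Fraction of exactly agreeing pixels; equals `(TP + TN) / N` for binary
#' maps and extends unchanged to multi-class label maps.
#'
#' @param gt,pred label maps of equal shape.
#' @return scalar in `[0, 1]`.
#' @export
overall_accuracy <- function(gt, pred) {
  check_same_shape(gt, pred)
  mean(gt == pred)
}

#' Construct an instance set
#'
#' A labeled instance map plus one record per instance (id, class,
#' confidence, area). When `records` is omitted they are synthesized from
#' the label map (class from `class_mask` majority or 1, confidence 1).
#'
#' @param label_map `H x W` matrix of non-negative integers, positive labels
#'   consecutive `1..K`.
#' @param records data frame with columns `id`, `class`, `confidence`,
#'   `area`, or `NULL`.
#' @param class_mask optional class mask used to derive classes.
#' @return an object of class `instance_set`.
#' @export
instance_set <- function(label_map, records = NULL, class_mask = NULL) {
  stopifnot(is.matrix(label_map), all(label_map >= 0))
  lab <- matrix(as.integer(label_map), nrow(label_map))
  ids <- sort(unique(lab[lab > 0L]))
  if (length(ids) && !identical(as.integer(ids), seq_along(ids))) {
    stop("instance labels must be consecutive 1..K")
  }
  k <- length(ids)
  areas <- tabulate(lab[lab > 0L], nbins = k)
  if (is.null(records)) {
    cls <- rep(1L, k)
    if (!is.null(class_mask) && k > 0) {
      for (i in seq_len(k)) {
        cl <- class_mask[lab == i]
        cl <- cl[cl > 0]
        cls[i] <- if (length(cl)) as.integer(names(which.max(table(cl)))) else 1L
      }
    }
    records <- data.frame(id = ids, class = cls, confidence = rep(1, k),
                          area = areas)
  } else {
    stopifnot(all(c("id", "class", "confidence", "area") %in% names(records)))
    if (anyDuplicated(records$id)) stop("duplicate instance ids")
    if (!identical(as.integer(sort(records$id)), as.integer(ids))) {
      stop("records do not match label_map ids")
    }
    records <- records[order(records$id), , drop = FALSE]
    if (!identical(as.integer(records$area), as.integer(areas))) {
      stop("record areas disagree with the label map")
    }
  }
  structure(list(label_map = lab, records = records), class = "instance_set")
}

#' @export
print.instance_set <- function(x, ...) {
  cat(sprintf("<instance_set> %d instances on %d x %d\n",
              nrow(x$records), nrow(x$label_map), ncol(x$label_map)))
  invisible(x)
}

# Pairwise IoU matrix between the instances of two label maps.
instance_iou_matrix <- function(pred_map, gt_map) {
  kp <- max(pred_map); kg <- max(gt_map)
  inter <- matrix(0, kp, kg)
  both <- pred_map > 0L & gt_map > 0L
  if (any(both)) {
    tb <- table(factor(pred_map[both], levels = seq_len(kp)),
                factor(gt_map[both], levels = seq_len(kg)))
    inter <- matrix(as.numeric(tb), kp, kg)
  }
  ap <- tabulate(pred_map[pred_map > 0L], nbins = kp)
  ag <- tabulate(gt_map[gt_map > 0L], nbins = kg)
  un <- outer(ap, ag, "+") - inter
  ifelse(un > 0, inter / un, 0)
}

#' Match predicted instances to ground truth
#'
#' Greedy matching iterates predictions in descending confidence (ties by
#' ascending id) and assigns each to the unmatched ground-truth instance of
#' maximal IoU, provided that IoU is at least `t` (inclusive). Hungarian
#' matching solves the maximum-weight one-to-one assignment on the IoU
#' matrix (via weighted bipartite matching) and then discards pairs below
#' `t`.
#'
#' @param pred,gt [instance_set()] objects.
#' @param t IoU threshold in `[0, 1]`.
#' @param method `"greedy"` (default) or `"hungarian"`.
#' @return an object of class `match_result`: a `pairs` data frame
#'   (`pred_id`, `gt_id`, `iou`), `unmatched_pred`, `unmatched_gt`, and the
#'   threshold used.
#' @export
match_instances <- function(pred, gt, t = 0.5,
                            method = c("greedy", "hungarian")) {
  method <- match.arg(method)
  stopifnot(inherits(pred, "instance_set"), inherits(gt, "instance_set"))
  kp <- nrow(pred$records); kg <- nrow(gt$records)
  pairs <- data.frame(pred_id = integer(0), gt_id = integer(0),
                      iou = numeric(0))
  if (kp > 0 && kg > 0) {
    m <- instance_iou_matrix(pred$label_map, gt$label_map)
    if (method == "greedy") {
      ord <- order(-pred$records$confidence, pred$records$id)
      taken <- rep(FALSE, kg)
      for (pi in pred$records$id[ord]) {
        avail <- which(!taken & m[pi, ] >= t)
        if (!length(avail)) next
        gi <- avail[which.max(m[pi, avail])]
        taken[gi] <- TRUE
        pairs[nrow(pairs) + 1L, ] <- c(pi, gi, m[pi, gi])
      }
    } else {
      el <- which(m > 0, arr.ind = TRUE)
      if (nrow(el)) {
        g <- igraph::make_bipartite_graph(
          types = c(rep(FALSE, kp), rep(TRUE, kg)),
          edges = as.vector(t(cbind(el[, 1], kp + el[, 2]))))
        igraph::E(g)$weight <- m[el]
        mt <- igraph::max_bipartite_match(g)$matching
        for (pi in seq_len(kp)) {
          gi <- mt[pi]
          if (is.na(gi)) next
          gi <- as.integer(gi) - kp
          if (m[pi, gi] >= t) {
            pairs[nrow(pairs) + 1L, ] <- c(pi, gi, m[pi, gi])
          }
        }
      }
    }
  }
  structure(list(pairs = pairs,
                 unmatched_pred = setdiff(pred$records$id, pairs$pred_id),
                 unmatched_gt = setdiff(gt$records$id, pairs$gt_id),
                 threshold = t),
            class = "match_result")
}

# Average precision at one IoU threshold via the all-point interpolated
# precision-recall curve. preds: data frame (confidence, image, id);
# iou_list: per-image IoU matrices; gts per image counts.
ap_at_threshold <- function(conf, img, pid, iou_mats, gt_counts, t) {
  n_gt <- sum(gt_counts)
  if (n_gt == 0) return(if (length(conf)) 0 else NA_real_)
  if (!length(conf)) return(0)
  ord <- order(-conf, img, pid)
  taken <- lapply(gt_counts, function(k) rep(FALSE, k))
  tp <- numeric(length(ord))
  for (i in seq_along(ord)) {
    j <- ord[i]
    m <- iou_mats[[img[j]]]
    if (is.null(m) || ncol(m) == 0) next
    avail <- which(!taken[[img[j]]] & m[pid[j], ] >= t)
    if (length(avail)) {
      gi <- avail[which.max(m[pid[j], avail])]
      taken[[img[j]]][gi] <- TRUE
      tp[i] <- 1
    }
  }
  ctp <- cumsum(tp)
  cfp <- cumsum(1 - tp)
  recall <- ctp / n_gt
  precision <- ctp / (ctp + cfp)
  # all-point interpolation: running max of precision from the right
  penv <- rev(cummax(rev(precision)))
  r_prev <- c(0, head(recall, -1))
  sum((recall - r_prev) * penv)
}

#' Mask mean average precision over IoU thresholds 0.50-0.95
#'
#' For each threshold `t` in `{0.50, 0.55, ..., 0.95}` the average precision
#' is the area under the all-point interpolated precision-recall curve built
#' by sweeping predictions in descending confidence, matching each to the
#' best unmatched ground-truth mask with IoU >= t (inclusive). The final
#' score is the mean of the ten per-threshold APs. By default AP is computed
#' per class and averaged over the classes present in the ground truth;
#' `class_aware = FALSE` pools all instances. Empty ground truth with
#' predictions present scores 0 at every threshold.
#'
#' @param pred,gt [instance_set()] objects, or lists of them (paired by
#'   position) for corpus-level evaluation.
#' @param thresholds IoU thresholds (default the ten-value grid).
#' @param class_aware average per-class APs (default `TRUE`).
#' @return list with `per_threshold_ap` (named vector) and `map_50_95`
#'   (their mean).
#' @export
mask_map <- function(pred, gt, thresholds = seq(0.5, 0.95, by = 0.05),
                     class_aware = TRUE) {
  if (inherits(pred, "instance_set")) pred <- list(pred)
  if (inherits(gt, "instance_set")) gt <- list(gt)
  stopifnot(length(pred) == length(gt))
  classes <- if (class_aware) {
    sort(unique(unlist(lapply(gt, function(g) g$records$class))))
  } else 0L
  if (!length(classes)) classes <- 0L

  per_t <- vapply(thresholds, function(t) {
    aps <- vapply(classes, function(cl) {
      conf <- numeric(0); img <- integer(0); pid <- integer(0)
      iou_mats <- vector("list", length(pred))
      gt_counts <- integer(length(pred))
      for (i in seq_along(pred)) {
        pr <- pred[[i]]$records
        gr <- gt[[i]]$records
        if (class_aware) {
          psel <- pr$id[pr$class == cl]
          gsel <- gr$id[gr$class == cl]
        } else {
          psel <- pr$id
          gsel <- gr$id
        }
        gt_counts[i] <- length(gsel)
        if (length(psel) && length(gsel)) {
          m <- instance_iou_matrix(pred[[i]]$label_map, gt[[i]]$label_map)
          iou_mats[[i]] <- m[psel, gsel, drop = FALSE]
        } else if (length(psel)) {
          iou_mats[[i]] <- matrix(0, length(psel), 0)
        }
        if (length(psel)) {
          conf <- c(conf, pr$confidence[match(psel, pr$id)])
          img <- c(img, rep(i, length(psel)))
          pid <- c(pid, seq_along(psel))
        }
      }
      ap_at_threshold(conf, img, pid, iou_mats, gt_counts, t)
    }, numeric(1))
    aps <- aps[!is.na(aps)]
    if (length(aps)) mean(aps) else NA_real_
  }, numeric(1))
  names(per_t) <- sprintf("AP%.2f", thresholds)
  list(per_threshold_ap = per_t, map_50_95 = mean(per_t))
}

#' Full evaluation of a prediction against ground truth
#'
#' Pixel-level Dice and IoU are computed on the cell-foreground masks
#' (class > 0), overall accuracy on the full class maps, and mask mAP on the
#' instance sets.
#'
#' @param pred_class,gt_class `H x W` class label maps.
#' @param pred_instances,gt_instances [instance_set()] objects (optional;
#'   omit to skip the mAP block).
#' @param eps smoothing constant for Dice/IoU.
#' @return an object of class `metrics_report`: `dice`, `iou`,
#'   `overall_accuracy`, and (when instances are given) `per_threshold_ap`
#'   and `map_50_95`.
#' @export
evaluate_segmentation <- function(pred_class, gt_class,
                                  pred_instances = NULL, gt_instances = NULL,
                                  eps = 1e-6) {
  fg_p <- (pred_class > 0) * 1
  fg_g <- (gt_class > 0) * 1
  rep_ <- list(dice = dice_coef(fg_g, fg_p, eps),
               iou = iou(fg_g, fg_p, eps),
               overall_accuracy = overall_accuracy(gt_class, pred_class))
  if (!is.null(pred_instances) && !is.null(gt_instances)) {
    mm <- mask_map(pred_instances, gt_instances)
    rep_$per_threshold_ap <- mm$per_threshold_ap
    rep_$map_50_95 <- mm$map_50_95
  }
  structure(rep_, class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  cat(sprintf("Dice %.4f  IoU %.4f  OA %.4f", x$dice, x$iou,
              x$overall_accuracy))
  if (!is.null(x$map_50_95)) cat(sprintf("  mAP50-95 %.4f", x$map_50_95))
  cat("\n")
  invisible(x)
}
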
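#' Discretize probability maps
#'
#' The region mask is the pixelwise maximum of the two cell-class semantic
#' channels (parenchyma, vascular) thresholded at `threshold` (inclusive
#' `>=`); the boundary mask thresholds the boundary probability map the same
#' way.
#'
#' @param predictions a `predictions` object (semantic `H x W x 3`,
#'   `boundary`, `interior`).
#' @param threshold probability threshold in `(0, 1)`, default 0.5.
#' @return list with logical matrices `region` and `boundary`.
#' @export
discretize <- function(predictions, threshold = 0.5) {
  stopifnot(threshold > 0, threshold < 1)
  cellp <- pmax(predictions$semantic[, , 2], predictions$semantic[, , 3])
  list(region = cellp >= threshold,
       boundary = predictions$boundary >= threshold)
}

#' Separate adhered regions by predicted boundaries and label instances
#'
#' Removes boundary pixels from the region mask (interiors =
#' `region & !boundary`) so that densely adhered cells fall apart along the
#' predicted walls, then labels connected components `1..K` in raster-scan
#' discovery order.
#'
#' @param region,boundary logical matrices of equal shape.
#' @param connectivity 4 (default) or 8. 4-connectivity prevents labels
#'   leaking diagonally across one-pixel walls.
#' @return integer label matrix.
#' @export
separate_and_label <- function(region, boundary, connectivity = 4) {
  check_same_shape(region, boundary)
  stopifnot(connectivity %in% c(4, 8))
  interiors <- region & !boundary
  label_components_cpp(interiors, as.integer(connectivity))
}

#' Reassign wall pixels to their nearest instance
#'
#' With `mode = "nearest"`, every region-positive pixel left unlabeled
#' (typically the boundary band) is assigned to the geodesically nearest
#' instance by iterative label dilation inside the region mask until a
#' fixpoint; ties go to the first neighbor in the fixed order N, S, W, E,
#' NW, SW, NE, SE. With `mode = "off"` the label map passes through
#' unchanged.
#'
#' @param label_map integer label matrix from [separate_and_label()].
#' @param region logical region mask.
#' @param mode `"off"` (default) or `"nearest"`.
#' @return integer label matrix.
#' @export
reclaim_boundary <- function(label_map, region, mode = c("off", "nearest")) {
  mode <- match.arg(mode)
  if (mode == "off") return(label_map)
  h <- nrow(label_map); w <- ncol(label_map)
  lab <- label_map
  offs <- list(c(-1L, 0L), c(1L, 0L), c(0L, -1L), c(0L, 1L),
               c(-1L, -1L), c(1L, -1L), c(-1L, 1L), c(1L, 1L))
  repeat {
    todo <- which(region & lab == 0L)
    if (!length(todo)) break
    pad <- matrix(0L, h + 2, w + 2)
    pad[2:(h + 1), 2:(w + 1)] <- lab
    newlab <- rep(0L, length(todo))
    ti <- (todo - 1L) %% h + 1L
    tj <- (todo - 1L) %/% h + 1L
    for (o in rev(offs)) {
      nb <- pad[cbind(ti + 1L + o[1], tj + 1L + o[2])]
      newlab[nb > 0L] <- nb[nb > 0L]
    }
    if (!any(newlab > 0L)) break # isolated region pixels with no labels at all
    lab[todo[newlab > 0L]] <- newlab[newlab > 0L]
  }
  lab
}

#' Score and classify labeled instances
#'
#' Per instance: the confidence is the mean over its pixels of the maximum
#' cell-class semantic probability; the class is 1 (parenchyma) or 2
#' (vascular) by the larger summed class probability over its pixels.
#'
#' @param label_map integer label matrix (consecutive labels `1..K`).
#' @param predictions a `predictions` object.
#' @return an [instance_set()].
#' @export
score_and_class <- function(label_map, predictions) {
  check_same_shape(label_map, predictions$boundary)
  k <- max(label_map)
  if (k == 0) {
    return(instance_set(label_map,
                        records = data.frame(id = integer(0), class = integer(0),
                                             confidence = numeric(0),
                                             area = integer(0))))
  }
  pos <- label_map > 0L
  lab <- label_map[pos]
  p1 <- predictions$semantic[, , 2][pos]
  p2 <- predictions$semantic[, , 3][pos]
  cellmax <- pmax(p1, p2)
  areas <- tabulate(lab, nbins = k)
  conf <- as.vector(rowsum(cellmax, lab)) / areas
  s1 <- as.vector(rowsum(p1, lab))
  s2 <- as.vector(rowsum(p2, lab))
  cls <- ifelse(s2 > s1, 2L, 1L)
  instance_set(label_map,
               records = data.frame(id = seq_len(k), class = cls,
                                    confidence = conf, area = areas))
}

#' Remove small instances
#'
#' Drops instances whose pixel area is below `min_area` and compacts the
#' surviving ids to `1..K'`.
#'
#' @param instances an [instance_set()].
#' @param min_area minimum area in pixels (>= 0).
#' @return a filtered [instance_set()].
#' @export
size_filter <- function(instances, min_area) {
  stopifnot(inherits(instances, "instance_set"), min_area >= 0)
  keep <- instances$records$area >= min_area
  if (all(keep)) return(instances)
  old <- instances$records$id[keep]
  lut <- integer(max(instances$records$id, 1L))
  lut[old] <- seq_along(old)
  lab <- instances$label_map
  drop <- lab > 0L & !(lab %in% old)
  lab[drop] <- 0L
  lab[lab > 0L] <- lut[lab[lab > 0L]]
  rec <- instances$records[keep, , drop = FALSE]
  rec$id <- seq_along(old)
  rownames(rec) <- NULL
  instance_set(lab, records = rec)
}

#' Boundary-guided instance extraction, end to end
#'
#' Convenience wrapper chaining [discretize()], [separate_and_label()],
#' optionally [reclaim_boundary()], [score_and_class()] and [size_filter()].
#'
#' @param predictions a `predictions` object.
#' @param threshold discretization threshold.
#' @param connectivity component connectivity (4 or 8).
#' @param reclaim `"off"` or `"nearest"`.
#' @param min_area suppression threshold for speckle components.
#' @return an [instance_set()].
#' @export
extract_instances <- function(predictions, threshold = 0.5, connectivity = 4,
                              reclaim = "off", min_area = 0) {
  dm <- discretize(predictions, threshold)
  lab <- separate_and_label(dm$region, dm$boundary, connectivity)
  lab <- reclaim_boundary(lab, dm$region, mode = reclaim)
  inst <- score_and_class(lab, predictions)
  size_filter(inst, min_area)
}
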
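#' Read / write RGB images
#'
#' Images are stored as 8-bit RGB PNG or TIFF; values are quantized to
#' 1/255 steps on write (writing an already 8-bit-quantized image round-trips
#' exactly). Coordinates are pixel-center, row-major, 0-based throughout the
#' package's file formats.
#'
#' @param path file path; format chosen by extension (`.png`, `.tif`,
#'   `.tiff`).
#' @param image `H x W x 3` array in `[0, 1]`.
#' @return `read_image` returns the array; `write_image` the path,
#'   invisibly.
#' @export
read_image <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  img <- if (grepl("\\.png$", path, ignore.case = TRUE)) {
    png::readPNG(path)
  } else {
    tiff::readTIFF(path)
  }
  if (length(dim(img)) == 2) img <- array(rep(img, 3), c(dim(img), 3))
  img[, , 1:3, drop = FALSE]
}

#' @rdname read_image
#' @export
write_image <- function(image, path) {
  img <- round(image * 255) / 255
  if (grepl("\\.png$", path, ignore.case = TRUE)) {
    png::writePNG(img, path)
  } else {
    tiff::writeTIFF(img, path, bits.per.sample = 8L)
  }
  invisible(path)
}

#' Read / write 16-bit label maps
#'
#' Class masks and instance maps are stored as single-channel 16-bit TIFF
#' (losslessly; labels up to 65535). Round-trips are bit-exact.
#'
#' @param label_map `H x W` non-negative integer matrix (values < 65536).
#' @param path file path (`.tif` / `.tiff`).
#' @return `read_label_map` returns an integer matrix; `write_label_map`
#'   the path, invisibly.
#' @export
read_label_map <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  m <- tiff::readTIFF(path)
  if (length(dim(m)) == 3) m <- m[, , 1]
  matrix(as.integer(round(m * 65535)), nrow(m))
}

#' @rdname read_label_map
#' @export
write_label_map <- function(label_map, path) {
  if (any(label_map < 0) || any(label_map > 65535)) {
    stop("label values must lie in 0..65535")
  }
  tiff::writeTIFF(label_map / 65535, path, bits.per.sample = 16L,
                  compression = "none")
  invisible(path)
}

#' Write / read an image sample as files
#'
#' One sample becomes four sidecar files: `<id>_image.png` (8-bit RGB),
#' `<id>_class.tif` and `<id>_instance.tif` (16-bit), and `<id>_meta.json`.
#'
#' @param sample an [image_sample()].
#' @param dir directory.
#' @param id sample identifier used as the filename stem.
#' @return `write_sample` returns the four paths invisibly; `read_sample`
#'   the reconstructed [image_sample()].
#' @export
write_sample <- function(sample, dir, id) {
  stopifnot(inherits(sample, "image_sample"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- file.path(dir, paste0(id, c("_image.png", "_class.tif",
                                       "_instance.tif", "_meta.json")))
  write_image(sample$image, paths[1])
  write_label_map(sample$class_mask, paths[2])
  write_label_map(sample$instance_map, paths[3])
  jsonlite::write_json(sample$meta, paths[4], auto_unbox = TRUE, digits = NA)
  invisible(paths)
}

#' @rdname write_sample
#' @export
read_sample <- function(dir, id) {
  image_sample(read_image(file.path(dir, paste0(id, "_image.png"))),
               read_label_map(file.path(dir, paste0(id, "_class.tif"))),
               read_label_map(file.path(dir, paste0(id, "_instance.tif"))),
               meta = jsonlite::read_json(file.path(dir, paste0(id, "_meta.json")),
                                          simplifyVector = TRUE))
}

# Even-odd (crossing number) point-in-polygon rasterizer over the closed
# region: pixels whose centers fall inside or exactly on an edge are
# included. Vertices in (x, y) with 0-based pixel-center coordinates: pixel
# (row r, col c) has center (x = c - 1, y = r - 1).
rasterize_polygon <- function(xy, h, w) {
  px <- rep(0:(w - 1), each = h)
  py <- rep(0:(h - 1), times = w)
  nv <- nrow(xy)
  inside <- rep(FALSE, h * w)
  onedge <- rep(FALSE, h * w)
  tol <- 1e-9
  j <- nv
  for (i in seq_len(nv)) {
    xi <- xy[i, 1]; yi <- xy[i, 2]
    xj <- xy[j, 1]; yj <- xy[j, 2]
    crosses <- ((yi > py) != (yj > py)) &
      (px < (xj - xi) * (py - yi) / (yj - yi) + xi)
    inside <- xor(inside, crosses)
    onedge <- onedge |
      (abs((px - xi) * (yj - yi) - (py - yi) * (xj - xi)) < tol &
         px >= pmin(xi, xj) - tol & px <= pmax(xi, xj) + tol &
         py >= pmin(yi, yj) - tol & py <= pmax(yi, yj) + tol)
    j <- i
  }
  matrix(inside | onedge, h, w)
}

labelme_classes <- c("parenchyma" = 1L, "parenchyma cell" = 1L,
                     "vascular bundle" = 2L, "vascular" = 2L)

#' Read LabelMe-style polygon annotations
#'
#' Parses a LabelMe JSON file (fields beyond `shapes`/`label`/`points` and
#' the image size are ignored) and rasterizes the polygons into instance and
#' class maps. Later polygons overwrite earlier ones where they overlap.
#' Accepted labels: "parenchyma" / "parenchyma cell" (class 1),
#' "vascular bundle" / "vascular" (class 2).
#'
#' @param path JSON file path.
#' @param height,width canvas size; defaults to the file's
#'   `imageHeight`/`imageWidth`.
#' @return an [image_sample()] with a neutral (all-0.5) image and the
#'   rasterized masks.
#' @export
read_labelme_json <- function(path, height = NULL, width = NULL) {
  if (!file.exists(path)) stop("no such file: ", path)
  js <- tryCatch(jsonlite::read_json(path),
                 error = function(e) stop("malformed JSON in ", path, ": ",
                                          conditionMessage(e)))
  h <- height %||% js$imageHeight
  w <- width %||% js$imageWidth
  if (is.null(h) || is.null(w)) stop("canvas size missing (imageHeight/imageWidth)")
  inst <- matrix(0L, h, w)
  cls <- matrix(0L, h, w)
  shapes <- js$shapes %||% list()
  k <- 0L
  for (sh in shapes) {
    lab <- sh$label
    if (is.null(lab) || !lab %in% names(labelme_classes)) {
      stop("unknown class label '", lab, "'; accepted: ",
           paste(names(labelme_classes), collapse = ", "))
    }
    xy <- do.call(rbind, lapply(sh$points, function(p) as.numeric(unlist(p))))
    k <- k + 1L
    m <- rasterize_polygon(xy, h, w)
    inst[m] <- k
    cls[m] <- labelme_classes[[lab]]
  }
  inst <- relabel_consecutive(inst) # overlap may erase earlier polygons
  image_sample(array(0.5, c(h, w, 3)), cls, inst,
               meta = list(source = path, format = "labelme"))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Moore-neighbor contour tracing of one binary mask; returns (x, y) vertices
# in 0-based pixel-center coordinates.
trace_contour <- function(mask) {
  pix <- which(mask, arr.ind = TRUE)
  if (nrow(pix) == 1) {
    return(cbind(x = pix[1, 2] - 1, y = pix[1, 1] - 1))
  }
  start <- pix[order(pix[, 2], pix[, 1])[1], ] # leftmost column, then top
  h <- nrow(mask); w <- ncol(mask)
  at <- function(i, j) i >= 1 && i <= h && j >= 1 && j <= w && mask[i, j]
  # Moore neighborhood in clockwise order starting from W
  nb <- list(c(0, -1), c(-1, -1), c(-1, 0), c(-1, 1),
             c(0, 1), c(1, 1), c(1, 0), c(1, -1))
  cur <- start
  back <- 1L # came from the west
  path <- list(start)
  repeat {
    found <- FALSE
    for (step in seq_len(8)) {
      k <- ((back - 1L + step - 1L) %% 8L) + 1L
      ni <- cur[1] + nb[[k]][1]
      nj <- cur[2] + nb[[k]][2]
      if (at(ni, nj)) {
        back <- ((k - 1L + 4L + 1L) %% 8L) + 1L # opposite direction, advanced one
        cur <- c(ni, nj)
        path[[length(path) + 1L]] <- cur
        found <- TRUE
        break
      }
    }
    if (!found) break
    if (all(cur == start) && length(path) > 2) break
  }
  m <- do.call(rbind, path)
  if (nrow(m) > 1 && all(m[nrow(m), ] == m[1, ])) m <- m[-nrow(m), , drop = FALSE]
  cbind(x = m[, 2] - 1, y = m[, 1] - 1)
}

#' Write instances as LabelMe-style polygon JSON
#'
#' Traces the outer contour of every instance (straight-line connections
#' between successive coordinate points form the closed contours) and writes
#' a LabelMe-compatible shape list.
#'
#' @param instances an [instance_set()].
#' @param path output JSON path.
#' @return the path, invisibly.
#' @export
write_labelme_json <- function(instances, path) {
  stopifnot(inherits(instances, "instance_set"))
  lm <- instances$label_map
  shapes <- lapply(instances$records$id, function(i) {
    xy <- trace_contour(lm == i)
    list(label = ifelse(instances$records$class[instances$records$id == i] == 2L,
                        "vascular bundle", "parenchyma"),
         points = lapply(seq_len(nrow(xy)), function(r) as.numeric(xy[r, ])),
         shape_type = "polygon")
  })
  jsonlite::write_json(list(version = "5.2.1", shapes = shapes,
                            imageHeight = nrow(lm), imageWidth = ncol(lm)),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read plain-text contour files
#'
#' One instance per block (blocks separated by blank lines); each line holds
#' whitespace- or comma-separated coordinate pairs `x y`. Closure between
#' the last and first vertex is implicit.
#'
#' @param path text file path.
#' @return list of two-column `(x, y)` vertex matrices.
#' @export
read_contour_txt <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path)
  polys <- list()
  cur <- list()
  flush <- function() {
    if (length(cur)) {
      polys[[length(polys) + 1L]] <<- do.call(rbind, cur)
      cur <<- list()
    }
  }
  for (ln in seq_along(lines)) {
    txt <- trimws(lines[ln])
    if (txt == "") { flush(); next }
    tok <- as.numeric(strsplit(txt, "[,[:space:]]+")[[1]])
    if (anyNA(tok)) stop("non-numeric token on line ", ln)
    if (length(tok) %% 2 != 0) {
      stop("odd coordinate count on line ", ln)
    }
    cur[[length(cur) + 1L]] <- matrix(tok, ncol = 2, byrow = TRUE,
                                      dimnames = list(NULL, c("x", "y")))
  }
  flush()
  polys
}

#' @rdname read_contour_txt
#' @param polys list of vertex matrices.
#' @export
write_contour_txt <- function(polys, path) {
  blocks <- vapply(polys, function(p) {
    paste(apply(p, 1, function(r) paste(r, collapse = " ")), collapse = "\n")
  }, character(1))
  writeLines(paste(blocks, collapse = "\n\n"), path)
  invisible(path)
}

#' Rasterize polygon contours into an image sample
#'
#' @param polys list of `(x, y)` vertex matrices (0-based pixel centers).
#' @param height,width canvas size.
#' @param classes integer class per polygon (default all parenchyma).
#' @return an [image_sample()].
#' @export
polygons_to_sample <- function(polys, height, width, classes = NULL) {
  if (is.null(classes)) classes <- rep(1L, length(polys))
  inst <- matrix(0L, height, width)
  cls <- matrix(0L, height, width)
  for (i in seq_along(polys)) {
    m <- rasterize_polygon(polys[[i]], height, width)
    inst[m] <- i
    cls[m] <- classes[i]
  }
  inst <- relabel_consecutive(inst)
  image_sample(array(0.5, c(height, width, 3)), cls, inst,
               meta = list(format = "contours"))
}

#' Run configuration
#'
#' Bundles the network, augmentation and loss configurations with training
#' and evaluation options. Training defaults: 150 epochs, batch size 12,
#' initial learning rate 1e-4, decay 1e-15, RMSprop.
#'
#' @param data_root,output_dir paths.
#' @param network a [network_config()].
#' @param augment an [augment_config()].
#' @param loss a [loss_config()].
#' @param epochs,batch_size,learning_rate,decay,optimizer training options.
#' @param threshold,connectivity,matcher evaluation options.
#' @param seed global seed fanned out per stage via [rng_for_stage()].
#' @return an object of class `run_config`.
#' @export
run_config <- function(data_root = ".", output_dir = "out",
                       network = network_config(),
                       augment = augment_config(),
                       loss = loss_config(),
                       epochs = 150, batch_size = 12,
                       learning_rate = 1e-4, decay = 1e-15,
                       optimizer = "rmsprop",
                       threshold = 0.5, connectivity = 4,
                       matcher = "greedy", seed = 1) {
  structure(list(data_root = data_root, output_dir = output_dir,
                 network = network, augment = augment, loss = loss,
                 training = list(epochs = epochs, batch_size = batch_size,
                                 learning_rate = learning_rate, decay = decay,
                                 optimizer = optimizer),
                 eval = list(threshold = threshold,
                             connectivity = connectivity, matcher = matcher),
                 seed = as.integer(seed)),
            class = "run_config")
}

#' Read / write a run configuration as YAML
#'
#' `read_run_config(write_run_config(cfg, path))` returns a normalized,
#' fully populated configuration: missing fields take their defaults.
#'
#' @param cfg a [run_config()].
#' @param path YAML file path.
#' @return `write_run_config` the path invisibly; `read_run_config` a
#'   `run_config`.
#' @export
write_run_config <- function(cfg, path) {
  plain <- rapply(unclass(cfg), unclass, how = "replace")
  yaml::write_yaml(plain, path)
  invisible(path)
}

#' @rdname write_run_config
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  y <- yaml::read_yaml(path)
  keep_formals <- function(args, fn) args[intersect(names(args), names(formals(fn)))]
  net <- do.call(network_config, keep_formals(y$network %||% list(), network_config))
  aug <- do.call(augment_config, keep_formals(y$augment %||% list(), augment_config))
  lss <- do.call(loss_config, keep_formals(y$loss %||% list(), loss_config))
  args <- c(list(network = net, augment = aug, loss = lss),
            y[c("data_root", "output_dir", "seed")],
            y$training %||% list(), y$eval %||% list())
  args <- args[!vapply(args, is.null, logical(1))]
  do.call(run_config, keep_formals(args, run_config))
}

#' Write / read a JSON-lines dataset manifest
#'
#' @param entries list of records (id, paths, split, fold, ...).
#' @param path `.jsonl` path.
#' @return `read_manifest` returns the list of records.
#' @export
write_manifest <- function(entries, path) {
  writeLines(vapply(entries, function(e)
    as.character(jsonlite::toJSON(e, auto_unbox = TRUE, digits = NA)),
    character(1)), path)
  invisible(path)
}

#' @rdname write_manifest
#' @export
read_manifest <- function(path) {
  lapply(readLines(path), function(l) jsonlite::fromJSON(l))
}
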
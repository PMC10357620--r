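## Seeded generator of endoscopy-like scenes with exact ground-truth boxes.
## The scenes emulate the stated challenges of gastroscopic imagery: weak
## foreground/background contrast, fold-like sinusoidal ridges, saturated
## specular highlights, and many small (sometimes clustered) polyps.

with_seed <- function(seed, expr) {
  if (is.null(seed)) return(force(expr))
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv())
          else if (exists(".Random.seed", globalenv())) rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  expr
}

#' Scene specification
#'
#' Full parameterisation of one synthetic endoscopy scene. Polyp box sides
#' are drawn log-uniformly from `size_range` so small polyps dominate, and
#' `contrast_delta` is the luminance gap between a polyp and its surrounding
#' mucosa (the low-contrast regime of real gastroscopy corresponds to values
#' around 0.05-0.15).
#'
#' @param image_size side of the square image in pixels (default 416).
#' @param n_polyps number of polyps to render.
#' @param size_range `(min_px, max_px)` of the polyp major axis; `min >= 4`.
#' @param contrast_delta polyp/background luminance gap in `[0, 1]`.
#' @param n_folds number of sinusoidal fold ridges.
#' @param n_speculars number of specular highlight discs.
#' @param density_mode cluster polyp centres around a single hub.
#' @param seed integer seed; the same spec renders bitwise-identically.
#' @return object of class `scene_spec`.
#' @export
scene_spec <- function(image_size = 416L, n_polyps = 3L, size_range = c(6, 64),
                       contrast_delta = 0.10, n_folds = 6L, n_speculars = 8L,
                       density_mode = FALSE, seed = 1L) {
  stopifnot(image_size >= 32, n_polyps >= 0, size_range[1] >= 4,
            size_range[2] >= size_range[1], size_range[2] <= image_size / 2,
            contrast_delta >= 0, contrast_delta <= 1)
  structure(list(image_size = as.integer(image_size),
                 n_polyps = as.integer(n_polyps),
                 size_range = as.numeric(size_range),
                 contrast_delta = contrast_delta,
                 n_folds = as.integer(n_folds),
                 n_speculars = as.integer(n_speculars),
                 density_mode = isTRUE(density_mode),
                 seed = as.integer(seed)),
            class = "scene_spec")
}

## bilinear interpolation of an n x n grid to an S x S field
bilerp_field <- function(S, g) {
  n <- nrow(g)
  t <- (seq_len(S) - 0.5) / S * (n - 1) + 1
  i0 <- pmin(floor(t), n - 1)
  fr <- t - i0
  g[i0, i0] * outer(1 - fr, 1 - fr) + g[i0 + 1, i0] * outer(fr, 1 - fr) +
    g[i0, i0 + 1] * outer(1 - fr, fr) + g[i0 + 1, i0 + 1] * outer(fr, fr)
}

## anti-aliased ellipse alpha mask on a local patch, via 4x supersampling.
## Returns the patch row/col range (full-res pixels), the alpha matrix and
## the tight box in continuous 0-based pixel coordinates.
render_ellipse <- function(cx, cy, a, b, theta, S, ss = 4L) {
  R <- max(a, b) + 1
  c0 <- max(0L, floor(cx - R)); c1 <- min(S, ceiling(cx + R))
  r0 <- max(0L, floor(cy - R)); r1 <- min(S, ceiling(cy + R))
  nx <- (c1 - c0) * ss; ny <- (r1 - r0) * ss
  xs <- c0 + (seq_len(nx) - 0.5) / ss
  ys <- r0 + (seq_len(ny) - 0.5) / ss
  dx <- outer(ys * 0, xs - cx, `+`)      # ny x nx
  dy <- outer(ys - cy, xs * 0, `+`)
  u <- (dx * cos(theta) + dy * sin(theta)) / a
  v <- (-dx * sin(theta) + dy * cos(theta)) / b
  inside <- (u * u + v * v) <= 1
  if (!any(inside)) return(NULL)
  ## 4x4 block average down to full resolution
  alpha <- apply(array(inside * 1, c(ss, ny / ss, ss, nx / ss)), c(2, 4), sum) / (ss * ss)
  cols <- which(apply(inside, 2, any)); rows <- which(apply(inside, 1, any))
  box <- c(x_min = c0 + (min(cols) - 1) / ss, y_min = r0 + (min(rows) - 1) / ss,
           x_max = c0 + max(cols) / ss, y_max = r0 + max(rows) / ss)
  list(r0 = r0, r1 = r1, c0 = c0, c1 = c1, alpha = alpha, box = box)
}

box_overlap <- function(box, boxes) {
  if (is.null(boxes) || nrow(boxes) == 0L) return(0)
  max(iou_matrix(boxes_frame(as.numeric(box)), boxes_frame(boxes)))
}

#' Generate one synthetic endoscopy scene
#'
#' Renders, in order: a smooth dark reddish base texture; sinusoidal fold
#' ridges; anti-aliased elliptical polyps whose luminance exceeds the local
#' background by `contrast_delta` (added equally to all channels, so the
#' luminance gap is exact up to edge anti-aliasing); and saturated specular
#' discs placed away from the polyps. Polyps are placed fully inside the
#' image with bounded retries against heavy overlap; the returned boxes are
#' the tight axis-aligned bounds of each rendered ellipse, measured on the
#' 4x supersampled mask.
#'
#' @param spec a [scene_spec()].
#' @return list with `image` (`H x W x 3` array in `[0, 1]`) and `boxes`
#'   (data frame `x_min, y_min, x_max, y_max`, one row per polyp).
#' @export
generate_scene <- function(spec) {
  stopifnot(inherits(spec, "scene_spec"))
  with_seed(spec$seed, {
    S <- spec$image_size
    L <- bilerp_field(S, matrix(stats::runif(81, 0.25, 0.45), 9, 9))
    xs <- (seq_len(S) - 0.5) / S
    xg <- outer(rep(1, S), xs); yg <- outer(xs, rep(1, S))
    for (k in seq_len(spec$n_folds)) {
      th <- stats::runif(1, 0, pi)
      f <- stats::runif(1, 1.5, 4)
      ph <- stats::runif(1, 0, 2 * pi)
      amp <- stats::runif(1, 0.02, 0.05)
      L <- L + amp * sin(2 * pi * f * (xg * cos(th) + yg * sin(th)) + ph)
    }
    L <- pmin(pmax(L, 0.05), 0.85)
    img <- array(0, c(S, S, 3))
    img[, , 1] <- L + 0.15
    img[, , 2] <- 0.55 * L
    img[, , 3] <- 0.50 * L
    boxes <- NULL
    hub <- stats::runif(2, 0.3 * S, 0.7 * S)
    for (k in seq_len(spec$n_polyps)) {
      placed <- FALSE
      for (try in seq_len(200L)) {
        side <- exp(stats::runif(1, log(spec$size_range[1]), log(spec$size_range[2])))
        a <- side / 2
        b <- a * stats::runif(1, 0.6, 1)
        th <- stats::runif(1, 0, pi)
        m <- max(a, b) + 2
        if (spec$density_mode) {
          cx <- stats::rnorm(1, hub[1], S / 8); cy <- stats::rnorm(1, hub[2], S / 8)
          if (cx < m || cx > S - m || cy < m || cy > S - m) next
        } else {
          cx <- stats::runif(1, m, S - m); cy <- stats::runif(1, m, S - m)
        }
        re <- render_ellipse(cx, cy, a, b, th, S)
        if (is.null(re)) next
        if (box_overlap(re$box, boxes) > 0.25) next
        rows <- (re$r0 + 1):re$r1; cols <- (re$c0 + 1):re$c1
        for (ch in 1:3)
          img[rows, cols, ch] <- img[rows, cols, ch] + re$alpha * spec$contrast_delta
        boxes <- rbind(boxes, as.data.frame(as.list(re$box)))
        placed <- TRUE
        break
      }
      if (!placed)
        stop("could not place polyp ", k, " after bounded retries (packing too dense)")
    }
    if (is.null(boxes))
      boxes <- data.frame(x_min = numeric(0), y_min = numeric(0),
                          x_max = numeric(0), y_max = numeric(0))
    ## speculars last, kept off the polyps (they are a background nuisance)
    ns <- 0L; tries <- 0L
    while (ns < spec$n_speculars && tries < 500L) {
      tries <- tries + 1L
      r <- stats::runif(1, 1, 3)
      cx <- stats::runif(1, r + 1, S - r - 1); cy <- stats::runif(1, r + 1, S - r - 1)
      spot <- c(cx - r, cy - r, cx + r, cy + r)
      if (nrow(boxes) && box_overlap(spot, boxes) > 0) next
      rows <- max(1, floor(cy - r)):min(S, ceiling(cy + r))
      cols <- max(1, floor(cx - r)):min(S, ceiling(cx + r))
      dx <- outer(rep(1, length(rows)), cols - 0.5 - cx)
      dy <- outer(rows - 0.5 - cy, rep(1, length(cols)))
      alpha <- pmax(0, 1 - (dx * dx + dy * dy) / (r * r))
      for (ch in 1:3)
        img[rows, cols, ch] <- img[rows, cols, ch] * (1 - alpha) + alpha * 0.98
      ns <- ns + 1L
    }
    img <- pmin(pmax(img, 0), 1)
    list(image = img, boxes = boxes)
  })
}

per_image_seed <- function(base_seed, i) {
  as.integer((base_seed %% 100000L) * 10000L + i)
}

#' In-memory synthetic dataset
#'
#' Generates `n` scenes from a spec template, giving image `i` the derived
#' seed `per-image seed(spec$seed, i)` so any scene can be regenerated in
#' isolation.
#'
#' @param n number of scenes.
#' @param spec template [scene_spec()]; its `seed` anchors the per-image seeds.
#' @return list of `n` elements, each a `generate_scene()` result plus
#'   `image_id` and `seed`.
#' @export
synthetic_dataset <- function(n, spec = scene_spec()) {
  lapply(seq_len(n), function(i) {
    si <- per_image_seed(spec$seed, i)
    sp <- spec; sp$seed <- si
    sc <- generate_scene(sp)
    sc$image_id <- sprintf("img_%04d", i)
    sc$seed <- si
    sc
  })
}

#' Generate a dataset on disk
#'
#' Writes PNG images, COCO JSON and Pascal VOC XML annotations (both
#' dialects describe the same boxes), and a YAML manifest recording the
#' per-image seeds and the train/validation split.
#'
#' @param n_images number of scenes.
#' @param spec template [scene_spec()].
#' @param split fraction of images assigned to the training split.
#' @param out_dir output directory (created if missing).
#' @return the manifest, invisibly (also written to `manifest.yaml`).
#' @export
generate_dataset <- function(n_images, spec = scene_spec(), split = 0.8,
                             out_dir) {
  dir.create(file.path(out_dir, "images"), recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(out_dir, "voc"), showWarnings = FALSE)
  ds <- synthetic_dataset(n_images, spec)
  n_train <- floor(n_images * split)
  entries <- list()
  all_boxes <- NULL
  for (i in seq_along(ds)) {
    sc <- ds[[i]]
    fn <- paste0(sc$image_id, ".png")
    png::writePNG(sc$image, file.path(out_dir, "images", fn))
    write_voc_annotation(sc$boxes, file.path(out_dir, "voc", paste0(sc$image_id, ".xml")),
                         filename = fn, width = spec$image_size,
                         height = spec$image_size)
    entries[[i]] <- list(image_id = sc$image_id, file = file.path("images", fn),
                         seed = sc$seed,
                         split = if (i <= n_train) "train" else "val",
                         n_boxes = nrow(sc$boxes))
    if (nrow(sc$boxes))
      all_boxes <- rbind(all_boxes, cbind(image_id = sc$image_id, sc$boxes))
  }
  if (is.null(all_boxes))
    all_boxes <- data.frame(image_id = character(0), x_min = numeric(0),
                            y_min = numeric(0), x_max = numeric(0),
                            y_max = numeric(0))
  write_coco_annotations(all_boxes,
                         vapply(entries, `[[`, character(1), "image_id"),
                         file.path(out_dir, "annotations.json"),
                         width = spec$image_size, height = spec$image_size)
  manifest <- list(n_images = n_images, split = split,
                   spec = unclass(spec), images = entries)
  yaml::write_yaml(manifest, file.path(out_dir, "manifest.yaml"))
  invisible(manifest)
}
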
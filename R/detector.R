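## Minimal single-class anchor-based reference detector: a tiny strided
## convolutional backbone feeding the attentional fusion neck, one 1x1
## prediction head per attended level, a YOLO-style composite loss
## (objectness binary cross-entropy + box regression; the class term is
## degenerate for a single class), mosaic augmentation, and a two-phase
## freeze/thaw training schedule.

#' Default anchor sizes
#'
#' Three `(w, h)` anchors per pyramid level, in pixels, spanning the
#' log-uniform small-heavy polyp size distribution of the synthetic scenes.
#'
#' @return list of three `3 x 2` matrices (levels at strides 8/16/32).
#' @export
default_anchors <- function() list(
  l2 = matrix(c(8, 8, 16, 16, 24, 24), ncol = 2, byrow = TRUE),
  l3 = matrix(c(32, 32, 48, 48, 64, 64), ncol = 2, byrow = TRUE),
  l4 = matrix(c(96, 96, 128, 128, 176, 176), ncol = 2, byrow = TRUE))

#' Detector / training configuration
#'
#' @param image_size training image side in pixels, divisible by 32
#'   (default 416).
#' @param backbone_widths channel widths of the five stride-2 backbone
#'   convolutions; the last three are the pyramid widths `(c2, c3, c4)`.
#' @param neck a [neck_config()].
#' @param anchors per-level anchor matrices, see [default_anchors()].
#' @param lr0 initial learning rate (default 0.001).
#' @param freeze_epochs,thaw_epochs epochs with the backbone frozen, then
#'   with all parameters training.
#' @param mosaic enable mosaic augmentation during training.
#' @param optimizer `"adam"` (default) or `"sgd"` (with momentum).
#' @param momentum SGD momentum.
#' @param lambda_box,lambda_obj,lambda_noobj loss term weights.
#' @param score_thr default confidence threshold for [detect()].
#' @param nms_iou IoU threshold for non-maximum suppression.
#' @param seed global training seed.
#' @return list of class `detector_config`.
#' @export
detector_config <- function(image_size = 416L,
                            backbone_widths = c(16L, 32L, 64L, 128L, 256L),
                            neck = neck_config(), anchors = default_anchors(),
                            lr0 = 0.001, freeze_epochs = 10L, thaw_epochs = 20L,
                            mosaic = FALSE, optimizer = c("adam", "sgd"),
                            momentum = 0.9, lambda_box = 5, lambda_obj = 1,
                            lambda_noobj = 0.5, score_thr = 0.25,
                            nms_iou = 0.5, seed = 1L) {
  stopifnot(image_size %% 32L == 0L, lr0 > 0, length(backbone_widths) == 5L)
  structure(list(image_size = as.integer(image_size),
                 backbone_widths = as.integer(backbone_widths),
                 neck = neck, anchors = anchors, lr0 = lr0,
                 freeze_epochs = as.integer(freeze_epochs),
                 thaw_epochs = as.integer(thaw_epochs),
                 mosaic = isTRUE(mosaic), optimizer = match.arg(optimizer),
                 momentum = momentum, lambda_box = lambda_box,
                 lambda_obj = lambda_obj, lambda_noobj = lambda_noobj,
                 score_thr = score_thr, nms_iou = nms_iou,
                 seed = as.integer(seed)),
            class = "detector_config")
}

n_anchors <- function(cfg) nrow(cfg$anchors[[1]])

#' Initialise detector parameters
#'
#' @param cfg a [detector_config()].
#' @param seed optional seed for reproducible initialisation.
#' @return flat named list of arrays (`backbone.*`, `neck.*`, `head*.*`).
#' @export
init_detector_params <- function(cfg, seed = NULL) {
  with_seed(seed, {
    w <- cfg$backbone_widths
    p <- list()
    cins <- c(3L, w[-5])
    for (i in 1:5) {
      cv <- conv_init(w[i], cins[i], 3L, "random")
      p[[paste0("backbone.conv", i, ".w")]] <- cv$w
      p[[paste0("backbone.conv", i, ".b")]] <- cv$b
    }
    np <- neck_params(w[3], w[4], w[5], cfg$neck)
    names(np) <- paste0("neck.", names(np))
    p <- c(p, np)
    A <- n_anchors(cfg)
    for (lev in c("head2", "head3", "head4")) {
      cv <- conv_init(5L * A, cfg$neck$channels, 1L, "random")
      ## start objectness biased low so the background sea is quiet
      cv$b[seq(5L, 5L * A, by = 5L)] <- -3
      p[[paste0(lev, ".w")]] <- cv$w; p[[paste0(lev, ".b")]] <- cv$b
    }
    p
  })
}

image_to_tensor <- function(image) {
  if (length(dim(image)) == 3L && dim(image)[3] == 3L) aperm(image, c(3, 1, 2))
  else if (length(dim(image)) == 3L && dim(image)[1] == 3L) image
  else stop("image must be H x W x 3 (or 3 x H x W)")
}

ad_backbone <- function(tp, img, get) {
  x <- img
  outs <- vector("list", 5L)
  for (i in 1:5) {
    x <- ad_conv_act(tp, x, get, paste0("backbone.conv", i), stride = 2L)
    outs[[i]] <- x
  }
  list(F2 = outs[[3]], F3 = outs[[4]], F4 = outs[[5]])
}

#' Tiny strided backbone
#'
#' Five 3x3 stride-2 convolutions with leaky-ReLU; the last three activations
#' form the stride-8/16/32 pyramid (a 416x416 input yields 52/26/13).
#'
#' @param image `H x W x 3` array (values in `[0, 1]`), sides divisible by 32.
#' @param params detector parameter list from [init_detector_params()].
#' @param cfg a [detector_config()].
#' @return a [pyramid_features()] triple.
#' @export
tiny_backbone <- function(image, params, cfg) {
  imgt <- image_to_tensor(image)
  d <- dim(imgt)
  if (d[2] %% 32L != 0L || d[3] %% 32L != 0L)
    stop("image sides must be divisible by 32")
  tp <- tape_new()
  leaves <- lapply(params, function(v) tp_leaf(tp, v))
  get <- function(nm) leaves[[nm]] %||% stop("unknown parameter: ", nm)
  bb <- ad_backbone(tp, tp_leaf(tp, imgt), get)
  pyramid_features(bb$F2$value, bb$F3$value, bb$F4$value)
}

## full forward on a tape; returns head handles and parameter leaves
ad_detector_forward <- function(tp, params, cfg, imgt) {
  leaves <- lapply(params, function(v) tp_leaf(tp, v))
  get <- function(nm) leaves[[nm]] %||% stop("unknown parameter: ", nm)
  getn <- function(nm) get(paste0("neck.", nm))
  bb <- ad_backbone(tp, tp_leaf(tp, imgt), get)
  nk <- ad_neck_forward(tp, bb$F2, bb$F3, bb$F4, getn, cfg$neck)
  heads <- list(
    h2 = ad_conv_act(tp, nk$A2, get, "head2", act = FALSE),
    h3 = ad_conv_act(tp, nk$A3, get, "head3", act = FALSE),
    h4 = ad_conv_act(tp, nk$A4, get, "head4", act = FALSE))
  list(heads = heads, pyramid = bb, neck = nk, leaves = leaves)
}

## ---- decode + NMS ---------------------------------------------------------

decode_level <- function(hv, anchors, stride, img_h, img_w) {
  A <- nrow(anchors)
  d <- dim(hv); Si <- d[2]; Sj <- d[3]
  H5 <- array(hv, c(5L, A, Si, Sj))
  sx <- sigmoid(H5[1, , , , drop = FALSE])
  sy <- sigmoid(H5[2, , , , drop = FALSE])
  tw <- H5[3, , , , drop = FALSE]
  th <- H5[4, , , , drop = FALSE]
  sc <- sigmoid(H5[5, , , , drop = FALSE])
  ii <- array(rep(seq_len(Si), each = A), c(A, Si, Sj))
  jj <- array(rep(seq_len(Sj), each = A * Si), c(A, Si, Sj))
  aw <- array(anchors[, 1], c(A, Si, Sj))
  ah <- array(anchors[, 2], c(A, Si, Sj))
  cx <- (jj - 1 + c(sx)) * stride
  cy <- (ii - 1 + c(sy)) * stride
  bw <- aw * exp(pmin(c(tw), 8))
  bh <- ah * exp(pmin(c(th), 8))
  data.frame(x_min = pmax(0, c(cx - bw / 2)), y_min = pmax(0, c(cy - bh / 2)),
             x_max = pmin(img_w, c(cx + bw / 2)), y_max = pmin(img_h, c(cy + bh / 2)),
             score = c(sc))
}

#' Non-maximum suppression
#'
#' Greedy suppression in descending score order at the given IoU threshold.
#'
#' @param dets data frame with box columns and `score`.
#' @param iou_thr suppression threshold (default 0.5).
#' @return the surviving detections, sorted by descending score.
#' @export
nms <- function(dets, iou_thr = 0.5) {
  if (nrow(dets) == 0L) return(dets)
  dets <- dets[order(-dets$score), , drop = FALSE]
  keep <- logical(nrow(dets))
  M <- iou_matrix(boxes_frame(dets), boxes_frame(dets))
  alive <- rep(TRUE, nrow(dets))
  for (i in seq_len(nrow(dets))) {
    if (!alive[i]) next
    keep[i] <- TRUE
    alive <- alive & (M[i, ] <= iou_thr)
    alive[i] <- FALSE
  }
  dets[keep, , drop = FALSE]
}

#' Run detection on one image
#'
#' Full forward pass, YOLO-style decode (sigmoid offsets within the cell,
#' exponential anchor scaling, sigmoid objectness as the score), confidence
#' thresholding, NMS, and clipping to the image bounds.
#'
#' @param model a fitted [polyp_detector()] (or a list with `params` and
#'   `config`).
#' @param image `H x W x 3` array.
#' @param score_thr confidence threshold (default from the config).
#' @param nms_iou NMS IoU threshold (default from the config).
#' @return data frame `(x_min, y_min, x_max, y_max, score)` sorted by
#'   descending score; zero rows when nothing is detected.
#' @export
detect <- function(model, image, score_thr = NULL, nms_iou = NULL) {
  cfg <- model$config
  score_thr <- score_thr %||% cfg$score_thr
  nms_iou <- nms_iou %||% cfg$nms_iou
  imgt <- image_to_tensor(image)
  tp <- tape_new()
  fw <- ad_detector_forward(tp, model$params, cfg, imgt)
  img_h <- dim(imgt)[2]; img_w <- dim(imgt)[3]
  dets <- do.call(rbind, lapply(1:3, function(k) {
    decode_level(fw$heads[[k]]$value, cfg$anchors[[k]], c(8L, 16L, 32L)[k],
                 img_h, img_w)
  }))
  dets <- dets[dets$score >= score_thr & dets$x_max > dets$x_min &
                 dets$y_max > dets$y_min, , drop = FALSE]
  if (nrow(dets) == 0L) return(dets)
  ## cap the candidate pool before the quadratic NMS pass
  if (nrow(dets) > 1000L)
    dets <- dets[order(-dets$score)[1:1000], , drop = FALSE]
  nms(dets, nms_iou)
}

## ---- training targets and loss -------------------------------------------

## Per-level target arrays: obj in {-1 (ignore), 0 (negative), 1 (positive)},
## and the four regression targets at positive cells.
build_targets <- function(boxes, img_h, img_w, cfg) {
  strides <- c(8L, 16L, 32L)
  A <- n_anchors(cfg)
  lv <- lapply(1:3, function(k) {
    Si <- img_h %/% strides[k]; Sj <- img_w %/% strides[k]
    list(obj = array(0, c(A, Si, Sj)), t = array(0, c(4L, A, Si, Sj)))
  })
  anc <- do.call(rbind, cfg$anchors)          # 3A x 2, level-major
  n_per <- nrow(cfg$anchors[[1]])
  if (!is.null(boxes) && nrow(boxes) > 0L) for (g in seq_len(nrow(boxes))) {
    w <- boxes$x_max[g] - boxes$x_min[g]; h <- boxes$y_max[g] - boxes$y_min[g]
    cx <- (boxes$x_min[g] + boxes$x_max[g]) / 2
    cy <- (boxes$y_min[g] + boxes$y_max[g]) / 2
    inter <- pmin(w, anc[, 1]) * pmin(h, anc[, 2])
    si <- inter / (w * h + anc[, 1] * anc[, 2] - inter)
    best <- which.max(si)
    k <- (best - 1L) %/% n_per + 1L
    a <- (best - 1L) %% n_per + 1L
    st <- strides[k]
    Si <- dim(lv[[k]]$obj)[2]; Sj <- dim(lv[[k]]$obj)[3]
    j <- min(max(floor(cx / st) + 1L, 1L), Sj)
    i <- min(max(floor(cy / st) + 1L, 1L), Si)
    if (lv[[k]]$obj[a, i, j] == 1) next      # cell already owns a target
    lv[[k]]$obj[a, i, j] <- 1
    lv[[k]]$t[1, a, i, j] <- cx / st - (j - 1L)
    lv[[k]]$t[2, a, i, j] <- cy / st - (i - 1L)
    lv[[k]]$t[3, a, i, j] <- log(w / anc[best, 1])
    lv[[k]]$t[4, a, i, j] <- log(h / anc[best, 2])
    ## ignore competing well-matched anchors instead of calling them negative
    for (o in which(si > 0.5)) {
      if (o == best) next
      ko <- (o - 1L) %/% n_per + 1L; ao <- (o - 1L) %% n_per + 1L
      sto <- strides[ko]
      Sjo <- dim(lv[[ko]]$obj)[3]; Sio <- dim(lv[[ko]]$obj)[2]
      jo <- min(max(floor(cx / sto) + 1L, 1L), Sjo)
      io <- min(max(floor(cy / sto) + 1L, 1L), Sio)
      if (lv[[ko]]$obj[ao, io, jo] == 0) lv[[ko]]$obj[ao, io, jo] <- -1
    }
  }
  lv
}

## Composite YOLO loss for one level as a single tape node with analytic
## backward into the raw head activations.
tp_yolo_loss <- function(tp, head, tgt, cfg) {
  hv <- head$value
  d <- dim(hv)
  A <- dim(tgt$obj)[1]
  H5 <- array(hv, c(5L, A, d[2], d[3]))
  obj <- tgt$obj
  P <- obj == 1; N <- obj == 0
  ## both objectness terms are normalised by the positive count: summed (not
  ## averaged) suppression over the background sea is what keeps confident
  ## false positives down on these sparse single-class scenes
  npos <- max(1, sum(P)); nneg <- npos
  eps <- 1e-7
  sx <- sigmoid(H5[1, , , ]); sy <- sigmoid(H5[2, , , ])
  twv <- H5[3, , , ]; thv <- H5[4, , , ]
  po <- sigmoid(H5[5, , , ])
  gx <- tgt$t[1, , , ]; gy <- tgt$t[2, , , ]
  gw <- tgt$t[3, , , ]; gh <- tgt$t[4, , , ]
  l_obj <- cfg$lambda_obj * sum(-log(po[P] + eps)) / npos +
    cfg$lambda_noobj * sum(-log(1 - po[N] + eps)) / nneg
  l_box <- cfg$lambda_box * sum(P * ((sx - gx)^2 + (sy - gy)^2 +
                                       (twv - gw)^2 + (thv - gh)^2)) / npos
  tp_node(tp, l_obj + l_box, head$id, function(g) {
    G <- array(0, c(5L, A, d[2], d[3]))
    cb <- 2 * cfg$lambda_box / npos
    G[1, , , ] <- g * cb * P * (sx - gx) * sx * (1 - sx)
    G[2, , , ] <- g * cb * P * (sy - gy) * sy * (1 - sy)
    G[3, , , ] <- g * cb * P * (twv - gw)
    G[4, , , ] <- g * cb * P * (thv - gh)
    dob <- array(0, dim(obj))
    dob[P] <- cfg$lambda_obj * (po[P] - 1) / npos
    dob[N] <- cfg$lambda_noobj * po[N] / nneg
    G[5, , , ] <- g * dob
    list(array(G, d))
  })
}

## ---- optimiser ------------------------------------------------------------

opt_state_new <- function() {
  st <- new.env(parent = emptyenv())
  st$m <- list(); st$v <- list(); st$t <- 0L
  st
}

opt_update <- function(st, params, grads, cfg, frozen_prefix = NULL) {
  st$t <- st$t + 1L
  lr <- cfg$lr0
  ## global gradient-norm clipping for stability
  gn <- sqrt(sum(vapply(grads, function(g) sum(g^2), numeric(1))))
  scale <- if (gn > 10) 10 / gn else 1
  for (nm in names(params)) {
    if (!is.null(frozen_prefix) && startsWith(nm, frozen_prefix)) next
    g <- grads[[nm]] * scale
    if (cfg$optimizer == "adam") {
      m <- st$m[[nm]] %||% 0; v <- st$v[[nm]] %||% 0
      m <- 0.9 * m + 0.1 * g
      v <- 0.999 * v + 0.001 * g^2
      st$m[[nm]] <- m; st$v[[nm]] <- v
      mh <- m / (1 - 0.9^st$t); vh <- v / (1 - 0.999^st$t)
      params[[nm]] <- params[[nm]] - lr * mh / (sqrt(vh) + 1e-8)
    } else {
      m <- st$m[[nm]] %||% 0
      m <- cfg$momentum * m + g
      st$m[[nm]] <- m
      params[[nm]] <- params[[nm]] - lr * m
    }
  }
  params
}

## ---- mosaic augmentation --------------------------------------------------

resize_nearest <- function(img, h, w) {
  H <- dim(img)[1]; W <- dim(img)[2]
  ri <- pmin(pmax(floor((seq_len(h) - 0.5) * H / h) + 1L, 1L), H)
  ci <- pmin(pmax(floor((seq_len(w) - 0.5) * W / w) + 1L, 1L), W)
  img[ri, ci, , drop = FALSE]
}

#' Mosaic augmentation
#'
#' Composes four annotated samples into one image: a split point divides the
#' canvas into four quadrants, each source image is resized (nearest
#' neighbour) into its quadrant and its boxes are mapped by the same affine
#' transform, clipped to the quadrant, and dropped if a side falls below
#' 2 px. By default the split point is sampled uniformly in the central 50%
#' of each axis; passing `split = c(x, y)` (pixels) fixes it, and with the
#' split at the exact centre and equal source/quadrant sizes the mapping is
#' a pure translation.
#'
#' @param samples list of at least four `list(image, boxes)` samples; the
#'   first four are used.
#' @param size side of the composite image.
#' @param split optional fixed split point `c(x, y)` in pixels.
#' @param seed optional seed for the random split.
#' @return `list(image, boxes)`.
#' @export
mosaic_augment <- function(samples, size, split = NULL, seed = NULL) {
  if (length(samples) < 4L) stop("mosaic augmentation needs four samples")
  with_seed(seed, {
    if (is.null(split))
      split <- c(stats::runif(1, 0.25, 0.75), stats::runif(1, 0.25, 0.75)) * size
    sx <- as.integer(round(split[1])); sy <- as.integer(round(split[2]))
    stopifnot(sx > 0, sx < size, sy > 0, sy < size)
    canvas <- array(0, c(size, size, 3))
    quads <- list(c(1L, sy, 1L, sx), c(1L, sy, sx + 1L, size),
                  c(sy + 1L, size, 1L, sx), c(sy + 1L, size, sx + 1L, size))
    boxes <- NULL
    for (q in 1:4) {
      qd <- quads[[q]]
      h <- qd[2] - qd[1] + 1L; w <- qd[4] - qd[3] + 1L
      smp <- samples[[q]]
      H <- dim(smp$image)[1]; W <- dim(smp$image)[2]
      canvas[qd[1]:qd[2], qd[3]:qd[4], ] <- resize_nearest(smp$image, h, w)
      b <- smp$boxes
      if (!is.null(b) && nrow(b)) {
        fx <- w / W; fy <- h / H
        ox <- qd[3] - 1L; oy <- qd[1] - 1L
        nb <- data.frame(x_min = pmax(b$x_min * fx + ox, ox),
                         y_min = pmax(b$y_min * fy + oy, oy),
                         x_max = pmin(b$x_max * fx + ox, ox + w),
                         y_max = pmin(b$y_max * fy + oy, oy + h))
        nb <- nb[nb$x_max - nb$x_min >= 2 & nb$y_max - nb$y_min >= 2, , drop = FALSE]
        boxes <- rbind(boxes, nb)
      }
    }
    if (is.null(boxes))
      boxes <- data.frame(x_min = numeric(0), y_min = numeric(0),
                          x_max = numeric(0), y_max = numeric(0))
    list(image = canvas, boxes = boxes)
  })
}

## ---- fitting --------------------------------------------------------------

#' Fit the reference polyp detector
#'
#' Trains the tiny backbone + attentional fusion neck + YOLO-style heads on
#' an annotated dataset with the two-phase schedule: during the freeze phase
#' the backbone parameters receive no updates (they are bitwise unchanged);
#' during the thaw phase every parameter trains. One image is processed per
#' optimisation step; the loss history is recorded per step.
#'
#' @param data list of samples, each `list(image, boxes)` (`image` an
#'   `H x W x 3` array with sides divisible by 32, `boxes` a data frame of
#'   ground-truth boxes).
#' @param config a [detector_config()].
#' @param params optional warm-start parameter list.
#' @return an object of class `polyp_detector` with elements `params`,
#'   `config`, `history` (data frame: step, epoch, phase, loss) and
#'   `n_params`.
#' @export
polyp_detector <- function(data, config = detector_config(), params = NULL) {
  if (length(data) == 0L) stop("empty dataset")
  set.seed(config$seed)
  params <- params %||% init_detector_params(config)
  st <- opt_state_new()
  phases <- c(rep("freeze", config$freeze_epochs), rep("thaw", config$thaw_epochs))
  hist <- vector("list", length(phases) * length(data))
  step <- 0L
  for (ep in seq_along(phases)) {
    frozen <- if (phases[ep] == "freeze") "backbone." else NULL
    for (idx in sample.int(length(data))) {
      smp <- data[[idx]]
      if (config$mosaic && length(data) >= 4L) {
        others <- sample.int(length(data), 3L)
        smp <- mosaic_augment(c(list(smp), data[others]), size = dim(smp$image)[1])
      }
      imgt <- image_to_tensor(smp$image)
      tgt <- build_targets(smp$boxes, dim(imgt)[2], dim(imgt)[3], config)
      tp <- tape_new()
      fw <- ad_detector_forward(tp, params, config, imgt)
      loss <- tp_add(tp, tp_yolo_loss(tp, fw$heads$h2, tgt[[1]], config),
                     tp_add(tp, tp_yolo_loss(tp, fw$heads$h3, tgt[[2]], config),
                            tp_yolo_loss(tp, fw$heads$h4, tgt[[3]], config)))
      if (!is.finite(loss$value)) stop("non-finite training loss at step ", step + 1L)
      grads_all <- tp_backward(tp, loss)
      grads <- lapply(fw$leaves, function(h) tp_grad(grads_all, h))
      params <- opt_update(st, params, grads, config, frozen_prefix = frozen)
      step <- step + 1L
      hist[[step]] <- data.frame(step = step, epoch = ep, phase = phases[ep],
                                 loss = loss$value)
    }
  }
  structure(list(params = params, config = config,
                 history = do.call(rbind, hist),
                 n_params = sum(lengths(params))),
            class = "polyp_detector")
}

#' @export
print.polyp_detector <- function(x, ...) {
  h <- x$history
  cat("Polyp detector (attentional feature fusion neck)\n")
  cat(sprintf("  parameters : %d\n", x$n_params))
  cat(sprintf("  schedule   : %d freeze + %d thaw epochs, lr0 = %g (%s)\n",
              x$config$freeze_epochs, x$config$thaw_epochs, x$config$lr0,
              x$config$optimizer))
  if (!is.null(h) && nrow(h))
    cat(sprintf("  loss       : %.4f (initial) -> %.4f (final) over %d steps\n",
                h$loss[1], h$loss[nrow(h)], nrow(h)))
  invisible(x)
}

#' @export
summary.polyp_detector <- function(object, ...) {
  h <- object$history
  out <- list(n_params = object$n_params, config = object$config,
              steps = nrow(h),
              loss_initial = h$loss[1], loss_final = h$loss[nrow(h)],
              loss_by_epoch = tapply(h$loss, h$epoch, mean))
  class(out) <- "summary.polyp_detector"
  out
}

#' @export
print.summary.polyp_detector <- function(x, ...) {
  cat(sprintf("polyp_detector: %d parameters, %d steps\n", x$n_params, x$steps))
  cat(sprintf("loss %.4f -> %.4f (ratio %.3f)\n", x$loss_initial, x$loss_final,
              x$loss_final / x$loss_initial))
  invisible(x)
}

#' @export
coef.polyp_detector <- function(object, ...) unlist(object$params)

#' @export
predict.polyp_detector <- function(object, newdata, score_thr = NULL,
                                   nms_iou = NULL, ...) {
  if (is.list(newdata) && !is.null(newdata$image)) newdata <- newdata$image
  detect(object, newdata, score_thr = score_thr, nms_iou = nms_iou)
}

#' @export
plot.polyp_detector <- function(x, ...) {
  h <- x$history
  graphics::plot(h$step, h$loss, type = "l", xlab = "step", ylab = "loss",
                 main = "Training loss", ...)
  thaw0 <- h$step[match("thaw", h$phase)]
  if (!is.na(thaw0)) graphics::abline(v = thaw0, lty = 2)
  invisible(x)
}

#' Save / load a detector checkpoint
#'
#' Single-file serialized parameter dictionary with the config snapshot and
#' training history.
#'
#' @param model a `polyp_detector`.
#' @param path file path.
#' @return `load_checkpoint()` returns the restored `polyp_detector`.
#' @export
save_checkpoint <- function(model, path) {
  saveRDS(unclass(model), path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  structure(readRDS(path), class = "polyp_detector")
}
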
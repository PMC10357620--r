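## Independent scalar-loop oracles. These deliberately avoid the package's
## vectorised code paths: everything is written as explicit loops over
## (channel, row, column) so agreement is meaningful evidence.

rand_fmap <- function(C, H, W, sd = 1) array(rnorm(C * H * W, sd = sd), c(C, H, W))

## softmax-weighted 2x2 window average, replicate padding bottom/right
oracle_enhance <- function(x) {
  d <- dim(x); out <- array(0, d)
  for (c in seq_len(d[1])) for (i in seq_len(d[2])) for (j in seq_len(d[3])) {
    i2 <- min(i + 1, d[2]); j2 <- min(j + 1, d[3])
    v <- c(x[c, i, j], x[c, i, j2], x[c, i2, j], x[c, i2, j2])
    w <- exp(v - max(v)); w <- w / sum(w)
    out[c, i, j] <- sum(w * v)
  }
  out
}

oracle_dirpool <- function(x) {
  d <- dim(x)
  h <- matrix(0, d[1], d[2]); w <- matrix(0, d[1], d[3])
  for (c in seq_len(d[1])) {
    for (i in seq_len(d[2])) h[c, i] <- sum(x[c, i, ]) / d[3]
    for (j in seq_len(d[3])) w[c, j] <- sum(x[c, , j]) / d[2]
  }
  list(h_pool = h, w_pool = w)
}

oracle_softpool <- function(u) {
  d <- dim(u)
  vapply(seq_len(d[1]), function(c) {
    v <- as.numeric(u[c, , ])
    e <- exp(v - max(v))
    sum(e / sum(e) * v)
  }, numeric(1))
}

oracle_hswish <- function(x) {
  sapply(x, function(v) v * min(max(v + 3, 0), 6) / 6)
}

## position attention via loops, using the parameter matrices directly
oracle_position_attention <- function(x, p) {
  d <- dim(x); C <- d[1]; H <- d[2]; W <- d[3]
  dp <- oracle_dirpool(oracle_enhance(x))
  x1 <- cbind(dp$h_pool, dp$w_pool)
  t1 <- matrix(0, p$cr, H + W)
  for (r in seq_len(p$cr)) for (l in seq_len(H + W))
    t1[r, l] <- sum(p$pos$w1[r, ] * x1[, l]) + p$pos$b1[r]
  act <- function(v) if (p$position_gate == "hard_swish") oracle_hswish(v) else 1 / (1 + exp(-v))
  wh <- matrix(0, C, H); ww <- matrix(0, C, W)
  for (c in seq_len(C)) {
    for (i in seq_len(H)) wh[c, i] <- act(sum(p$pos$wh[c, ] * t1[, i]) + p$pos$bh[c])
    for (j in seq_len(W)) ww[c, j] <- act(sum(p$pos$ww[c, ] * t1[, H + j]) + p$pos$bw[c])
  }
  out <- array(0, d)
  for (c in seq_len(C)) for (i in seq_len(H)) for (j in seq_len(W))
    out[c, i, j] <- x[c, i, j] * wh[c, i] * ww[c, j]
  out
}

oracle_channel_attention <- function(u, p) {
  d <- dim(u); C <- d[1]
  s1 <- vapply(seq_len(C), function(c) mean(u[c, , ]), numeric(1))
  s2 <- oracle_softpool(u)
  mlp <- function(s, q) {
    z <- numeric(p$cr)
    for (r in seq_len(p$cr)) z[r] <- max(sum(q$w1[r, ] * s) + q$b1[r], 0)
    out <- numeric(C)
    for (c in seq_len(C)) out[c] <- sum(q$w2[c, ] * z) + q$b2[c]
    out
  }
  q2 <- if (p$shared_mlp) p$chan else p$chan2
  g <- 1 / (1 + exp(-(mlp(s1, p$chan) + mlp(s2, q2))))
  out <- array(0, d)
  for (c in seq_len(C)) out[c, , ] <- u[c, , ] * g[c]
  out
}

## slow AP oracle: rebuild the PR table by explicit prefix enumeration,
## re-running greedy matching from scratch for every rank cutoff
oracle_ap <- function(dets, gts, iou_thr = 0.5) {
  ngt <- nrow(gts)
  if (ngt == 0L || nrow(dets) == 0L) return(0)
  dets <- dets[order(-dets$score), , drop = FALSE]
  rec <- prec <- numeric(nrow(dets))
  for (k in seq_len(nrow(dets))) {
    TP <- 0L
    for (id in unique(gts$image_id)) {
      dk <- dets[seq_len(k), , drop = FALSE]
      dk <- dk[dk$image_id == id, , drop = FALSE]
      gk <- gts[gts$image_id == id, , drop = FALSE]
      used <- logical(nrow(gk))
      for (i in seq_len(nrow(dk))) {
        best <- 0; bj <- 0L
        for (j in seq_len(nrow(gk))) {
          if (used[j]) next
          v <- iou(as.numeric(dk[i, c("x_min", "y_min", "x_max", "y_max")]),
                   as.numeric(gk[j, c("x_min", "y_min", "x_max", "y_max")]))
          if (v > best) { best <- v; bj <- j }
        }
        if (bj > 0L && best >= iou_thr) { used[bj] <- TRUE; TP <- TP + 1L }
      }
    }
    rec[k] <- TP / ngt
    prec[k] <- TP / k
  }
  penv <- rev(cummax(rev(prec)))
  sum(diff(c(0, rec)) * penv)
}

## random detection scenario over a couple of images
rand_detection_set <- function(n_img = 2, max_gt = 4, max_det = 6, size = 100) {
  rbox <- function(n) {
    x0 <- runif(n, 0, size - 20); y0 <- runif(n, 0, size - 20)
    w <- runif(n, 5, 20); h <- runif(n, 5, 20)
    data.frame(x_min = x0, y_min = y0, x_max = x0 + w, y_max = y0 + h)
  }
  gts <- do.call(rbind, lapply(seq_len(n_img), function(i) {
    ng <- sample(0:max_gt, 1)
    if (ng == 0) return(NULL)
    cbind(image_id = paste0("im", i), rbox(ng))
  }))
  dets <- do.call(rbind, lapply(seq_len(n_img), function(i) {
    nd <- sample(0:max_det, 1)
    if (nd == 0) return(NULL)
    g <- if (is.null(gts)) NULL
    else gts[gts$image_id == paste0("im", i), , drop = FALSE]
    b <- rbox(nd)
    ## make some detections near ground truths so TPs occur
    if (!is.null(g) && nrow(g)) for (k in seq_len(nd)) {
      if (runif(1) < 0.6) {
        j <- sample(nrow(g), 1)
        jit <- runif(4, -4, 4)
        b[k, ] <- g[j, c("x_min", "y_min", "x_max", "y_max")] + jit
        if (b$x_max[k] <= b$x_min[k]) b$x_max[k] <- b$x_min[k] + 1
        if (b$y_max[k] <= b$y_min[k]) b$y_max[k] <- b$y_min[k] + 1
      }
    }
    cbind(image_id = paste0("im", i), b, score = runif(nd))
  }))
  if (is.null(gts)) gts <- data.frame(image_id = character(0), x_min = numeric(0),
                                      y_min = numeric(0), x_max = numeric(0),
                                      y_max = numeric(0))
  list(dets = dets, gts = gts)
}

## compact configs for fast end-to-end exercises
tiny_neck_cfg <- function(...) neck_config(channels = 8L, conv_block_depth = 3L,
                                           reduction_ratio = 4L, ...)
tiny_detector_cfg <- function(...) {
  detector_config(image_size = 64L, backbone_widths = c(4L, 6L, 8L, 10L, 12L),
                  neck = tiny_neck_cfg(), freeze_epochs = 1L, thaw_epochs = 1L,
                  seed = 1L, ...)
}
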
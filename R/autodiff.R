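## Minimal tape-based reverse-mode differentiation over numeric arrays.
##
## A tape records one operation per node in topological order; each node
## stores its parent ids and a backward closure mapping the output gradient
## to per-parent gradients. Handles are lightweight lists (id, value) so
## forward code reads like plain array code. Everything is double precision
## and deterministic. Feature maps follow the package layout dim (C, H, W).

tape_new <- function() {
  tp <- new.env(parent = emptyenv())
  tp$nodes <- vector("list", 256L)
  tp$n <- 0L
  tp
}

tp_node <- function(tp, value, parents = integer(0), backward = NULL) {
  ## force the arguments before taking an id: nested node-creating calls in
  ## an argument expression must be recorded ahead of this node
  force(value); force(parents); force(backward)
  n <- tp$n + 1L
  if (n > length(tp$nodes)) tp$nodes <- c(tp$nodes, vector("list", length(tp$nodes)))
  tp$nodes[[n]] <- list(parents = parents, backward = backward)
  tp$n <- n
  list(id = n, value = value)
}

tp_leaf <- function(tp, value) tp_node(tp, value)

## Reverse sweep from a scalar root; returns the list of accumulated
## gradients indexed by node id (NULL where no gradient flowed).
tp_backward <- function(tp, root) {
  stopifnot(length(root$value) == 1L)
  grads <- vector("list", tp$n)
  grads[[root$id]] <- 1
  for (id in seq(root$id, 1L)) {
    g <- grads[[id]]
    if (is.null(g)) next
    nd <- tp$nodes[[id]]
    if (is.null(nd$backward)) next
    pg <- nd$backward(g)
    for (k in seq_along(nd$parents)) {
      if (is.null(pg[[k]])) next
      p <- nd$parents[k]
      grads[[p]] <- if (is.null(grads[[p]])) pg[[k]] else grads[[p]] + pg[[k]]
    }
  }
  grads
}

tp_grad <- function(grads, h) {
  g <- grads[[h$id]]
  if (is.null(g)) array(0, dim(h$value) %||% length(h$value)) else g
}

`%||%` <- function(a, b) if (is.null(a)) b else a

## ---- elementwise ops ------------------------------------------------------

tp_ewise <- function(tp, x, f, dfx) {
  xv <- x$value
  tp_node(tp, f(xv), x$id, function(g) list(g * dfx(xv)))
}

tp_relu <- function(tp, x) tp_ewise(tp, x, function(v) pmax(v, 0), function(v) (v > 0) * 1)

tp_leaky_relu <- function(tp, x, alpha = 0.1)
  tp_ewise(tp, x, function(v) pmax(v, 0) + alpha * pmin(v, 0),
           function(v) alpha + (1 - alpha) * (v > 0))

tp_sigmoid <- function(tp, x) {
  y <- sigmoid(x$value)
  tp_node(tp, y, x$id, function(g) list(g * y * (1 - y)))
}

## derivative: 0 below -3, (2x+3)/6 inside (-3, 3) (reaching 1.5 at the
## kink), exactly 1 above 3
tp_hard_swish <- function(tp, x)
  tp_ewise(tp, x, hard_swish,
           function(v) (v > -3 & v < 3) * (2 * v + 3) / 6 + (v >= 3))

tp_add <- function(tp, a, b)
  tp_node(tp, a$value + b$value, c(a$id, b$id), function(g) list(g, g))

tp_sum_all <- function(tp, x) {
  d <- dim(x$value) %||% length(x$value)
  tp_node(tp, sum(x$value), x$id, function(g) list(array(g, d)))
}

## ---- matrix ops (used by the attention descriptor transforms) -------------

tp_matmul <- function(tp, w, x) {
  wv <- w$value; xv <- x$value
  tp_node(tp, wv %*% xv, c(w$id, x$id),
          function(g) list(g %*% t(xv), t(wv) %*% g))
}

## add a length-nrow column vector to every column
tp_add_colvec <- function(tp, x, b) {
  tp_node(tp, x$value + b$value, c(x$id, b$id),
          function(g) list(g, rowSums(g)))
}

tp_concat_cols <- function(tp, a, b) {
  na <- ncol(a$value)
  tp_node(tp, cbind(a$value, b$value), c(a$id, b$id),
          function(g) list(g[, seq_len(na), drop = FALSE],
                           g[, -seq_len(na), drop = FALSE]))
}

tp_slice_cols <- function(tp, x, idx) {
  d <- dim(x$value)
  tp_node(tp, x$value[, idx, drop = FALSE], x$id,
          function(g) { out <- matrix(0, d[1], d[2]); out[, idx] <- g; list(out) })
}

## ---- convolution ----------------------------------------------------------

im2col <- function(x, k, stride, pad) {
  d <- dim(x); C <- d[1]; H <- d[2]; W <- d[3]
  if (pad > 0) {
    xp <- array(0, c(C, H + 2L * pad, W + 2L * pad))
    xp[, pad + seq_len(H), pad + seq_len(W)] <- x
  } else xp <- x
  Hp <- H + 2L * pad; Wp <- W + 2L * pad
  Ho <- (Hp - k) %/% stride + 1L; Wo <- (Wp - k) %/% stride + 1L
  cols <- matrix(0, C * k * k, Ho * Wo)
  idx <- 0L
  for (dj in seq_len(k)) for (di in seq_len(k)) {
    idx <- idx + 1L
    rows <- seq.int(di, by = stride, length.out = Ho)
    cls <- seq.int(dj, by = stride, length.out = Wo)
    cols[((idx - 1L) * C + 1L):(idx * C), ] <-
      matrix(xp[, rows, cls, drop = FALSE], C, Ho * Wo)
  }
  list(cols = cols, Ho = Ho, Wo = Wo, Hp = Hp, Wp = Wp)
}

col2im <- function(dcols, C, k, stride, pad, Ho, Wo, Hp, Wp) {
  gxp <- array(0, c(C, Hp, Wp))
  idx <- 0L
  for (dj in seq_len(k)) for (di in seq_len(k)) {
    idx <- idx + 1L
    rows <- seq.int(di, by = stride, length.out = Ho)
    cls <- seq.int(dj, by = stride, length.out = Wo)
    block <- array(dcols[((idx - 1L) * C + 1L):(idx * C), ], c(C, Ho, Wo))
    gxp[, rows, cls] <- gxp[, rows, cls] + block
  }
  if (pad > 0)
    gxp[, pad + seq_len(Hp - 2L * pad), pad + seq_len(Wp - 2L * pad), drop = FALSE]
  else gxp
}

## 2-d convolution, weight array w dim (Cout, Cin, k, k), bias length Cout.
tp_conv2d <- function(tp, x, w, b, stride = 1L, pad = 1L) {
  xv <- x$value; wv <- w$value; bv <- b$value
  C <- dim(xv)[1]; Cout <- dim(wv)[1]; k <- dim(wv)[3]
  ic <- im2col(xv, k, stride, pad)
  wmat <- matrix(wv, Cout, C * k * k)
  out <- wmat %*% ic$cols + bv
  val <- array(out, c(Cout, ic$Ho, ic$Wo))
  tp_node(tp, val, c(x$id, w$id, b$id), function(g) {
    gm <- matrix(g, Cout, ic$Ho * ic$Wo)
    dw <- array(gm %*% t(ic$cols), dim(wv))
    db <- rowSums(gm)
    dx <- col2im(t(wmat) %*% gm, C, k, stride, pad, ic$Ho, ic$Wo, ic$Hp, ic$Wp)
    list(dx, dw, db)
  })
}

## ---- spatial ops ----------------------------------------------------------

tp_upsample_nearest <- function(tp, x, f) {
  xv <- x$value
  d <- dim(xv); C <- d[1]; H <- d[2]; W <- d[3]
  val <- xv[, rep(seq_len(H), each = f), rep(seq_len(W), each = f), drop = FALSE]
  tp_node(tp, val, x$id, function(g) {
    g5 <- array(g, c(C, f, H, f, W))
    list(apply(g5, c(1, 3, 5), sum))
  })
}

tp_concat_chan <- function(tp, xs) {
  dims <- lapply(xs, function(h) dim(h$value))
  Cs <- vapply(dims, `[`, integer(1), 1L)
  H <- dims[[1]][2]; W <- dims[[1]][3]
  val <- array(0, c(sum(Cs), H, W))
  off <- 0L
  for (h in xs) {
    ch <- dim(h$value)[1]
    val[off + seq_len(ch), , ] <- h$value
    off <- off + ch
  }
  tp_node(tp, val, vapply(xs, `[[`, integer(1), "id"), function(g) {
    out <- vector("list", length(xs)); off <- 0L
    for (k in seq_along(xs)) {
      ch <- Cs[k]
      out[[k]] <- g[off + seq_len(ch), , , drop = FALSE]
      off <- off + ch
    }
    out
  })
}

tp_pool_h <- function(tp, x) {
  d <- dim(x$value); C <- d[1]; H <- d[2]; W <- d[3]
  val <- matrix(rowSums(matrix(x$value, C * H, W)), C, H) / W
  tp_node(tp, val, x$id, function(g) list(array(g, c(C, H, W)) / W))
}

tp_pool_w <- function(tp, x) {
  d <- dim(x$value); C <- d[1]; H <- d[2]; W <- d[3]
  val <- matrix(rowSums(matrix(aperm(x$value, c(1, 3, 2)), C * W, H)), C, W) / H
  tp_node(tp, val, x$id,
          function(g) list(aperm(array(g, c(C, W, H)), c(1, 3, 2)) / H))
}

tp_gap <- function(tp, x) {
  d <- dim(x$value); n <- d[2] * d[3]
  val <- rowMeans(matrix(x$value, d[1], n))
  tp_node(tp, val, x$id, function(g) list(array(g, d) / n))
}

tp_softpool <- function(tp, x) {
  d <- dim(x$value); C <- d[1]; n <- d[2] * d[3]
  m <- matrix(x$value, C, n)
  e <- exp(m - apply(m, 1, max))
  wn <- e / rowSums(e)
  val <- rowSums(wn * m)
  tp_node(tp, val, x$id, function(g) {
    dm <- wn * (1 + m - val) * as.vector(g)  # g, val recycle down columns
    list(array(dm, d))
  })
}

## accumulate a into the replicate-shifted position (row i -> min(i+1, H))
row_down <- function(a) {
  H <- dim(a)[2]
  b <- array(0, dim(a))
  b[, 2:H, ] <- a[, 1:(H - 1), , drop = FALSE]
  b[, H, ] <- b[, H, ] + a[, H, ]
  b
}
col_right <- function(a) {
  W <- dim(a)[3]
  b <- array(0, dim(a))
  b[, , 2:W] <- a[, , 1:(W - 1), drop = FALSE]
  b[, , W] <- b[, , W] + a[, , W]
  b
}

tp_local_soft_enhance <- function(tp, x) {
  xv <- x$value
  v <- window_views(xv)
  mx <- pmax(v$tl, v$tr, v$bl, v$br)
  e <- lapply(v, function(a) exp(a - mx))
  z <- e$tl + e$tr + e$bl + e$br
  w <- lapply(e, function(a) a / z)
  y <- w$tl * v$tl + w$tr * v$tr + w$bl * v$bl + w$br * v$br
  tp_node(tp, y, x$id, function(g) {
    ct <- function(role) g * w[[role]] * (1 + v[[role]] - y)
    list(ct("tl") + col_right(ct("tr")) + row_down(ct("bl")) +
           row_down(col_right(ct("br"))))
  })
}

## out[c,i,j] = x[c,i,j] * wh[c,i] * ww[c,j]
tp_pos_scale <- function(tp, x, wh, ww) {
  xv <- x$value; whv <- wh$value; wwv <- ww$value
  C <- dim(xv)[1]; H <- dim(xv)[2]; W <- dim(xv)[3]
  gh <- array(whv, c(C, H, W))
  gw <- aperm(array(wwv, c(C, W, H)), c(1, 3, 2))
  tp_node(tp, xv * gh * gw, c(x$id, wh$id, ww$id), function(g) {
    t1 <- g * xv
    dwh <- matrix(rowSums(matrix(t1 * gw, C * H, W)), C, H)
    dww <- matrix(rowSums(matrix(aperm(t1 * gh, c(1, 3, 2)), C * W, H)), C, W)
    list(g * gh * gw, dwh, dww)
  })
}

## out[c,i,j] = u[c,i,j] * gate[c]
tp_chan_scale <- function(tp, u, gate) {
  uv <- u$value; gv <- gate$value
  d <- dim(uv)
  ga <- array(gv, d)
  tp_node(tp, uv * ga, c(u$id, gate$id), function(g) {
    list(g * ga, rowSums(matrix(g * uv, d[1], d[2] * d[3])))
  })
}
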
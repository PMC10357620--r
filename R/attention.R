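#' Feature-map tensors
#'
#' Throughout the package a feature map is a numeric array with
#' `dim = c(C, H, W)`: `C` channels, `H` rows, `W` columns. All operators
#' require finite values and preserve this layout.
#'
#' @param x object to validate / coerce.
#' @param min_hw minimum spatial extent required by the caller.
#' @return `as_fmap()` returns the validated array.
#' @examples
#' x <- as_fmap(array(rnorm(2 * 4 * 5), c(2, 4, 5)))
#' dim(x)
#' @export
as_fmap <- function(x, min_hw = 1L) {
  if (is.matrix(x)) x <- array(x, c(1L, nrow(x), ncol(x)))
  if (!is.array(x) || length(dim(x)) != 3L)
    stop("feature map must be a 3-d array with dim (C, H, W)")
  if (!is.numeric(x)) stop("feature map must be numeric")
  if (!all(is.finite(x))) stop("feature map contains non-finite values")
  d <- dim(x)
  if (d[2] < min_hw || d[3] < min_hw)
    stop(sprintf("feature map spatial size %dx%d below required minimum %d",
                 d[2], d[3], min_hw))
  x
}

#' Hard-Swish activation
#'
#' Piecewise gate `x * clamp(x + 3, 0, 6) / 6`, applied elementwise. Exact at
#' the saturation endpoints: `hard_swish(-3) == 0`, `hard_swish(3) == 3`.
#'
#' @param x numeric vector or array.
#' @return object of the same shape.
#' @examples
#' hard_swish(c(-3, 0, 1, 3))
#' @export
hard_swish <- function(x) x * pmin(pmax(x + 3, 0), 6) / 6

sigmoid <- function(x) 1 / (1 + exp(-x))

## Shifted 2x2 window views of x under replicate padding (bottom/right).
## Returns list of four (C,H,W) arrays: top-left, top-right, bottom-left,
## bottom-right neighbour of each anchor position.
window_views <- function(x) {
  d <- dim(x); C <- d[1]; H <- d[2]; W <- d[3]
  ri <- c(seq_len(H - 1L) + 1L, H)   # row below, replicated at bottom
  ci <- c(seq_len(W - 1L) + 1L, W)   # col right, replicated at right
  list(tl = x,
       tr = x[, , ci, drop = FALSE],
       bl = x[, ri, , drop = FALSE],
       br = x[, ri, ci, drop = FALSE])
}

#' Local soft enhancement
#'
#' Replaces each element by the softmax-weighted average of its 2x2
#' neighbourhood (the element itself plus its right, lower and lower-right
#' neighbours, with replicate padding at the bottom/right edge). The weights
#' are the softmax of the four activations, so the kernel is data-dependent
#' and carries no learned parameters; each output lies within the min/max of
#' its window, and a constant map is returned unchanged.
#'
#' @param x feature map, `dim (C, H, W)` with `H, W >= 2`.
#' @param return_weights if `TRUE`, also return the four weight planes
#'   (each `dim (C, H, W)`; they sum to 1 at every position).
#' @return enhanced feature map, or a list `(values, weights)` when
#'   `return_weights = TRUE`.
#' @examples
#' x <- array(c(0, 0, 0, log(3)), c(1, 2, 2))
#' local_soft_enhance(x)[1, 1, 1]  # 3*log(3)/6
#' @export
local_soft_enhance <- function(x, return_weights = FALSE) {
  x <- as_fmap(x, min_hw = 2L)
  v <- window_views(x)
  m <- pmax(v$tl, v$tr, v$bl, v$br)
  e <- lapply(v, function(a) exp(a - m))
  z <- e$tl + e$tr + e$bl + e$br
  out <- (e$tl * v$tl + e$tr * v$tr + e$bl * v$bl + e$br * v$br) / z
  if (return_weights)
    list(values = out, weights = lapply(e, function(a) a / z))
  else out
}

#' Directional average pooling
#'
#' Global average pooling separately along the width and height dimensions:
#' `h_pool[c, h]` is the mean over the W columns of row `h`, `w_pool[c, w]`
#' the mean over the H rows of column `w`. These directional descriptors
#' retain position along one axis while summarising the other, which is what
#' lets the position attention branch localise along both axes.
#'
#' @param x feature map, `dim (C, H, W)`.
#' @return list with `h_pool` (`C x H` matrix) and `w_pool` (`C x W` matrix).
#' @examples
#' directional_avg_pool(array(1:6, c(1, 2, 3)))
#' @export
directional_avg_pool <- function(x) {
  x <- as_fmap(x)
  d <- dim(x); C <- d[1]; H <- d[2]; W <- d[3]
  h_pool <- matrix(rowSums(matrix(x, C * H, W)), C, H)
  w_pool <- matrix(rowSums(matrix(aperm(x, c(1, 3, 2)), C * W, H)), C, W)
  list(h_pool = h_pool / W, w_pool = w_pool / H)
}

#' Soft pooling of each channel
#'
#' Exponential-weight activation pooling: each channel is reduced to
#' `sum(softmax(U_c) * U_c)`, so every position contributes but strong
#' activations dominate. The result always lies between the channel mean and
#' the channel maximum (strictly, unless the channel is constant), which is
#' why it preserves more of the salient signal than plain average pooling.
#' Exponentials are stabilised by subtracting the per-channel maximum.
#'
#' @param u feature map, `dim (C, H, W)`.
#' @return numeric vector of length `C`.
#' @examples
#' soft_pool_channel(array(c(0, log(3)), c(1, 2, 1)))  # 0.75 * log(3)
#' @export
soft_pool_channel <- function(u) {
  u <- as_fmap(u)
  C <- dim(u)[1]
  m <- matrix(u, C, dim(u)[2] * dim(u)[3])
  mx <- apply(m, 1, max)
  e <- exp(m - mx)
  rowSums(e * m) / rowSums(e)
}

global_avg_pool <- function(u) {
  C <- dim(u)[1]
  rowMeans(matrix(u, C, dim(u)[2] * dim(u)[3]))
}

## ---- parameters -----------------------------------------------------------

#' Attention-block parameters
#'
#' Creates the learnable parameter set for the serial position/channel
#' attention block on feature maps with `C` channels. Both branches use a
#' bottleneck of width `max(1, floor(C / r))`: the position branch transforms
#' the concatenated directional descriptors with a pointwise map `C -> C/r`,
#' splits back into height and width parts and restores each to `C` channels;
#' the channel branch reduces and re-expands the pooled channel descriptors
#' through a (by default shared) two-layer bottleneck. Biases start at zero;
#' weights are Gaussian with sd `1/sqrt(fan_in)` (or all zero with
#' `init = "zero"`, which makes the zero-gate identities exact).
#'
#' @param C channel count of the maps the block will see.
#' @param r reduction ratio (default 16, as in the squeeze-excite family).
#' @param shared_mlp share the channel bottleneck between the average-pool and
#'   soft-pool branches (default `TRUE`).
#' @param position_gate activation for the position attention maps,
#'   `"hard_swish"` (default) or `"sigmoid"`.
#' @param init `"random"` or `"zero"`.
#' @param seed optional integer seed for reproducible initialisation.
#' @return an object of class `attention_params`.
#' @export
attention_params <- function(C, r = 16L, shared_mlp = TRUE,
                             position_gate = c("hard_swish", "sigmoid"),
                             init = c("random", "zero"), seed = NULL) {
  stopifnot(C >= 1, r >= 1)
  position_gate <- match.arg(position_gate)
  init <- match.arg(init)
  cr <- max(1L, as.integer(floor(C / r)))
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(seed)
  }
  w <- function(nr, nc) {
    if (init == "zero") matrix(0, nr, nc)
    else matrix(stats::rnorm(nr * nc, sd = 1 / sqrt(nc)), nr, nc)
  }
  ## random init starts the position gates at the hard-Swish unit fixed
  ## point (x with x*(x+3)/6 = 1), so the block begins near pass-through
  ## instead of zeroing the map; zero init keeps the exact zero-gate cases
  gb <- if (init == "zero") 0 else if (position_gate == "hard_swish")
    (-3 + sqrt(33)) / 2 else 0
  p <- list(
    C = as.integer(C), r = as.integer(r), cr = cr,
    shared_mlp = shared_mlp, position_gate = position_gate,
    pos = list(w1 = w(cr, C), b1 = numeric(cr),
               wh = w(C, cr), bh = rep(gb, C),
               ww = w(C, cr), bw = rep(gb, C)),
    chan = list(w1 = w(cr, C), b1 = numeric(cr),
                w2 = w(C, cr), b2 = numeric(C))
  )
  if (!shared_mlp)
    p$chan2 <- list(w1 = w(cr, C), b1 = numeric(cr),
                    w2 = w(C, cr), b2 = numeric(C))
  class(p) <- "attention_params"
  p
}

check_params_fit <- function(params, C) {
  if (!inherits(params, "attention_params"))
    stop("params must be created by attention_params()")
  if (params$C != C)
    stop(sprintf("params sized for C=%d but feature map has C=%d", params$C, C))
  invisible(params)
}

## Position-branch weight vectors for a given map; shared by the pure
## operator and the autodiff forward.
position_weights <- function(x, params) {
  d <- dim(x); C <- d[1]; H <- d[2]; W <- d[3]
  dp <- directional_avg_pool(local_soft_enhance(x))
  x1 <- cbind(dp$h_pool, dp$w_pool)                    # C x (H + W)
  t1 <- params$pos$w1 %*% x1 + params$pos$b1           # cr x (H + W)
  fh <- params$pos$wh %*% t1[, seq_len(H), drop = FALSE] + params$pos$bh
  fw <- params$pos$ww %*% t1[, H + seq_len(W), drop = FALSE] + params$pos$bw
  act <- if (params$position_gate == "hard_swish") hard_swish else sigmoid
  list(wh = act(fh), ww = act(fw))                      # C x H, C x W
}

#' Position attention
#'
#' Gates a feature map along both spatial axes. The input is locally
#' soft-enhanced, pooled directionally, and the two descriptors are
#' concatenated along the spatial axis and mixed by a pointwise `C -> C/r`
#' transform; the result is split back into height and width parts, each
#' restored to `C` channels and passed through the position gate (hard-Swish
#' by default). The original (pre-enhancement) map is then multiplied by the
#' per-row and per-column weights:
#' `out[c,i,j] = x[c,i,j] * wh[c,i] * ww[c,j]`.
#'
#' @param x feature map, `dim (C, H, W)` with `H, W >= 2`.
#' @param params an [attention_params] object sized for `C`.
#' @param return_weights if `TRUE`, also return the `wh`/`ww` weight matrices.
#' @return attended feature map of the same shape, or a list
#'   `(values, wh, ww)`.
#' @export
position_attention <- function(x, params, return_weights = FALSE) {
  x <- as_fmap(x, min_hw = 2L)
  check_params_fit(params, dim(x)[1])
  pw <- position_weights(x, params)
  out <- x * pos_weight_grid(pw$wh, pw$ww)
  if (!all(is.finite(out))) stop("non-finite values in position attention output")
  if (return_weights) list(values = out, wh = pw$wh, ww = pw$ww) else out
}

## Expand (C,H) and (C,W) weight matrices to a full (C,H,W) multiplier grid.
pos_weight_grid <- function(wh, ww) {
  C <- nrow(wh); H <- ncol(wh); W <- ncol(ww)
  array(wh, c(C, H, W)) * aperm(array(ww, c(C, W, H)), c(1, 3, 2))
}

chan_mlp <- function(s, w1, b1, w2, b2) {
  drop(w2 %*% pmax(w1 %*% s + b1, 0) + b2)
}

#' Per-channel attention gate
#'
#' Channel descriptor pathway of the channel attention module: global average
#' pooling and global soft pooling run in parallel, each descriptor passes
#' through the bottleneck (`C -> C/r -> C`, ReLU in the middle, shared between
#' branches by default), the two outputs are fused by addition and squashed by
#' a sigmoid. The gate is therefore strictly inside (0, 1).
#'
#' @inheritParams channel_attention
#' @return numeric vector of length `C`.
#' @export
channel_gate <- function(u, params) {
  u <- as_fmap(u)
  check_params_fit(params, dim(u)[1])
  s1 <- global_avg_pool(u)
  s2 <- soft_pool_channel(u)
  p1 <- params$chan
  p2 <- if (params$shared_mlp) params$chan else params$chan2
  sigmoid(chan_mlp(s1, p1$w1, p1$b1, p1$w2, p1$b2) +
          chan_mlp(s2, p2$w1, p2$b1, p2$w2, p2$b2))
}

#' Channel attention
#'
#' Rescales each channel of `u` by the gate computed by [channel_gate()]:
#' `out[c,i,j] = u[c,i,j] * g[c]` with `0 < g[c] < 1`.
#'
#' @param u feature map, `dim (C, H, W)`.
#' @param params an [attention_params] object sized for `C`.
#' @param return_gate if `TRUE`, also return the gate vector.
#' @return attended feature map, or a list `(values, gate)`.
#' @export
channel_attention <- function(u, params, return_gate = FALSE) {
  u <- as_fmap(u)
  g <- channel_gate(u, params)
  out <- u * array(g, dim(u))
  if (return_gate) list(values = out, gate = g) else out
}

#' Serial attention block
#'
#' Composition of the position and channel attention modules. The default
#' order applies position attention first, then channel attention — the
#' serial ordering that performed best in ablation — but the order is
#' configurable to support ablations.
#'
#' @param x feature map, `dim (C, H, W)`.
#' @param params an [attention_params] object sized for `C`.
#' @param order one of `"pos_then_chan"` (default), `"chan_then_pos"`,
#'   `"pos_only"`, `"chan_only"`, `"none"`.
#' @return attended feature map of the same shape as `x`.
#' @export
attention_block <- function(x, params,
                            order = c("pos_then_chan", "chan_then_pos",
                                      "pos_only", "chan_only", "none")) {
  order <- match.arg(order)
  switch(order,
         pos_then_chan = channel_attention(position_attention(x, params), params),
         chan_then_pos = position_attention(channel_attention(x, params), params),
         pos_only      = position_attention(x, params),
         chan_only     = channel_attention(x, params),
         none          = as_fmap(x))
}

#' Parameter count of one attention block
#'
#' Closed form for the number of scalar parameters in an [attention_params]
#' object: position branch `cr*C + cr + 2*(C*cr + C)`, channel branch
#' `cr*C + cr + C*cr + C` (doubled when the bottleneck is not shared), with
#' `cr = max(1, floor(C/r))`.
#'
#' @inheritParams attention_params
#' @return integer.
#' @export
attention_param_count <- function(C, r = 16L, shared_mlp = TRUE) {
  cr <- max(1L, as.integer(floor(C / r)))
  pos <- (cr * C + cr) + 2L * (C * cr + C)
  chan <- (cr * C + cr) + (C * cr + C)
  pos + chan * (if (shared_mlp) 1L else 2L)
}
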
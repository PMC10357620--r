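#' Pyramid feature triples
#'
#' Backbone outputs at strides 8/16/32 are carried as a list
#' `(F2, F3, F4)` of feature maps whose spatial sizes halve exactly at each
#' level: `H(F2) = 2 H(F3) = 4 H(F4)` (and likewise for widths).
#'
#' @param F2,F3,F4 feature maps (`dim (C, H, W)`).
#' @return validated list of class `pyramid_features`.
#' @export
pyramid_features <- function(F2, F3, F4) {
  F2 <- as_fmap(F2); F3 <- as_fmap(F3); F4 <- as_fmap(F4)
  d2 <- dim(F2); d3 <- dim(F3); d4 <- dim(F4)
  if (d2[2] != 2L * d3[2] || d3[2] != 2L * d4[2] ||
      d2[3] != 2L * d3[3] || d3[3] != 2L * d4[3])
    stop("pyramid stride relation violated: need H(F2)=2H(F3)=4H(F4), same for W")
  structure(list(F2 = F2, F3 = F3, F4 = F4), class = "pyramid_features")
}

#' Nearest-neighbour upsampling
#'
#' Integer-factor nearest-neighbour interpolation with the `floor(i/f)` index
#' map: output pixel `(i, j)` copies source pixel `(ceiling(i/f),
#' ceiling(j/f))` (1-based).
#'
#' @param x feature map `dim (C, H, W)`.
#' @param f positive integer factor.
#' @return feature map `dim (C, f*H, f*W)`.
#' @export
upsample_nearest <- function(x, f) {
  x <- as_fmap(x)
  d <- dim(x)
  x[, rep(seq_len(d[2]), each = f), rep(seq_len(d[3]), each = f), drop = FALSE]
}

#' Neck configuration
#'
#' @param channels common channel width of the fused maps (default 128).
#' @param conv_block_depth number of convolutions in the post-concatenation
#'   block, alternating 1x1 and 3x3 kernels starting at 1x1 (default 5).
#' @param reduction_ratio,order,position_gate,shared_mlp attention settings,
#'   see [attention_params()] and [attention_block()].
#' @return a list of class `neck_config`.
#' @export
neck_config <- function(channels = 128L, conv_block_depth = 5L,
                        reduction_ratio = 16L, order = "pos_then_chan",
                        position_gate = "hard_swish", shared_mlp = TRUE) {
  structure(list(channels = as.integer(channels),
                 conv_block_depth = as.integer(conv_block_depth),
                 reduction_ratio = as.integer(reduction_ratio),
                 order = order, position_gate = position_gate,
                 shared_mlp = shared_mlp),
            class = "neck_config")
}

conv_init <- function(cout, cin, k, init) {
  if (init == "zero") w <- array(0, c(cout, cin, k, k))
  else w <- array(stats::rnorm(cout * cin * k * k, sd = sqrt(2 / (cin * k * k))),
                  c(cout, cin, k, k))
  list(w = w, b = numeric(cout))
}

flatten_attention <- function(p, prefix) {
  out <- list()
  for (br in c("pos", "chan", if (!p$shared_mlp) "chan2")) {
    for (nm in names(p[[br]]))
      out[[paste0(prefix, br, ".", nm)]] <- p[[br]][[nm]]
  }
  out
}

#' Neck parameters
#'
#' Initialises all learnable parameters of the attentional fusion neck for
#' backbone widths `(c2, c3, c4)`: the post-concatenation conv block, the N2
#' head, the stride-2 downsampling convolutions, the 1x1 lateral projections
#' of F3/F4, the N3/N4 fusion convolutions, and (unless `cfg$order ==
#' "none"`) one attention block per output level.
#'
#' @param c2,c3,c4 backbone channel widths at strides 8/16/32.
#' @param cfg a [neck_config()].
#' @param init `"random"` or `"zero"`.
#' @param seed optional seed for reproducible initialisation.
#' @return flat named list of numeric arrays.
#' @export
neck_params <- function(c2, c3, c4, cfg = neck_config(),
                        init = c("random", "zero"), seed = NULL) {
  init <- match.arg(init)
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(seed)
  }
  nc <- cfg$channels
  p <- list()
  cin <- c2 + c3 + c4
  for (i in seq_len(cfg$conv_block_depth)) {
    k <- if (i %% 2L == 1L) 1L else 3L
    cv <- conv_init(nc, if (i == 1L) cin else nc, k, init)
    p[[paste0("fuse.conv", i, ".w")]] <- cv$w
    p[[paste0("fuse.conv", i, ".b")]] <- cv$b
  }
  for (nm in c("n2", "down2", "down3", "n3", "n4")) {
    cin_k <- switch(nm, n2 = nc, down2 = nc, down3 = nc, n3 = 2L * nc, n4 = 2L * nc)
    cv <- conv_init(nc, cin_k, 3L, init)
    p[[paste0(nm, ".w")]] <- cv$w; p[[paste0(nm, ".b")]] <- cv$b
  }
  cv <- conv_init(nc, c3, 1L, init); p[["lat3.w"]] <- cv$w; p[["lat3.b"]] <- cv$b
  cv <- conv_init(nc, c4, 1L, init); p[["lat4.w"]] <- cv$w; p[["lat4.b"]] <- cv$b
  if (cfg$order != "none") {
    for (lev in c("att2.", "att3.", "att4.")) {
      ap <- attention_params(nc, r = cfg$reduction_ratio,
                             shared_mlp = cfg$shared_mlp,
                             position_gate = cfg$position_gate, init = init)
      p <- c(p, flatten_attention(ap, lev))
    }
  }
  p
}

#' Closed-form neck parameter count
#'
#' Hand-computed parameter total of [neck_params()]; used to guard against
#' silent architecture drift.
#'
#' @inheritParams neck_params
#' @return integer count.
#' @export
neck_param_count <- function(c2, c3, c4, cfg = neck_config()) {
  nc <- cfg$channels
  cin <- c2 + c3 + c4
  n <- 0L
  for (i in seq_len(cfg$conv_block_depth)) {
    k <- if (i %% 2L == 1L) 1L else 3L
    ci <- if (i == 1L) cin else nc
    n <- n + nc * ci * k * k + nc
  }
  n <- n + 3L * (nc * nc * 9L + nc)            # n2, down2, down3
  n <- n + 2L * (nc * 2L * nc * 9L + nc)       # n3, n4
  n <- n + (nc * c3 + nc) + (nc * c4 + nc)     # lat3, lat4
  if (cfg$order != "none")
    n <- n + 3L * attention_param_count(nc, cfg$reduction_ratio, cfg$shared_mlp)
  n
}

## ---- tape forwards --------------------------------------------------------

ad_conv_act <- function(tp, x, get, name, stride = 1L, act = TRUE) {
  w <- get(paste0(name, ".w"))
  k <- dim(w$value)[3]
  out <- tp_conv2d(tp, x, w, get(paste0(name, ".b")),
                   stride = stride, pad = (k - 1L) %/% 2L)
  if (act) tp_leaky_relu(tp, out) else out
}

tp_as_col <- function(tp, v) {
  n <- length(v$value)
  tp_node(tp, matrix(v$value, n, 1L), v$id, function(g) list(drop(g)))
}

ad_chan_mlp <- function(tp, s, get, prefix) {
  z <- tp_add_colvec(tp, tp_matmul(tp, get(paste0(prefix, "w1")), s),
                     get(paste0(prefix, "b1")))
  tp_add_colvec(tp, tp_matmul(tp, get(paste0(prefix, "w2")), tp_relu(tp, z)),
                get(paste0(prefix, "b2")))
}

ad_position_attention <- function(tp, x, get, prefix, cfg) {
  d <- dim(x$value); H <- d[2]; W <- d[3]
  enh <- tp_local_soft_enhance(tp, x)
  x1 <- tp_concat_cols(tp, tp_pool_h(tp, enh), tp_pool_w(tp, enh))
  t1 <- tp_add_colvec(tp, tp_matmul(tp, get(paste0(prefix, "pos.w1")), x1),
                      get(paste0(prefix, "pos.b1")))
  fh <- tp_add_colvec(tp, tp_matmul(tp, get(paste0(prefix, "pos.wh")),
                                    tp_slice_cols(tp, t1, seq_len(H))),
                      get(paste0(prefix, "pos.bh")))
  fw <- tp_add_colvec(tp, tp_matmul(tp, get(paste0(prefix, "pos.ww")),
                                    tp_slice_cols(tp, t1, H + seq_len(W))),
                      get(paste0(prefix, "pos.bw")))
  act <- if (cfg$position_gate == "hard_swish") tp_hard_swish else tp_sigmoid
  tp_pos_scale(tp, x, act(tp, fh), act(tp, fw))
}

ad_channel_attention <- function(tp, u, get, prefix, cfg) {
  s1 <- tp_as_col(tp, tp_gap(tp, u))
  s2 <- tp_as_col(tp, tp_softpool(tp, u))
  p2 <- if (cfg$shared_mlp) paste0(prefix, "chan.") else paste0(prefix, "chan2.")
  z <- tp_add(tp, ad_chan_mlp(tp, s1, get, paste0(prefix, "chan.")),
              ad_chan_mlp(tp, s2, get, p2))
  tp_chan_scale(tp, u, tp_sigmoid(tp, z))
}

ad_attention_block <- function(tp, x, get, prefix, cfg) {
  switch(cfg$order,
         pos_then_chan = ad_channel_attention(
           tp, ad_position_attention(tp, x, get, prefix, cfg), get, prefix, cfg),
         chan_then_pos = ad_position_attention(
           tp, ad_channel_attention(tp, x, get, prefix, cfg), get, prefix, cfg),
         pos_only = ad_position_attention(tp, x, get, prefix, cfg),
         chan_only = ad_channel_attention(tp, x, get, prefix, cfg),
         none = x)
}

ad_fuse_levels <- function(tp, f2, f3, f4, get, cfg) {
  cat <- tp_concat_chan(tp, list(f2,
                                 tp_upsample_nearest(tp, f3, 2L),
                                 tp_upsample_nearest(tp, f4, 4L)))
  x <- cat
  for (i in seq_len(cfg$conv_block_depth))
    x <- ad_conv_act(tp, x, get, paste0("fuse.conv", i))
  x
}

ad_build_pyramid <- function(tp, base, f3, f4, get, cfg) {
  n2 <- ad_conv_act(tp, base, get, "n2")
  d2 <- ad_conv_act(tp, n2, get, "down2", stride = 2L)
  l3 <- ad_conv_act(tp, f3, get, "lat3")
  n3 <- ad_conv_act(tp, tp_concat_chan(tp, list(d2, l3)), get, "n3")
  d3 <- ad_conv_act(tp, n3, get, "down3", stride = 2L)
  l4 <- ad_conv_act(tp, f4, get, "lat4")
  n4 <- ad_conv_act(tp, tp_concat_chan(tp, list(d3, l4)), get, "n4")
  list(N2 = n2, N3 = n3, N4 = n4)
}

ad_neck_forward <- function(tp, f2, f3, f4, get, cfg) {
  base <- ad_fuse_levels(tp, f2, f3, f4, get, cfg)
  pyr <- ad_build_pyramid(tp, base, f3, f4, get, cfg)
  att <- list(
    A2 = ad_attention_block(tp, pyr$N2, get, "att2.", cfg),
    A3 = ad_attention_block(tp, pyr$N3, get, "att3.", cfg),
    A4 = ad_attention_block(tp, pyr$N4, get, "att4.", cfg))
  c(list(base = base), pyr, att)
}

make_getter <- function(tp, params) {
  leaves <- lapply(params, function(v) tp_leaf(tp, v))
  function(nm) {
    h <- leaves[[nm]]
    if (is.null(h)) stop("unknown parameter: ", nm)
    h
  }
}

## ---- pure module surface --------------------------------------------------

#' Fuse the three backbone levels into one base map
#'
#' Upsamples F3 (x2) and F4 (x4) to F2's spatial size by nearest-neighbour
#' interpolation, concatenates all three along the channel axis
#' (`c2 + c3 + c4` channels) and passes the result through the alternating
#' 1x1/3x3 convolution block, yielding the fused base map at F2 scale with
#' `cfg$channels` channels.
#'
#' @param p a [pyramid_features()] triple.
#' @param params a [neck_params()] list sized for the pyramid's widths.
#' @param cfg a [neck_config()].
#' @return feature map at F2 scale.
#' @export
fuse_backbone_levels <- function(p, params, cfg = neck_config()) {
  stopifnot(inherits(p, "pyramid_features"))
  tp <- tape_new()
  get <- make_getter(tp, params)
  ad_fuse_levels(tp, tp_leaf(tp, p$F2), tp_leaf(tp, p$F3), tp_leaf(tp, p$F4),
                 get, cfg)$value
}

#' Grow the bottom-up pyramid N2..N4
#'
#' `N2 = conv(base)`; each deeper level concatenates a stride-2 convolution
#' of the previous level with the 1x1-projected backbone lateral and fuses
#' them with a 3x3 convolution: `N3 = conv(cat(down(N2), lat(F3)))`,
#' `N4 = conv(cat(down(N3), lat(F4)))`.
#'
#' @param base fused base map from [fuse_backbone_levels()].
#' @param p the [pyramid_features()] triple.
#' @inheritParams fuse_backbone_levels
#' @return list `(N2, N3, N4)` of feature maps at strides 8/16/32.
#' @export
build_pyramid <- function(base, p, params, cfg = neck_config()) {
  tp <- tape_new()
  get <- make_getter(tp, params)
  out <- ad_build_pyramid(tp, tp_leaf(tp, as_fmap(base)),
                          tp_leaf(tp, p$F3), tp_leaf(tp, p$F4), get, cfg)
  lapply(out, `[[`, "value")
}

#' Apply one attention block per pyramid level
#'
#' Applies the serial attention block with level-specific parameters
#' (`att2.*`, `att3.*`, `att4.*`) to each of N2..N4. With
#' `cfg$order == "none"` the maps pass through unchanged.
#'
#' @param n list `(N2, N3, N4)` from [build_pyramid()].
#' @inheritParams fuse_backbone_levels
#' @return list `(A2, A3, A4)` of attended maps, same shapes as the inputs.
#' @export
apply_attention_heads <- function(n, params, cfg = neck_config()) {
  tp <- tape_new()
  get <- make_getter(tp, params)
  out <- list(A2 = ad_attention_block(tp, tp_leaf(tp, as_fmap(n$N2)), get, "att2.", cfg),
              A3 = ad_attention_block(tp, tp_leaf(tp, as_fmap(n$N3)), get, "att3.", cfg),
              A4 = ad_attention_block(tp, tp_leaf(tp, as_fmap(n$N4)), get, "att4.", cfg))
  lapply(out, `[[`, "value")
}

#' Full neck forward pass
#'
#' Convenience composition of [fuse_backbone_levels()], [build_pyramid()] and
#' [apply_attention_heads()] in one pass.
#'
#' @inheritParams fuse_backbone_levels
#' @return list `(base, N2, N3, N4, A2, A3, A4)`.
#' @export
neck_forward <- function(p, params, cfg = neck_config()) {
  stopifnot(inherits(p, "pyramid_features"))
  tp <- tape_new()
  get <- make_getter(tp, params)
  out <- ad_neck_forward(tp, tp_leaf(tp, p$F2), tp_leaf(tp, p$F3),
                         tp_leaf(tp, p$F4), get, cfg)
  lapply(out, `[[`, "value")
}
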
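test_that("hard-Swish matches its closed form and saturation endpoints", {
  expect_identical(hard_swish(0), 0)
  expect_identical(hard_swish(3), 3)
  expect_identical(hard_swish(-3), 0)
  expect_equal(hard_swish(1), 2 / 3, tolerance = 1e-12)
  x <- rnorm(100, sd = 4)
  expect_equal(hard_swish(x), oracle_hswish(x), tolerance = 1e-12)
})

test_that("local soft enhancement reproduces hand-computed window values", {
  ## constant map is a fixed point: softmax of equal values averages to itself
  cst <- array(5, c(2, 3, 4))
  expect_equal(local_soft_enhance(cst), cst, tolerance = 1e-12)
  ## 2x2 window (0, 0, 0, ln 3): weights (1,1,1,3)/6, value 3 ln3 / 6
  x <- array(0, c(1, 2, 2)); x[1, 2, 2] <- log(3)
  expect_equal(local_soft_enhance(x)[1, 1, 1], 3 * log(3) / 6, tolerance = 1e-9)
})

test_that("local soft enhancement agrees with the scalar loop oracle", {
  set.seed(41)
  for (k in 1:20) {
    x <- rand_fmap(sample(1:4, 1), sample(2:9, 1), sample(2:9, 1), sd = 2)
    expect_equal(local_soft_enhance(x), oracle_enhance(x), tolerance = 1e-6)
  }
})

test_that("window softmax weights sum to one and outputs stay in window bounds", {
  set.seed(42)
  for (k in 1:10) {
    x <- rand_fmap(2, sample(2:8, 1), sample(2:8, 1), sd = 3)
    le <- local_soft_enhance(x, return_weights = TRUE)
    wsum <- Reduce(`+`, le$weights)
    expect_lt(max(abs(wsum - 1)), 1e-7)
    d <- dim(x)
    for (c in seq_len(d[1])) for (i in seq_len(d[2])) for (j in seq_len(d[3])) {
      i2 <- min(i + 1, d[2]); j2 <- min(j + 1, d[3])
      win <- c(x[c, i, j], x[c, i, j2], x[c, i2, j], x[c, i2, j2])
      expect_gte(le$values[c, i, j], min(win) - 1e-12)
      expect_lte(le$values[c, i, j], max(win) + 1e-12)
    }
  }
})

test_that("enhancement rejects degenerate or non-finite inputs", {
  expect_error(local_soft_enhance(array(1, c(2, 1, 5))), "spatial size")
  expect_error(local_soft_enhance(array(NaN, c(1, 2, 2))), "finite")
})

test_that("directional pooling gives exact row and column means", {
  x <- array(0, c(1, 2, 3))
  x[1, , ] <- rbind(c(1, 2, 3), c(4, 5, 6))
  dp <- directional_avg_pool(x)
  expect_equal(drop(dp$h_pool), c(2, 5))
  expect_equal(drop(dp$w_pool), c(2.5, 3.5, 4.5))
  ## constant rows collapse to the row constant
  y <- array(rep(1:3, times = 4 * 5), c(3, 4, 5))
  expect_true(all(directional_avg_pool(y)$h_pool == matrix(1:3, 3, 4)))
  ## both descriptors average the same elements
  set.seed(7)
  z <- rand_fmap(3, 5, 6)
  dp <- directional_avg_pool(z)
  expect_equal(rowMeans(dp$h_pool), rowMeans(dp$w_pool), tolerance = 1e-12)
  expect_equal(rowMeans(dp$h_pool), apply(z, 1, mean), tolerance = 1e-12)
  expect_equal(dp, oracle_dirpool(z), tolerance = 1e-12)
})

test_that("soft pooling matches hand values and sits between mean and max", {
  expect_equal(soft_pool_channel(array(2.5, c(1, 3, 3))), 2.5, tolerance = 1e-12)
  expect_equal(soft_pool_channel(array(c(0, log(3)), c(1, 2, 1))),
               0.75 * log(3), tolerance = 1e-9)
  set.seed(11)
  for (k in 1:100) {
    u <- rand_fmap(sample(1:4, 1), sample(2:6, 1), sample(2:6, 1), sd = 2)
    s2 <- soft_pool_channel(u)
    expect_equal(s2, oracle_softpool(u), tolerance = 1e-6)
    for (c in seq_len(dim(u)[1])) {
      expect_gt(s2[c], mean(u[c, , ]))
      expect_lte(s2[c], max(u[c, , ]))
    }
  }
})

test_that("soft pooling is translation covariant", {
  set.seed(12)
  u <- rand_fmap(4, 5, 5)
  for (k in c(-3, 0.5, 10)) {
    expect_equal(soft_pool_channel(u + k), soft_pool_channel(u) + k,
                 tolerance = 1e-9)
  }
})

test_that("position attention applies the separable row/column gate exactly", {
  set.seed(21)
  ## zero-init params: descriptor transforms output 0, hard-Swish(0) = 0,
  ## so the whole map is gated to zero
  p0 <- attention_params(3, r = 2, init = "zero")
  x <- rand_fmap(3, 5, 4)
  expect_true(all(position_attention(x, p0) == 0))
  ## random params: triple-loop oracle over (c, i, j)
  for (k in 1:10) {
    C <- sample(2:6, 1)
    p <- attention_params(C, r = 2, seed = k)
    x <- rand_fmap(C, sample(2:9, 1), sample(2:9, 1))
    expect_equal(position_attention(x, p), oracle_position_attention(x, p),
                 tolerance = 1e-5)
  }
  ## weights returned match the multiplicative decomposition
  p <- attention_params(4, r = 2, seed = 5)
  x <- rand_fmap(4, 6, 5)
  pa <- position_attention(x, p, return_weights = TRUE)
  for (c in 1:4) for (i in 1:6) for (j in 1:5)
    expect_equal(pa$values[c, i, j], x[c, i, j] * pa$wh[c, i] * pa$ww[c, j],
                 tolerance = 1e-12)
})

test_that("channel attention gate is strictly inside (0,1) and matches the oracle", {
  set.seed(31)
  ## zero input with zero-init bias-free MLP: gate = sigmoid(0) = 0.5
  p0 <- attention_params(4, r = 2, init = "zero")
  z <- array(0, c(4, 3, 3))
  ca <- channel_attention(z, p0, return_gate = TRUE)
  expect_equal(ca$gate, rep(0.5, 4), tolerance = 1e-12)
  expect_true(all(ca$values == 0))
  for (k in 1:10) {
    C <- sample(2:8, 1)
    p <- attention_params(C, r = 4, seed = 100 + k)
    u <- rand_fmap(C, sample(2:6, 1), sample(2:6, 1), sd = 3)
    g <- channel_gate(u, p)
    expect_true(all(g > 0 & g < 1))
    out <- channel_attention(u, p)
    expect_equal(out, oracle_channel_attention(u, p), tolerance = 1e-5)
    ## strict shrinkage wherever the input is nonzero
    nz <- u != 0
    expect_true(all(abs(out[nz]) < abs(u[nz])))
  }
})

test_that("the serial block composes its two independently tested operators", {
  set.seed(51)
  p <- attention_params(5, r = 2, seed = 9)
  x <- rand_fmap(5, 6, 6)
  expect_identical(attention_block(x, p, order = "pos_then_chan"),
                   channel_attention(position_attention(x, p), p))
  expect_identical(attention_block(x, p, order = "chan_then_pos"),
                   position_attention(channel_attention(x, p), p))
  expect_identical(attention_block(x, p, order = "none"), x)
  ## zero-init position branch zeroes the whole serial output
  p0 <- attention_params(5, r = 2, init = "zero")
  expect_true(all(attention_block(x, p0) == 0))
  ## shapes preserved across sizes, no NaN on wide-variance input
  for (k in 1:8) {
    C <- sample(1:6, 1); H <- sample(2:9, 1); W <- sample(2:9, 1)
    y <- attention_block(rand_fmap(C, H, W, sd = 10),
                         attention_params(C, r = 4, seed = k))
    expect_identical(dim(y), c(C, H, W))
    expect_true(all(is.finite(y)))
  }
})

test_that("attention parameter shapes are validated against the map", {
  p <- attention_params(4, r = 2)
  expect_error(position_attention(rand_fmap(3, 4, 4), p), "sized for C=4")
  expect_error(channel_attention(rand_fmap(5, 4, 4), p), "sized for C=4")
})

test_that("every attention parameter receives gradient from a scalar loss", {
  pp <- asNamespace("polypatt")
  set.seed(61)
  prm <- flatten_params <- pp$flatten_attention(attention_params(6, r = 3, seed = 2), "a.")
  cfg <- list(order = "pos_then_chan", position_gate = "hard_swish",
              shared_mlp = TRUE)
  tp <- pp$tape_new()
  leaves <- lapply(prm, function(v) pp$tp_leaf(tp, v))
  get <- function(nm) leaves[[nm]]
  x <- pp$tp_leaf(tp, rand_fmap(6, 5, 7))
  out <- pp$ad_attention_block(tp, x, get, "a.", cfg)
  gr <- pp$tp_backward(tp, pp$tp_sum_all(tp, out))
  for (nm in names(prm)) {
    expect_gt(sum(abs(pp$tp_grad(gr, leaves[[nm]]))), 0)
  }
})
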
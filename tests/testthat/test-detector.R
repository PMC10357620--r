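test_that("the backbone emits the stride-8/16/32 pyramid", {
  cfg <- tiny_detector_cfg()
  prm <- init_detector_params(cfg, seed = 1)
  img <- array(runif(64 * 64 * 3), c(64, 64, 3))
  p <- tiny_backbone(img, prm, cfg)
  expect_identical(dim(p$F2), c(8L, 8L, 8L))
  expect_identical(dim(p$F3), c(10L, 4L, 4L))
  expect_identical(dim(p$F4), c(12L, 2L, 2L))
  ## stride arithmetic at another size
  img2 <- array(runif(96 * 96 * 3), c(96, 96, 3))
  p2 <- tiny_backbone(img2, prm, cfg)
  expect_identical(dim(p2$F2)[2:3], c(12L, 12L))
  expect_error(tiny_backbone(array(0, c(50, 50, 3)), prm, cfg), "divisible by 32")
  ## deterministic
  expect_identical(tiny_backbone(img, prm, cfg), p)
})

test_that("head decoding reproduces a scalar oracle box", {
  pp <- asNamespace("polypatt")
  anchors <- matrix(c(8, 8, 16, 16, 24, 24), ncol = 2, byrow = TRUE)
  S <- 4L
  hv <- array(-20, c(15, S, S))        # all objectness effectively off
  ## hand-set one activation: anchor 2, cell (i=3, j=2)
  tx <- 0.4; ty <- -0.3; tw <- 0.2; th <- -0.1; to <- 1.5
  hv[5 + 1:5, 3, 2] <- c(tx, ty, tw, th, to)
  d <- pp$decode_level(hv, anchors, 16L, 64, 64)
  d <- d[d$score > 0.5, ]
  expect_identical(nrow(d), 1L)
  sg <- function(v) 1 / (1 + exp(-v))
  cx <- (2 - 1 + sg(tx)) * 16; cy <- (3 - 1 + sg(ty)) * 16
  bw <- 16 * exp(tw); bh <- 16 * exp(th)
  expect_equal(d$x_min, cx - bw / 2, tolerance = 1e-5)
  expect_equal(d$y_max, cy + bh / 2, tolerance = 1e-5)
  expect_equal(d$score, sg(to), tolerance = 1e-9)
})

test_that("NMS keeps the highest-scoring duplicate and detect clips to bounds", {
  d <- data.frame(x_min = c(10, 10), y_min = c(10, 10), x_max = c(20, 20),
                  y_max = c(20, 20), score = c(0.9, 0.8))
  out <- nms(d, 0.5)
  expect_identical(nrow(out), 1L)
  expect_equal(out$score, 0.9)
  ## non-overlapping boxes all survive
  d2 <- data.frame(x_min = c(0, 50), y_min = c(0, 50), x_max = c(10, 60),
                   y_max = c(10, 60), score = c(0.3, 0.9))
  expect_identical(nrow(nms(d2, 0.5)), 2L)
  ## a randomly initialised model yields in-bounds, score-sorted detections
  cfg <- tiny_detector_cfg()
  prm <- init_detector_params(cfg, seed = 2)
  model <- structure(list(params = prm, config = cfg), class = "polyp_detector")
  img <- array(runif(64 * 64 * 3), c(64, 64, 3))
  dets <- detect(model, img, score_thr = 0)
  if (nrow(dets)) {
    expect_true(all(dets$x_min >= 0 & dets$y_min >= 0 &
                      dets$x_max <= 64 & dets$y_max <= 64))
    expect_true(!is.unsorted(rev(dets$score)))
  }
  ## forcing objectness far negative suppresses everything
  prm0 <- prm
  for (lev in c("head2", "head3", "head4")) {
    prm0[[paste0(lev, ".w")]][] <- 0
    b <- prm0[[paste0(lev, ".b")]]
    b[] <- 0; b[seq(5, length(b), by = 5)] <- -50
    prm0[[paste0(lev, ".b")]] <- b
  }
  model0 <- structure(list(params = prm0, config = cfg), class = "polyp_detector")
  expect_identical(nrow(detect(model0, img, score_thr = 0.01)), 0L)
})

test_that("target assignment puts each box at its best shape-matched anchor", {
  pp <- asNamespace("polypatt")
  cfg <- detector_config(image_size = 64L)
  boxes <- data.frame(x_min = 24, y_min = 16, x_max = 40, y_max = 32) # 16x16
  tgt <- pp$build_targets(boxes, 64, 64, cfg)
  ## 16x16 matches anchor 2 of level 1; centre (32, 24) -> cell j=5, i=4
  expect_equal(sum(tgt[[1]]$obj == 1), 1)
  expect_equal(tgt[[1]]$obj[2, 4, 5], 1)
  expect_equal(sum(tgt[[2]]$obj == 1) + sum(tgt[[3]]$obj == 1), 0)
  ## offsets: cx/8 = 4 -> gx = 0 in cell 5; tw = log(16/16) = 0
  expect_equal(tgt[[1]]$t[1, 2, 4, 5], 0)
  expect_equal(tgt[[1]]$t[3, 2, 4, 5], 0)
  ## a 64x48 box best matches the 64x64 anchor on the stride-16 level
  big <- data.frame(x_min = 0, y_min = 8, x_max = 64, y_max = 56)
  tgt2 <- pp$build_targets(big, 64, 64, cfg)
  expect_equal(sum(tgt2[[2]]$obj == 1), 1)
})

test_that("mosaic composition maps boxes by the exact affine transform", {
  set.seed(5)
  mk <- function(col, box) {
    img <- array(col, c(64, 64, 3))
    list(image = img, boxes = box)
  }
  ctr <- data.frame(x_min = 24, y_min = 24, x_max = 40, y_max = 40)
  samples <- lapply(c(0.2, 0.4, 0.6, 0.8), mk, box = ctr)
  ## centred split, equal source/quadrant sizes: pure translation
  mz <- mosaic_augment(samples, size = 128L, split = c(64, 64))
  expect_identical(nrow(mz$boxes), 4L)
  offs <- list(c(0, 0), c(64, 0), c(0, 64), c(64, 64))
  for (q in 1:4) {
    expect_equal(as.numeric(mz$boxes[q, ]),
                 as.numeric(ctr) + rep(offs[[q]], 2), tolerance = 1e-12)
  }
  ## one box per quadrant of the composite
  cx <- (mz$boxes$x_min + mz$boxes$x_max) / 2
  cy <- (mz$boxes$y_min + mz$boxes$y_max) / 2
  expect_identical(length(unique(paste(cx > 64, cy > 64))), 4L)
  ## general split: exact affine scale + offset per quadrant
  mz2 <- mosaic_augment(samples, size = 128L, split = c(48, 80))
  b1 <- as.numeric(mz2$boxes[1, ])           # TL quadrant: 48 x 80 target
  expect_equal(b1, c(24 * 48 / 64, 24 * 80 / 64, 40 * 48 / 64, 40 * 80 / 64),
               tolerance = 1e-12)
  ## seeded determinism is bitwise
  m1 <- mosaic_augment(samples, size = 128L, seed = 7)
  m2 <- mosaic_augment(samples, size = 128L, seed = 7)
  expect_identical(m1, m2)
  expect_error(mosaic_augment(samples[1:3], size = 128L), "four samples")
})

test_that("mosaic drops boxes degenerated below the minimum side", {
  sliver <- data.frame(x_min = 0, y_min = 30, x_max = 2.5, y_max = 34)
  smp <- list(image = array(0.5, c(64, 64, 3)), boxes = sliver)
  mz <- mosaic_augment(rep(list(smp), 4), size = 64L, split = c(32, 32))
  ## after halving, the 2.5-px side falls under 2 px and is dropped
  expect_identical(nrow(mz$boxes), 0L)
})

test_that("training freezes the backbone, records history, and is seeded", {
  set.seed(6)
  spec <- scene_spec(image_size = 64L, n_polyps = 1L, size_range = c(6, 20),
                     n_folds = 2L, n_speculars = 2L, seed = 3L)
  ds <- synthetic_dataset(2, spec)
  cfg <- tiny_detector_cfg()
  prm0 <- init_detector_params(cfg, seed = 4)
  bb_names <- grep("^backbone\\.", names(prm0), value = TRUE)
  ## freeze-only run: backbone bitwise unchanged, neck/heads move
  cfg_f <- tiny_detector_cfg(); cfg_f$thaw_epochs <- 0L; cfg_f$freeze_epochs <- 2L
  m_f <- polyp_detector(ds, cfg_f, params = prm0)
  expect_identical(m_f$params[bb_names], prm0[bb_names])
  expect_gt(max(abs(unlist(m_f$params[["neck.n2.w"]]) - unlist(prm0[["neck.n2.w"]]))), 0)
  ## thaw updates the backbone too
  cfg_t <- tiny_detector_cfg(); cfg_t$freeze_epochs <- 0L; cfg_t$thaw_epochs <- 1L
  m_t <- polyp_detector(ds, cfg_t, params = prm0)
  expect_gt(max(abs(unlist(m_t$params[bb_names]) - unlist(prm0[bb_names]))), 0)
  ## loss history: finite, one row per step, phases labelled
  m <- polyp_detector(ds, cfg, params = prm0)
  expect_identical(nrow(m$history), 4L)
  expect_true(all(is.finite(m$history$loss)))
  expect_identical(unique(m$history$phase), c("freeze", "thaw"))
  ## same seed, same data: identical loss curve
  m2 <- polyp_detector(ds, cfg, params = prm0)
  expect_identical(m$history$loss, m2$history$loss)
  expect_error(polyp_detector(list(), cfg), "empty dataset")
})

test_that("attention toggles change the parameter count by the closed form", {
  cfg_on <- tiny_detector_cfg()
  cfg_off <- tiny_detector_cfg()
  cfg_off$neck <- tiny_neck_cfg(order = "none")
  n_on <- sum(lengths(init_detector_params(cfg_on, seed = 1)))
  n_off <- sum(lengths(init_detector_params(cfg_off, seed = 1)))
  expect_identical(n_on - n_off,
                   3L * attention_param_count(cfg_on$neck$channels,
                                              cfg_on$neck$reduction_ratio))
})

test_that("model methods expose coefficients, summaries and predictions", {
  set.seed(8)
  ds <- synthetic_dataset(2, scene_spec(image_size = 64L, n_polyps = 1L,
                                        size_range = c(8, 20), n_folds = 1L,
                                        n_speculars = 1L, seed = 5L))
  m <- polyp_detector(ds, tiny_detector_cfg())
  expect_s3_class(m, "polyp_detector")
  co <- coef(m)
  expect_identical(length(co), m$n_params)
  expect_output(print(m), "freeze")
  s <- summary(m)
  expect_output(print(s), "parameters")
  d <- predict(m, ds[[1]], score_thr = 0)
  expect_true(is.data.frame(d))
  ## checkpoint round trip
  tmp <- tempfile(fileext = ".rds")
  save_checkpoint(m, tmp)
  m2 <- load_checkpoint(tmp)
  expect_identical(m2$params, m$params)
  expect_identical(detect(m2, ds[[1]]$image, score_thr = 0.1),
                   detect(m, ds[[1]]$image, score_thr = 0.1))
  unlink(tmp)
})
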
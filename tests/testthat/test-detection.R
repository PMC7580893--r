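test_that("target heatmaps are single-slice Gaussians combined by maximum", {
  pos <- positions_tbl(0, 10, 10, 3)
  hm <- make_target_heatmap(pos, c(8, 32, 32))
  expect_equal(hm[11, 11, 4], 1)
  # exp(-d^2 / (2 sigma^2)) with sigma = 2 at in-plane distance 2
  expect_equal(hm[13, 11, 4], exp(-4 / 8), tolerance = 1e-12)
  # the spot does not cross z-slices
  expect_equal(hm[11, 11, 3], 0)
  expect_equal(hm[11, 11, 5], 0)
  # empty list -> all-zero volume
  expect_equal(max(make_target_heatmap(positions_tbl(), c(8, 32, 32))), 0)
  # overlapping spots combine by max, staying <= 1
  two <- positions_tbl(c(0, 0), c(10, 12), c(10, 10), c(3, 3))
  hm2 <- make_target_heatmap(two, c(8, 32, 32))
  expect_lte(max(hm2), 1)
  expect_equal(hm2[11, 12, 4], max(exp(-1 / 8), exp(-1 / 8)))
  expect_error(make_target_heatmap(positions_tbl(0, 40, 10, 3), c(8, 32, 32)),
               "outside")
})

test_that("contrast adjustment follows the mean-anchored formula", {
  img <- array(c(0, 100), c(2, 1, 1))
  expect_equal(contrast_adjust(img, 1), img)
  expect_equal(as.numeric(contrast_adjust(img, 0.5)), c(25, 75))
  # pixel 120 with image mean 100 and c = 1.5 -> 130
  img2 <- array(c(80, 120), c(2, 1, 1))
  expect_equal(contrast_adjust(img2, 1.5)[2, 1, 1], 130)
})

test_that("augmentation is deterministic, shared, and flips are involutions", {
  img <- array(runif(16 * 16 * 4), c(16, 16, 4))
  tgt <- make_target_heatmap(positions_tbl(0, 5, 9, 2), c(4, 16, 16))
  a1 <- augment_pair(img, tgt, seed = 42)
  a2 <- augment_pair(img, tgt, seed = 42)
  expect_identical(a1, a2)
  expect_false(identical(a1$image, augment_pair(img, tgt, seed = 43)$image))
  expect_true(all(a1$target >= 0))

  # a pure x-flip mirrors positions and undoes itself
  flipped <- img[, 16:1, , drop = FALSE]
  expect_identical(flipped[, 16:1, , drop = FALSE], img)

  # 90-degree rotation moves an off-center spot to the rotated coordinates:
  # with the inverse-mapped transform, (x, y) -> (cx - (y - cy), cy + (x - cx))
  spot <- make_target_heatmap(positions_tbl(0, 11, 7, 0), c(1, 16, 16))
  rot <- nuctrackr:::rotate_scale_xy(spot, pi / 2, 1)
  peak <- which(rot == max(rot), arr.ind = TRUE)[1, ]
  cx <- 7.5; cy <- 7.5
  expect_lt(abs((peak[2] - 1) - (cx - (7 - cy))), 1.01)
  expect_lt(abs((peak[1] - 1) - (cy + (11 - cx))), 1.01)
})

test_that("weighted MSE boosts the rare foreground voxels", {
  tgt <- array(0, c(4, 4, 2)); tgt[1, 1, 1] <- 1
  expect_equal(weighted_mse(tgt, tgt), 0)
  # frozen hand computation: one background voxel off by 0.5, f = 1/32;
  # weighted mean = e^2 / (2 N (1 - f)) = 0.25 / 62
  pred <- tgt; pred[4, 4, 2] <- 0.5
  expect_equal(weighted_mse(pred, tgt), 0.25 / 62, tolerance = 1e-12)
  # quadratic homogeneity
  pred2 <- tgt + 2 * (pred - tgt)
  expect_equal(weighted_mse(pred2, tgt), 4 * weighted_mse(pred, tgt))
  # all-zero target falls back to plain MSE
  z <- array(0, c(4, 4, 2))
  expect_equal(weighted_mse(z + 0.1, z), 0.01, tolerance = 1e-12)
  # non-negativity, zero iff equal (random probes)
  set.seed(1)
  for (k in 1:5) {
    p <- array(runif(32), c(4, 4, 2)); t2 <- array(rbinom(32, 1, 0.2), c(4, 4, 2))
    expect_gte(weighted_mse(p, t2), 0)
  }
})

test_that("the detector maps inputs to same-shape outputs and uses position", {
  cfg <- detector_config(depth = 2, base_filters = 4, patch_xy = 16, seed = 3)
  m <- build_detector(cfg)
  img <- array(runif(16 * 16 * 8), c(16, 16, 8))
  pred <- nuctrackr:::detector_forward(m, img, dim(img))$pred
  expect_equal(dim(pred), dim(img))
  # same seed, same initial weights
  m2 <- build_detector(cfg)
  expect_identical(m$weights, m2$weights)
  # translating the patch while updating the coordinate channels changes the
  # output: the network is deliberately not translation-equivariant
  full <- c(64L, 64L, 8L)
  p0 <- nuctrackr:::detector_forward(m, img, full, offset = c(0L, 0L))$pred
  p1 <- nuctrackr:::detector_forward(m, img, full, offset = c(32L, 32L))$pred
  expect_gt(max(abs(p0 - p1)), 1e-6)
  expect_error(detector_config(depth = 3, patch_xy = 18), "divisible")
})

test_that("training reduces the loss and is reproducible", {
  set <- simulate_training_set(31, 6, n_nuclei = 5, image_shape = c(8, 32, 32))
  cfg <- detector_config(depth = 2, base_filters = 4, patch_xy = 32, epochs = 3,
                         batch_size = 2, learning_rate = 2e-3,
                         steps_per_epoch = 4, seed = 2)
  m <- build_detector(cfg)
  m <- train_detector(m, set$images, set$targets)
  expect_length(m$history, 3L)
  expect_lt(m$history[3], m$history[1])
  # reproducible loss history on CPU
  m2 <- train_detector(build_detector(cfg), set$images, set$targets)
  expect_identical(m$history, m2$history)
  expect_error(train_detector(build_detector(cfg), list(), list()), "empty")

  # constant-zero targets drive predictions toward zero
  zt <- lapply(set$targets, function(t) t * 0)
  m0 <- build_detector(cfg)
  pr0 <- predict_heatmap(m0, set$images[[1]])
  mz <- train_detector(m0, set$images, zt)
  pr <- predict_heatmap(mz, set$images[[1]])
  expect_lt(mean(abs(pr)), 0.5 * mean(abs(pr0)))
  expect_lt(mean(abs(pr)), 0.15)
})

test_that("model save/load roundtrips weights exactly", {
  cfg <- detector_config(depth = 2, base_filters = 4, patch_xy = 16, seed = 8)
  m <- build_detector(cfg)
  f <- withr::local_tempfile(fileext = ".json")
  save_detector(m, f)
  m2 <- load_detector(f)
  expect_equal(m$weights, m2$weights)
  img <- array(runif(16 * 16 * 4), c(16, 16, 4))
  expect_equal(predict_heatmap(m, img), predict_heatmap(m2, img))
})

test_that("peak detection interpolates z and respects the distance floor", {
  res <- image_resolution(0.32, 2, 12)
  # single spot
  hm <- make_target_heatmap(positions_tbl(0, 20, 12, 5), c(12, 40, 40))
  pk <- detect_peaks(hm, res)
  expect_equal(nrow(pk), 1L)
  expect_equal(c(pk$x, pk$y, pk$z), c(20, 12, 5))
  # all-zero heatmap is empty, not an error
  expect_equal(nrow(detect_peaks(array(0, c(8, 8, 4)), res)), 0L)
  # two spots 10 um apart with a 3 um floor -> both survive
  two <- positions_tbl(c(0, 0), c(10, 10 + 10 / 0.32), c(10, 10), c(3, 3))
  hm2 <- make_target_heatmap(two, c(8, 64, 64))
  expect_equal(nrow(detect_peaks(hm2, res, min_distance_um = 3)), 2L)
  # two spots 2 um apart with a 3 um floor -> suppressed to one
  close2 <- positions_tbl(c(0, 0), c(10, 10 + 2 / 0.32), c(10, 10), c(3, 3))
  hm3 <- make_target_heatmap(close2, c(8, 64, 64))
  expect_equal(nrow(detect_peaks(hm3, res, min_distance_um = 3)), 1L)
})

test_that("heatmap to peaks roundtrip recovers well-separated spots exactly", {
  set.seed(77)
  repeat {
    n <- 20
    x <- round(runif(n, 4, 59)); y <- round(runif(n, 4, 59)); z <- sample(0:15, n, TRUE)
    d2 <- as.matrix(stats::dist(cbind(x, y))); diag(d2) <- Inf
    dz <- outer(z, z, "-")
    if (min(d2 + 1000 * (abs(dz) > 2)) >= 6 &&
        min(position_dist_um(positions_tbl(rep(0, n), x, y, z),
                             positions_tbl(rep(0, n), x, y, z),
                             paper_res) + diag(Inf, n)) >= 2.5) break
  }
  pos <- positions_tbl(rep(0L, n), x, y, z)
  hm <- make_target_heatmap(pos, c(16, 64, 64))
  pk <- detect_peaks(hm, paper_res, min_distance_um = 2, threshold_rel = 0.1)
  expect_equal(nrow(pk), n)
  # every true position recovered within 1 px in-plane and on its own slice
  for (k in seq_len(n)) {
    d <- sqrt((pk$x - x[k])^2 + (pk$y - y[k])^2)
    j <- which.min(d)
    expect_lte(d[j], 1)
    expect_equal(pk$z[j], z[k])
  }
})
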
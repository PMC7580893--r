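test_that("simulation is deterministic given a seed", {
  cfg <- simulation_config(n_nuclei = 6, n_frames = 4, image_shape = c(8, 48, 48),
                           seed = 5)
  m1 <- simulate_movie(cfg)
  m2 <- simulate_movie(cfg)
  expect_identical(m1$frames, m2$frames)
  expect_identical(m1$ground_truth$experiment$positions,
                   m2$ground_truth$experiment$positions)
  # different seed, different movie
  cfg2 <- cfg; cfg2$seed <- 6L
  expect_false(identical(simulate_movie(cfg2)$frames, m1$frames))
})

test_that("a one-nucleus one-frame noiseless movie is a single bright blob", {
  cfg <- simulation_config(n_nuclei = 1, n_frames = 1, image_shape = c(16, 64, 64),
                           noise_sigma = 0, debris_count = 0,
                           saturation_fraction = 0, seed = 2)
  mv <- simulate_movie(cfg)
  gt <- mv$ground_truth
  expect_equal(nrow(gt$experiment$positions), 1L)
  expect_equal(nrow(gt$experiment$links), 0L)
  img <- mv$frames[[1]]
  # brightest voxel sits at the nucleus center (within a voxel)
  pk <- which(img == max(img), arr.ind = TRUE)[1, ]
  p <- gt$experiment$positions
  expect_lt(abs(pk[1] - 1 - p$y), 1)
  expect_lt(abs(pk[2] - 1 - p$x), 1)
  expect_lt(abs(pk[3] - 1 - p$z), 1)
  # voxel at the mean carries (approximately) the peak intensity
  s <- gt$experiment$shapes
  expect_lt(abs(max(img) - s$a) / s$a, 0.1)
})

test_that("infeasible packing raises an error", {
  cfg <- simulation_config(n_nuclei = 500, n_frames = 1, image_shape = c(4, 24, 24))
  expect_error(simulate_ground_truth(cfg), "infeasible")
})

test_that("rendering is additive before clipping and recoverable by fitting", {
  cfg <- simulation_config(n_nuclei = 2, n_frames = 1, image_shape = c(12, 48, 48),
                           noise_sigma = 0, debris_count = 0,
                           saturation_fraction = 0, seed = 4)
  sh <- shapes_tbl(t = c(0L, 0L), i = 1:2, a = c(0.4, 0.5),
                   mx = c(5, 9), my = c(7, 7), mz = c(10, 10),
                   cxx = 2.5, cyy = 2.5, czz = 3)
  one <- render_frame(sh[1, ], NULL, cfg)
  two <- render_frame(sh[2, ], NULL, cfg)
  both <- render_frame(sh, NULL, cfg)
  expect_equal(both, one + two, tolerance = 1e-12)
  # saturation clips the top of the dynamic range
  cfg_sat <- cfg; cfg_sat$saturation_fraction <- 0.5
  expect_lte(max(render_frame(sh, NULL, cfg_sat)), 0.5)
})

test_that("expected division counts match the configured rate", {
  # all nuclei eligible from the start (cell_cycle_min 0) so the expected
  # count is n_cells_per_frame * rate summed over frames; binomial check
  rate <- 0.002
  counts <- vapply(1:100, function(seed) {
    gt <- simulate_ground_truth(simulation_config(
      n_nuclei = 30, n_frames = 40, division_rate = rate, cell_cycle_min = 0,
      debris_count = 0, seed = seed))
    nrow(gt$divisions)
  }, numeric(1))
  # ~30 * 39 * 0.002 = 2.3 expected per movie (slightly more as cells divide)
  n_trials <- 30 * 39 * 100
  expect_gt(mean(counts), 2.34 - 3 * sqrt(n_trials * rate) / 100)
  expect_lt(mean(counts), 2.6 + 3 * sqrt(n_trials * rate) / 100)
})

test_that("daughters satisfy the volume rules by construction", {
  gt <- simulate_ground_truth(simulation_config(n_nuclei = 15, n_frames = 20,
                                                division_rate = 0.05,
                                                cell_cycle_min = 0, seed = 9))
  expect_gt(nrow(gt$divisions), 0)
  exp <- gt$experiment
  vol <- stats::setNames(volume_proxy(exp$shapes),
                         pos_key_vec(exp$shapes$t, exp$shapes$i))
  for (k in seq_len(nrow(gt$divisions))) {
    tt <- gt$divisions$t[k]; mi <- gt$divisions$i[k]
    dl <- dplyr::filter(exp$links, .data$t == tt, .data$from == mi)
    expect_equal(nrow(dl), 2L)
    vm <- vol[pos_key_vec(tt, mi)]
    vd <- vol[pos_key_vec(tt + 1L, dl$to)]
    expect_gt(vm, sum(vd))          # mother larger than daughters combined
    expect_lt(max(vm / vd), 3)      # shrink under the 3x error rule
    # daughters at least 3 um apart
    d <- dplyr::filter(exp$positions, .data$t == tt + 1L, .data$i %in% dl$to)
    dm <- position_dist_um(d[1, ], d[2, ], exp$resolution)
    expect_gte(dm[1, 1], 3)
  }
})

test_that("clean ground truth passes the error checker", {
  gt <- simulate_ground_truth(simulation_config(n_nuclei = 20, n_frames = 30,
                                                division_rate = 0.01,
                                                cell_cycle_min = 10, seed = 12))
  w <- check_experiment(gt$experiment)
  expect_equal(nrow(w), 0L)
})

test_that("degrading ground truth behaves like the configured noise", {
  gt <- simulate_ground_truth(simulation_config(n_nuclei = 25, n_frames = 10,
                                                division_rate = 0, seed = 3))
  # identity when all rates are zero
  clean <- degrade_ground_truth(gt, 0, 0, 0, seed = 1)
  expect_equal(clean[, c("t", "x", "y", "z")],
               gt$experiment$positions[, c("t", "x", "y", "z")])
  # miss_rate 1 empties every frame
  expect_equal(nrow(degrade_ground_truth(gt, 1, 0, 0, seed = 1)), 0L)
  # deterministic given seed
  d1 <- degrade_ground_truth(gt, 0.1, 0.05, 0.2, seed = 7)
  d2 <- degrade_ground_truth(gt, 0.1, 0.05, 0.2, seed = 7)
  expect_identical(d1, d2)
  # kept fraction matches the binomial expectation over seeds
  n_total <- nrow(gt$experiment$positions)
  kept <- vapply(1:40, function(s)
    nrow(degrade_ground_truth(gt, 0.04, 0, 0, seed = s)), numeric(1))
  expect_lt(abs(mean(kept) / n_total - 0.96),
            3 * sqrt(0.96 * 0.04 / (n_total * 40)))
})

test_that("noiseless rendering and peak calling recover every nucleus", {
  cfg <- simulation_config(n_nuclei = 10, n_frames = 1, image_shape = c(16, 96, 96),
                           noise_sigma = 0, debris_count = 0, min_spacing_um = 6,
                           saturation_fraction = 0, seed = 21)
  mv <- simulate_movie(cfg)
  pk <- detect_peaks(mv$frames[[1]], cfg$resolution, min_distance_um = 3,
                     threshold_rel = 0.2)
  gtp <- mv$ground_truth$experiment$positions
  m <- match_detections(gtp, pk, cfg$resolution, max_dist = 2)
  expect_equal(m$fn, 0L)
  expect_equal(m$tp, 10L)
})
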
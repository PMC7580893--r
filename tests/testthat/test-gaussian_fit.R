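test_that("gaussian_eval matches the closed form", {
  s <- gaussian_shape(10, c(1, 2, 3), diag(3) * 4)
  expect_equal(gaussian_eval(s, c(1, 2, 3)), 10)
  expect_equal(gaussian_eval(s, c(3, 2, 3)), 10 * exp(-0.5), tolerance = 1e-12)
  s0 <- gaussian_shape(0, c(0, 0, 0), diag(3))
  expect_equal(gaussian_eval(s0, matrix(rnorm(9), 3)), rep(0, 3))
  expect_error(gaussian_shape(1, c(0, 0, 0), diag(c(1, 1, 0))), "positive-definite")
})

test_that("volume proxy is the product of diagonal covariances", {
  expect_equal(volume_proxy(gaussian_shape(1, c(0, 0, 0), diag(3))), 1)
  expect_equal(volume_proxy(gaussian_shape(1, c(0, 0, 0), diag(c(4, 4, 1)))), 16)
  sh <- shapes_tbl(0, 1, 1, 0, 0, 0, cxx = 2, cyy = 3, czz = 4)
  expect_equal(volume_proxy(sh), 24)
})

test_that("the erosion kernel shrinks a 7x7 square to its center pixel", {
  m <- array(FALSE, c(16, 16, 1))
  m[5:11, 5:11, 1] <- TRUE
  e <- m
  for (k in 1:3) e <- nuctrackr:::erode_cross_xy(e)
  expect_equal(sum(e), 1L)
  expect_true(e[8, 8, 1])
})

test_that("segmentation handles degenerate and simple images", {
  empty <- segment_foreground(array(0, c(16, 16, 4)))
  expect_equal(sum(empty$mask), 0)
  expect_equal(max(empty$labels), 0)

  cfg <- simulation_config(n_nuclei = 1, n_frames = 1, image_shape = c(12, 48, 48),
                           noise_sigma = 0, debris_count = 0,
                           saturation_fraction = 0, seed = 6)
  mv <- simulate_movie(cfg)
  seeds <- mv$ground_truth$experiment$positions
  masks <- segment_foreground(mv$frames[[1]], seeds)
  expect_equal(max(masks$labels), 1L)
  expect_equal(masks$clusters$cluster, 1L)
  expect_true(all(masks$mask_eroded <= masks$mask_filled))
})

test_that("raising the threshold offset never grows the foreground mask", {
  cfg <- simulation_config(n_nuclei = 4, n_frames = 1, image_shape = c(10, 40, 40),
                           noise_sigma = 0.02, seed = 8)
  img <- simulate_movie(cfg)$frames[[1]]
  offsets <- c(0.01, 0.03, 0.08)
  sizes <- vapply(offsets, function(o) {
    sum(segment_foreground(img, cfg = segmentation_config(offset_frac = o))$mask)
  }, numeric(1))
  expect_true(all(diff(sizes) <= 0))
})

test_that("negative iso-intensity curvature marks the neck between nuclei", {
  # two bright blobs with a saddle between them
  cfg <- simulation_config(n_nuclei = 2, n_frames = 1, image_shape = c(10, 48, 48),
                           noise_sigma = 0, debris_count = 0,
                           saturation_fraction = 0, seed = 1)
  sh <- shapes_tbl(t = c(0L, 0L), i = 1:2, a = 0.8,
                   mx = c(5, 10), my = c(7, 7), mz = c(8, 8),
                   cxx = 2, cyy = 2, czz = 2.5)
  img <- render_frame(sh, NULL, cfg)
  neg <- nuctrackr:::curvature_negative(img, 1)
  # neck midpoint (x = 7.5 um ~ px 23/24, y = 7 um ~ px 22, z = 8 um -> slice 4)
  expect_true(any(neg[22:24, 23:26, 5]))
  # blob centers are convex (positive curvature)
  expect_false(neg[23, round(5 / 0.32) + 1, 5])
})

test_that("fitting recovers rendered nucleus parameters", {
  res <- image_resolution()
  for (seed in c(3, 4)) {
    cfg <- simulation_config(n_nuclei = 1, n_frames = 1, image_shape = c(16, 64, 64),
                             noise_sigma = 0, debris_count = 0,
                             saturation_fraction = 0, seed = seed)
    gt <- simulate_ground_truth(cfg)
    img <- render_frame(gt$experiment$shapes, NULL, cfg)
    seeds <- gt$experiment$positions
    masks <- segment_foreground(img, seeds)
    sh <- fit_cluster(img, masks, masks$clusters$cluster[1], seeds, res)
    true <- gt$experiment$shapes
    expect_false(sh$unreliable)
    # mean within 0.5 px, amplitude and diagonal covariances within 10%
    expect_lt(abs(sh$mx - true$mx) / res$pixel_size_xy, 0.5)
    expect_lt(abs(sh$my - true$my) / res$pixel_size_xy, 0.5)
    expect_lt(abs(sh$a - true$a) / true$a, 0.10)
    expect_lt(abs(sh$cxx - true$cxx) / true$cxx, 0.10)
    expect_lt(abs(sh$cyy - true$cyy) / true$cyy, 0.10)
    expect_lt(abs(sh$czz - true$czz) / true$czz, 0.10)
  }
})

test_that("two nuclei in one cluster are fitted jointly near their seeds", {
  res <- image_resolution()
  cfg <- simulation_config(n_nuclei = 2, n_frames = 1, image_shape = c(12, 64, 64),
                           noise_sigma = 0, debris_count = 0,
                           saturation_fraction = 0, seed = 10)
  sh_true <- shapes_tbl(t = c(0L, 0L), i = 1:2, a = c(0.6, 0.7),
                        mx = c(7, 12), my = c(9, 9), mz = c(10, 10),
                        cxx = c(2.2, 2.6), cyy = c(2.4, 2.2), czz = c(3, 3.2))
  img <- render_frame(sh_true, NULL, cfg)
  seeds <- positions_tbl(c(0, 0), sh_true$mx / 0.32, sh_true$my / 0.32,
                         sh_true$mz / 2)
  masks <- segment_foreground(img, seeds)
  cl <- unique(masks$clusters$cluster)
  fits <- dplyr::bind_rows(lapply(cl[cl > 0], function(c)
    fit_cluster(img, masks, c, seeds, res)))
  expect_equal(nrow(fits), 2L)
  for (k in 1:2) {
    expect_lt(abs(fits$mx[k] - sh_true$mx[k]), 0.5)
    expect_lt(abs(fits$my[k] - sh_true$my[k]), 0.5)
  }
})

test_that("optimisation never worsens the residual", {
  res <- image_resolution()
  cfg <- simulation_config(n_nuclei = 2, n_frames = 1, image_shape = c(12, 48, 48),
                           noise_sigma = 0.03, debris_count = 1, seed = 13)
  mv <- simulate_movie(cfg)
  img <- mv$frames[[1]]
  seeds <- mv$ground_truth$experiment$positions
  seg_cfg <- segmentation_config()
  masks <- segment_foreground(img, seeds, seg_cfg)
  blurred <- nuctrackr:::gaussian_blur_3d(img, seg_cfg$blur_sigma_xy, seg_cfg$blur_sigma_z)
  for (cl in unique(masks$clusters$cluster[masks$clusters$cluster > 0])) {
    fits <- fit_cluster(img, masks, cl, seeds, res)
    vox <- which(masks$mask_filled & masks$regions == cl)
    in_cl <- masks$clusters$cluster == cl
    sd_seeds <- seeds[match(masks$clusters$i[in_cl], seeds$i), ]
    coords <- cbind(arrayInd(vox, dim(img))[, 2] - 1, arrayInd(vox, dim(img))[, 1] - 1,
                    arrayInd(vox, dim(img))[, 3] - 1)
    coords <- sweep(coords, 2, c(res$pixel_size_xy, res$pixel_size_xy, res$z_step), "*")
    mix <- function(sh) {
      rowSums(vapply(seq_len(nrow(sh)), function(k)
        gaussian_eval(nuctrackr:::shape_from_row(sh, k), coords), numeric(nrow(coords))))
    }
    # residual of the returned (deconvolved) fit re-blurred is hard to state
    # exactly; instead check the optimiser's own guarantee on the init shapes
    init <- shapes_tbl(sd_seeds$t, sd_seeds$i,
                       a = vapply(seq_len(nrow(sd_seeds)), function(k) {
                         blurred[round(sd_seeds$y[k]) + 1, round(sd_seeds$x[k]) + 1,
                                 round(sd_seeds$z[k]) + 1]
                       }, numeric(1)),
                       mx = sd_seeds$x * res$pixel_size_xy,
                       my = sd_seeds$y * res$pixel_size_xy,
                       mz = sd_seeds$z * res$z_step,
                       cxx = (3 * res$pixel_size_xy)^2, cyy = (3 * res$pixel_size_xy)^2,
                       czz = (1.5 * res$z_step)^2)
    # re-blur the deconvolved fit to compare in blurred-image space
    bc <- nuctrackr:::blur_covariance(seg_cfg, res)
    reblur <- fits
    for (k in seq_len(nrow(reblur))) {
      sg <- matrix(c(reblur$cxx[k], reblur$cxy[k], reblur$cxz[k],
                     reblur$cxy[k], reblur$cyy[k], reblur$cyz[k],
                     reblur$cxz[k], reblur$cyz[k], reblur$czz[k]), 3, 3) + bc
      det_ratio <- sqrt(det(sg - bc) / det(sg))
      reblur$a[k] <- reblur$a[k] * det_ratio
      reblur$cxx[k] <- sg[1, 1]; reblur$cyy[k] <- sg[2, 2]; reblur$czz[k] <- sg[3, 3]
    }
    r_init <- sum((blurred[vox] - mix(init))^2)
    r_fit <- sum((blurred[vox] - mix(reblur))^2)
    expect_lte(r_fit, r_init + 1e-9)
  }
})

test_that("volume proxy is stable over time for non-dividing nuclei", {
  cfg <- simulation_config(n_nuclei = 3, n_frames = 12, image_shape = c(16, 64, 64),
                           division_rate = 0, debris_count = 0, noise_sigma = 0.015,
                           min_spacing_um = 6, seed = 17)
  mv <- simulate_movie(cfg)
  exp <- mv$ground_truth$experiment
  fitted <- fit_experiment(
    tracking_experiment(cfg$resolution, exp$positions, exp$links,
                        n_frames = cfg$n_frames),
    mv$frames)
  vols <- dplyr::mutate(fitted$shapes, v = volume_proxy(fitted$shapes))
  cv <- dplyr::summarise(dplyr::group_by(dplyr::filter(vols, !.data$unreliable),
                                         .data$i),
                         cv = stats::sd(.data$v) / mean(.data$v))
  expect_true(all(cv$cv < 0.2))
})

test_that("the fitted mixture reproduces the blurred image over clusters", {
  res <- image_resolution()
  cfg <- simulation_config(n_nuclei = 5, n_frames = 1, image_shape = c(12, 64, 64),
                           noise_sigma = 0, debris_count = 0,
                           saturation_fraction = 0, seed = 19)
  mv <- simulate_movie(cfg)
  img <- mv$frames[[1]]
  seeds <- mv$ground_truth$experiment$positions
  seg_cfg <- segmentation_config()
  masks <- segment_foreground(img, seeds, seg_cfg)
  blurred <- nuctrackr:::gaussian_blur_3d(img, seg_cfg$blur_sigma_xy,
                                          seg_cfg$blur_sigma_z)
  exp <- tracking_experiment(res, seeds, n_frames = 1L)
  fitted <- fit_experiment(exp, list(img))
  # evaluate the re-blurred mixture on all cluster voxels
  vox <- which(masks$mask_filled & masks$regions > 0)
  ai <- arrayInd(vox, dim(img))
  coords <- cbind((ai[, 2] - 1) * res$pixel_size_xy, (ai[, 1] - 1) * res$pixel_size_xy,
                  (ai[, 3] - 1) * res$z_step)
  bc <- nuctrackr:::blur_covariance(seg_cfg, res)
  total <- numeric(length(vox))
  for (k in seq_len(nrow(fitted$shapes))) {
    s <- nuctrackr:::shape_from_row(fitted$shapes, k)
    sg <- s$sigma + bc
    a <- s$a * sqrt(det(s$sigma) / det(sg))
    total <- total + gaussian_eval(gaussian_shape(a, s$mu, sg), coords)
  }
  expect_gt(stats::cor(total, blurred[vox]), 0.9)
})
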
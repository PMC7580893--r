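# Shared fixtures: everything is generated in code at test time.

paper_res <- image_resolution(0.32, 2, 12)

pos_key_vec <- function(t, i) paste(t, i, sep = ".")

# a small hand-built experiment with one division and one linear track
fixture_experiment <- function(with_shapes = FALSE) {
  pos <- positions_tbl(
    t = c(0, 0, 1, 1, 1, 2, 2, 2),
    x = c(10, 40, 11, 39, 43, 12, 38, 44),
    y = c(10, 40, 10, 38, 42, 11, 37, 43),
    z = c(3, 8, 3, 8, 8, 3, 8, 8))
  lk <- links_tbl(
    t = c(0L, 0L, 0L, 1L, 1L, 1L),
    from = c(1L, 2L, 2L, 1L, 2L, 3L),
    to = c(1L, 2L, 3L, 1L, 2L, 3L))
  shapes <- NULL
  if (with_shapes) {
    p <- to_micrometers(pos, paper_res)
    vol_sd <- c(1.6, 1.6, 1.1, 1.1, 1.1, 1.1, 1.1, 1.1)  # mother bigger
    shapes <- shapes_tbl(p$t, p$i, a = 0.6,
                         mx = p$x_um, my = p$y_um, mz = p$z_um,
                         cxx = vol_sd^2, cyy = vol_sd^2, czz = vol_sd^2)
  }
  tracking_experiment(paper_res, pos, lk, shapes = shapes, n_frames = 3L)
}

# deterministic small simulated movie set for detector tests
simulate_training_set <- function(seed, n_frames, n_nuclei = 8,
                                  image_shape = c(16, 64, 64)) {
  cfg <- simulation_config(n_nuclei = n_nuclei, n_frames = n_frames,
                           image_shape = image_shape, motion_sigma = 1,
                           division_rate = 0.003, debris_count = 2,
                           noise_sigma = 0.02, seed = seed)
  mv <- simulate_movie(cfg)
  shape <- cfg$image_shape
  targets <- lapply(seq_len(n_frames) - 1L, function(tt) {
    make_target_heatmap(dplyr::filter(mv$ground_truth$experiment$positions,
                                      .data$t == tt), shape)
  })
  list(images = mv$frames, targets = targets, gt = mv$ground_truth, cfg = cfg)
}

# detection F1 of a model on a held-out simulated set, 5 um matching; the
# peak suppression radius matches the generator's minimum nucleus spacing
heldout_detection_f1 <- function(model, test_set, threshold_rel = 0.1,
                                 min_distance_um = 3, tta = FALSE) {
  res <- test_set$cfg$resolution
  tp <- fp <- fn <- 0L
  for (k in seq_along(test_set$images)) {
    hm <- predict_heatmap(model, test_set$images[[k]], tta = tta)
    pk <- detect_peaks(hm, res, min_distance_um = min_distance_um,
                       threshold_rel = threshold_rel, t = k - 1L)
    gtp <- dplyr::filter(test_set$gt$experiment$positions, .data$t == k - 1L)
    m <- match_detections(gtp, pk, res, 5)
    tp <- tp + m$tp; fp <- fp + m$fp; fn <- fn + m$fn
  }
  precision_recall_f1(tp, fp, fn, quiet = TRUE)$f1
}

# seeds whose single simulated nucleus lies at least 3 sigma inside the
# stack on every axis: parameter recovery is only well-posed for a fully
# imaged nucleus, so the recovery experiments draw from these
interior_nucleus_seeds <- function(n_wanted, start_seed = 60L) {
  found <- integer(0)
  seed <- start_seed
  while (length(found) < n_wanted) {
    cfg <- simulation_config(n_nuclei = 1, n_frames = 1,
                             image_shape = c(16, 64, 64), noise_sigma = 0,
                             debris_count = 0, saturation_fraction = 0,
                             seed = seed)
    s <- simulate_ground_truth(cfg)$experiment$shapes
    ext <- c(63 * 0.32, 63 * 0.32, 15 * 2)
    mu <- c(s$mx, s$my, s$mz)
    sd3 <- 3 * sqrt(c(s$cxx, s$cyy, s$czz))
    if (all(mu - sd3 >= 0) && all(mu + sd3 <= ext)) found <- c(found, seed)
    seed <- seed + 1L
  }
  found
}

# random tiny link problem for oracle-equivalence checks; most instances get
# random volume proxies and intensities so the division gate and the volume
# cost term are exercised, every fourth runs without shapes (fallback path)
random_link_problem <- function(seed) {
  set.seed(seed)
  nf <- sample(2:4, 1)
  pos <- do.call(rbind, lapply(seq_len(nf) - 1L, function(tt) {
    np <- sample(1:6, 1)
    data.frame(t = tt, x = runif(np, 0, 18), y = runif(np, 0, 18),
               z = runif(np, 0, 5))
  }))
  pos <- positions_tbl(pos$t, pos$x, pos$y, pos$z)
  w <- link_weights(runif(1, 5, 30), runif(1, 20, 120), runif(1, 20, 160),
                    runif(1, 20, 160), runif(1, 5, 40))
  if (seed %% 4L == 0L) {
    return(link_problem(pos, weights = w, res = paper_res))
  }
  sd2 <- runif(nrow(pos), 1, 2.5)
  shapes <- shapes_tbl(pos$t, pos$i, a = runif(nrow(pos), 0.3, 0.9),
                       mx = pos$x * paper_res$pixel_size_xy,
                       my = pos$y * paper_res$pixel_size_xy,
                       mz = pos$z * paper_res$z_step,
                       cxx = sd2, cyy = sd2, czz = sd2)
  exp <- tracking_experiment(paper_res, pos, shapes = shapes)
  link_problem(exp, weights = w)
}

# Builds an experiment with exactly one planted violation of each of the six
# curation rules (and nothing else):
#   rule 1: a track that appears out of nowhere at t=2
#   rule 2: a second division 0.4 h after the first on the same branch
#   rule 3: a single 12 um jump
#   rule 4: a division whose daughters together outweigh the mother
#   rule 5: one 4-fold volume shrink along a link
#   rule 6: two cells merging into one
fixture_one_per_rule <- function() {
  res <- paper_res
  df <- tibble::tribble(
    ~t, ~x, ~y,
    # branch M: (10,10) for the whole movie
    0, 10, 10,  1, 10, 10,  2, 10, 10,  3, 10, 10,
    4, 10, 10,  5, 10, 10,  6, 10, 10,  7, 10, 10,
    # daughter D1b of division 1: (26,10) from t=2 on
    2, 26, 10,  3, 26, 10,  4, 26, 10,  5, 26, 10,  6, 26, 10,  7, 26, 10,
    # daughter D2b of division 2: (18,18) from t=4 on
    4, 18, 18,  5, 18, 18,  6, 18, 18,  7, 18, 18,
    # track B: straight at (80,80), jumping to (80,117.5) after t=3 (rule 3)
    0, 80, 80,  1, 80, 80,  2, 80, 80,  3, 80, 80,
    4, 80, 117.5,  5, 80, 117.5,  6, 80, 117.5,  7, 80, 117.5,
    # track C: appears at t=2 (rule 1), then runs to the end
    2, 40, 60,  3, 40, 60,  4, 40, 60,  5, 40, 60,  6, 40, 60,  7, 40, 60,
    # track D: two cells merging at t=1 (rule 6)
    0, 150, 20,  0, 150, 40,
    1, 150, 30,  2, 150, 30,  3, 150, 30,  4, 150, 30,
    5, 150, 30,  6, 150, 30,  7, 150, 30)
  p <- positions_tbl(df$t, df$x, df$y, rep(5, nrow(df)))
  idx <- function(tt, x0, y0) {
    i <- p$i[p$t == tt & abs(p$x - x0) < 1e-6 & abs(p$y - y0) < 1e-6]
    stopifnot(length(i) == 1)
    i
  }
  links <- list()
  lnk <- function(tt, from_xy, to_xy) {
    links[[length(links) + 1L]] <<- tibble::tibble(
      t = as.integer(tt), from = idx(tt, from_xy[1], from_xy[2]),
      to = idx(tt + 1, to_xy[1], to_xy[2]))
  }
  # branch M with division 1 at t=1 and division 2 at t=3 (rule 2)
  lnk(0, c(10, 10), c(10, 10))
  lnk(1, c(10, 10), c(10, 10)); lnk(1, c(10, 10), c(26, 10))
  lnk(2, c(10, 10), c(10, 10))
  lnk(3, c(10, 10), c(10, 10)); lnk(3, c(10, 10), c(18, 18))
  for (tt in 4:6) lnk(tt, c(10, 10), c(10, 10))
  for (tt in 2:6) lnk(tt, c(26, 10), c(26, 10))
  for (tt in 4:6) lnk(tt, c(18, 18), c(18, 18))
  # track B with its jump (rule 3): 37.5 px * 0.32 = 12 um
  for (tt in 0:6) {
    lnk(tt, c(80, if (tt <= 3) 80 else 117.5),
        c(80, if (tt + 1 <= 3) 80 else 117.5))
  }
  # track C (rule 1: appears at t=2)
  for (tt in 2:6) lnk(tt, c(40, 60), c(40, 60))
  # track D merge (rule 6)
  lnk(0, c(150, 20), c(150, 30))
  lnk(0, c(150, 40), c(150, 30))
  for (tt in 1:6) lnk(tt, c(150, 30), c(150, 30))
  lk <- dplyr::bind_rows(links)

  # shapes: base covariance diag 1.44 um^2 everywhere; division-1 daughters
  # keep the mother size (rule 4); division-2 daughters take a compliant
  # 0.42x volume; one 4x shrink planted on track B at t=2 (rule 5)
  pm <- to_micrometers(p, res)
  sd2 <- rep(1.44, nrow(p))
  set_v <- function(tt, x0, y0, v) sd2[idx2(tt, x0, y0)] <<- v
  idx2 <- function(tt, x0, y0) which(p$t == tt & p$i == idx(tt, x0, y0))
  set_v(2, 80, 80, 1.44 / 4^(1 / 3))
  f <- 0.42^(1 / 3)
  for (tt in 4:7) for (xy in list(c(10, 10), c(18, 18))) {
    set_v(tt, xy[1], xy[2], 1.44 * f)
  }
  shapes <- shapes_tbl(p$t, p$i, a = 0.6, mx = pm$x_um, my = pm$y_um,
                       mz = pm$z_um, cxx = sd2, cyy = sd2, czz = sd2)
  tracking_experiment(res, p, lk, shapes = shapes, n_frames = 8L)
}

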
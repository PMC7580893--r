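#' Configuration for the synthetic movie generator
#'
#' The generator emulates H2B-labelled nuclei in dense epithelial tissue as
#' imaged by confocal time-lapse microscopy: bright anisotropic Gaussian
#' blobs with varying intensity, visual overlap (especially along the coarse
#' z-axis), additive sensor noise, saturation clipping, and static dead-cell
#' debris that mimics nuclei. Nuclei perform a Gaussian random walk, and can
#' divide into two smaller daughters once old enough.
#'
#' @param n_nuclei Number of nuclei at the first frame.
#' @param n_frames Number of frames.
#' @param image_shape Integer `(z, y, x)` voxel counts of a frame.
#' @param resolution An [image_resolution()].
#' @param motion_sigma Random-walk step standard deviation per axis, um/frame.
#' @param division_rate Per-nucleus per-frame division probability (applies
#'   only once a nucleus is at least `cell_cycle_min` hours old).
#' @param cell_cycle_min Minimum age before a nucleus may divide, hours.
#' @param debris_count Number of static debris blobs.
#' @param noise_sigma Additive Gaussian noise standard deviation, on the
#'   image intensity scale where full scale is 1.
#' @param saturation_fraction Fraction of the dynamic range clipped at the
#'   top: intensities are clipped at `1 - saturation_fraction`.
#' @param min_spacing_um Minimum center-to-center distance when placing the
#'   initial nuclei.
#' @param seed Integer seed; all generator randomness is a deterministic
#'   function of it.
#' @return A `simulation_config` object (a named list).
#' @export
simulation_config <- function(n_nuclei = 30, n_frames = 40,
                              image_shape = c(z = 16, y = 128, x = 128),
                              resolution = image_resolution(),
                              motion_sigma = 1.0,
                              division_rate = 0.003,
                              cell_cycle_min = 10,
                              debris_count = 5,
                              noise_sigma = 0.02,
                              saturation_fraction = 0.1,
                              min_spacing_um = 3,
                              seed = 1L) {
  stopifnot(n_nuclei >= 1, n_frames >= 1, length(image_shape) == 3,
            all(image_shape >= 4), is_resolution(resolution),
            motion_sigma >= 0, division_rate >= 0, division_rate <= 1,
            cell_cycle_min >= 0, debris_count >= 0, noise_sigma >= 0,
            saturation_fraction >= 0, saturation_fraction <= 1,
            min_spacing_um >= 0)
  image_shape <- as.integer(image_shape)
  names(image_shape) <- c("z", "y", "x")
  structure(list(n_nuclei = as.integer(n_nuclei), n_frames = as.integer(n_frames),
                 image_shape = image_shape, resolution = resolution,
                 motion_sigma = motion_sigma, division_rate = division_rate,
                 cell_cycle_min = cell_cycle_min, debris_count = as.integer(debris_count),
                 noise_sigma = noise_sigma, saturation_fraction = saturation_fraction,
                 min_spacing_um = min_spacing_um, seed = as.integer(seed)),
            class = "simulation_config")
}

# physical extent of the stack in um, c(x, y, z)
stack_extent_um <- function(cfg) {
  res <- cfg$resolution
  c((cfg$image_shape[["x"]] - 1) * res$pixel_size_xy,
    (cfg$image_shape[["y"]] - 1) * res$pixel_size_xy,
    (cfg$image_shape[["z"]] - 1) * res$z_step)
}

with_preserved_rng <- function(code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  }
  force(code)
}

random_unit_vector <- function() {
  v <- stats::rnorm(3)
  v / sqrt(sum(v * v))
}

# random anisotropic nucleus covariance (um^2) with random in-plane orientation
random_nucleus_cov <- function() {
  sx <- stats::runif(1, 1.3, 1.9)
  sy <- stats::runif(1, 1.3, 1.9)
  sz <- stats::runif(1, 1.6, 2.2)
  th <- stats::runif(1, 0, pi)
  R <- matrix(c(cos(th), sin(th), 0, -sin(th), cos(th), 0, 0, 0, 1), 3, 3)
  R %*% diag(c(sx^2, sy^2, sz^2)) %*% t(R)
}

reflect_into <- function(p, lo, hi) {
  for (k in seq_along(p)) {
    span <- hi[k] - lo[k]
    v <- (p[k] - lo[k]) %% (2 * span)
    if (v > span) v <- 2 * span - v
    p[k] <- lo[k] + v
  }
  p
}

#' Simulate ground-truth nucleus trajectories (no images)
#'
#' Generates the trajectories, divisions, true Gaussian shapes and debris of a
#' synthetic movie, deterministically from `cfg$seed`. Daughter nuclei are
#' placed 3.2 um apart and each receives 0.42x the mother's volume proxy, so
#' that by construction the mother's volume exceeds the daughters' combined
#' volume and no frame-to-frame shrink exceeds 3x.
#'
#' @param cfg A [simulation_config()].
#' @return A `ground_truth` object: list with `experiment` (a
#'   [tracking_experiment()] whose shapes are the true per-frame Gaussians),
#'   `divisions` (tibble `t`, `i` of each mother), `debris` (tibble of static
#'   blob parameters) and `config`.
#' @export
simulate_ground_truth <- function(cfg) {
  stopifnot(inherits(cfg, "simulation_config"))
  with_preserved_rng({
    set.seed(cfg$seed)
    ext <- stack_extent_um(cfg)
    margin <- 2
    lo <- rep(margin, 3); hi <- ext - margin
    if (any(hi <= lo)) stop("simulate_ground_truth: image_shape too small", call. = FALSE)

    # initial placement with minimum spacing, by rejection
    centers <- matrix(NA_real_, cfg$n_nuclei, 3)
    tries <- 0L
    placed <- 0L
    while (placed < cfg$n_nuclei) {
      cand <- lo + stats::runif(3) * (hi - lo)
      ok <- placed == 0L ||
        min(sqrt(colSums((t(centers[seq_len(placed), , drop = FALSE]) - cand)^2))) >=
          cfg$min_spacing_um
      if (ok) { placed <- placed + 1L; centers[placed, ] <- cand }
      tries <- tries + 1L
      if (tries > 2000L * cfg$n_nuclei) {
        stop("simulate_ground_truth: infeasible config, cannot place ",
             cfg$n_nuclei, " nuclei at ", cfg$min_spacing_um, " um spacing",
             call. = FALSE)
      }
    }

    cells <- lapply(seq_len(cfg$n_nuclei), function(k) {
      list(mu = centers[k, ], cov = random_nucleus_cov(),
           a = stats::runif(1, 0.4, 0.9),
           age_h = stats::runif(1, 0, cfg$cell_cycle_min))
    })
    dt_h <- cfg$resolution$time_step / 60

    pos_rows <- list(); shape_rows <- list(); link_rows <- list(); div_rows <- list()
    record_frame <- function(tt) {
      n <- length(cells)
      mus <- t(vapply(cells, function(c) c$mu, numeric(3)))
      pos_rows[[tt + 1L]] <<- tibble::tibble(
        t = tt, i = seq_len(n),
        x = mus[, 1] / cfg$resolution$pixel_size_xy,
        y = mus[, 2] / cfg$resolution$pixel_size_xy,
        z = mus[, 3] / cfg$resolution$z_step)
      shape_rows[[tt + 1L]] <<- purrr::map_dfr(seq_len(n), function(k) {
        cc <- cells[[k]]
        shapes_tbl(tt, k, cc$a, cc$mu[1], cc$mu[2], cc$mu[3],
                   cc$cov[1, 1], cc$cov[2, 2], cc$cov[3, 3],
                   cc$cov[1, 2], cc$cov[1, 3], cc$cov[2, 3])
      })
    }
    record_frame(0L)

    for (tt in seq_len(cfg$n_frames - 1L)) {
      new_cells <- list(); lt <- integer(); lf <- integer(); lto <- integer()
      divs <- integer()
      for (k in seq_along(cells)) {
        cc <- cells[[k]]
        divide <- cc$age_h >= cfg$cell_cycle_min &&
          stats::runif(1) < cfg$division_rate
        if (divide) {
          u <- random_unit_vector()
          # each daughter: volume proxy 0.42x mother (sum 0.84 < 1, shrink 2.4 < 3)
          shrink <- 0.42^(1 / 3)
          # shift the pair's midpoint inward (rather than reflecting the
          # endpoints) so the 3.2 um daughter separation is preserved
          half <- 1.6 * u
          mid <- pmin(pmax(cc$mu, lo + abs(half)), hi - abs(half))
          for (sgn in c(-1, 1)) {
            d <- cc
            d$mu <- mid + sgn * half
            d$cov <- cc$cov * shrink
            d$age_h <- 0
            new_cells[[length(new_cells) + 1L]] <- d
            lt <- c(lt, tt - 1L); lf <- c(lf, k)
            lto <- c(lto, length(new_cells))
          }
          divs <- c(divs, k)
        } else {
          cc$mu <- reflect_into(cc$mu + stats::rnorm(3, 0, cfg$motion_sigma), lo, hi)
          cc$age_h <- cc$age_h + dt_h
          new_cells[[length(new_cells) + 1L]] <- cc
          lt <- c(lt, tt - 1L); lf <- c(lf, k); lto <- c(lto, length(new_cells))
        }
      }
      cells <- new_cells
      link_rows[[tt]] <- links_tbl(lt, lf, lto)
      if (length(divs)) div_rows[[tt]] <- tibble::tibble(t = tt - 1L, i = divs)
      record_frame(tt)
    }

    debris <- if (cfg$debris_count > 0) {
      purrr::map_dfr(seq_len(cfg$debris_count), function(k) {
        mu <- lo + stats::runif(3) * (hi - lo)
        tibble::tibble(x = mu[1], y = mu[2], z = mu[3],
                       sigma = stats::runif(1, 0.6, 0.9),
                       a = stats::runif(1, 0.4, 0.9))
      })
    } else {
      tibble::tibble(x = numeric(), y = numeric(), z = numeric(),
                     sigma = numeric(), a = numeric())
    }

    positions <- dplyr::bind_rows(pos_rows)
    exp <- tracking_experiment(cfg$resolution, positions,
                               if (length(link_rows)) dplyr::bind_rows(link_rows)
                               else links_tbl(),
                               shapes = dplyr::bind_rows(shape_rows),
                               n_frames = cfg$n_frames)
    structure(list(experiment = exp,
                   divisions = if (length(div_rows)) dplyr::bind_rows(div_rows)
                               else tibble::tibble(t = integer(), i = integer()),
                   debris = debris, config = cfg),
              class = "ground_truth")
  })
}

#' @export
print.ground_truth <- function(x, ...) {
  cat(sprintf("<ground_truth> %d frames, %d positions, %d divisions, %d debris blobs\n",
              x$config$n_frames, nrow(x$experiment$positions),
              nrow(x$divisions), nrow(x$debris)))
  invisible(x)
}

#' Render one synthetic frame
#'
#' Sums the Gaussian intensity profiles of the given nucleus shapes (and
#' debris blobs) on the anisotropic voxel grid, adds Gaussian noise, clips
#' below zero and at the saturation level `1 - saturation_fraction`.
#'
#' @param shapes A shapes tibble (means in um, covariances in um^2).
#' @param debris Debris tibble as produced by [simulate_ground_truth()]
#'   (may be empty).
#' @param cfg A [simulation_config()].
#' @param noise_seed Optional integer; when given, the noise is drawn from a
#'   generator seeded with it (used for per-frame determinism).
#' @return A 3D array, dim `(ny, nx, nz)`, intensities in `[0, 1]`.
#' @export
render_frame <- function(shapes, debris = NULL, cfg, noise_seed = NULL) {
  stopifnot(inherits(cfg, "simulation_config"))
  res <- cfg$resolution
  ny <- cfg$image_shape[["y"]]; nx <- cfg$image_shape[["x"]]; nz <- cfg$image_shape[["z"]]
  img <- array(0, dim = c(ny, nx, nz))
  add_blob <- function(a, mu, cov) {
    si <- solve(cov)
    sd3 <- sqrt(diag(cov))
    xr <- range_to_idx(mu[1] + c(-4, 4) * sd3[1], res$pixel_size_xy, nx)
    yr <- range_to_idx(mu[2] + c(-4, 4) * sd3[2], res$pixel_size_xy, ny)
    zr <- range_to_idx(mu[3] + c(-4, 4) * sd3[3], res$z_step, nz)
    if (!length(xr) || !length(yr) || !length(zr)) return()
    gx <- xr * res$pixel_size_xy - mu[1]
    gy <- yr * res$pixel_size_xy - mu[2]
    gz <- zr * res$z_step - mu[3]
    d <- as.matrix(expand.grid(y = gy, x = gx, z = gz))
    q <- rowSums((d[, c("x", "y", "z")] %*% si) * d[, c("x", "y", "z")])
    img[yr + 1, xr + 1, zr + 1] <<-
      img[yr + 1, xr + 1, zr + 1] + array(a * exp(-0.5 * q),
                                          dim = c(length(yr), length(xr), length(zr)))
  }
  if (!is.null(shapes) && nrow(shapes)) {
    for (k in seq_len(nrow(shapes))) {
      s <- shapes[k, ]
      cov <- matrix(c(s$cxx, s$cxy, s$cxz, s$cxy, s$cyy, s$cyz, s$cxz, s$cyz, s$czz), 3, 3)
      add_blob(s$a, c(s$mx, s$my, s$mz), cov)
    }
  }
  if (!is.null(debris) && nrow(debris)) {
    for (k in seq_len(nrow(debris))) {
      d <- debris[k, ]
      add_blob(d$a, c(d$x, d$y, d$z), diag(rep(d$sigma^2, 3)))
    }
  }
  if (cfg$noise_sigma > 0) {
    with_preserved_rng({
      if (!is.null(noise_seed)) set.seed(noise_seed)
      img <- img + array(stats::rnorm(length(img), 0, cfg$noise_sigma), dim = dim(img))
    })
  }
  sat <- 1 - cfg$saturation_fraction
  img[img < 0] <- 0
  img[img > sat] <- sat
  img
}

# voxel indices (0-based) whose centers fall inside a um range on one axis
range_to_idx <- function(range_um, step_um, n) {
  lo <- max(0L, floor(range_um[1] / step_um))
  hi <- min(n - 1L, ceiling(range_um[2] / step_um))
  if (hi < lo) return(integer())
  seq.int(lo, hi)
}

#' Simulate a full movie: images plus ground truth
#'
#' Runs [simulate_ground_truth()] and renders every frame with
#' [render_frame()]. Per-frame noise seeds are derived deterministically from
#' `cfg$seed`, so the same config and seed always yield bit-identical movies.
#'
#' @param cfg A [simulation_config()].
#' @return A list with `frames` (list of 3D arrays) and `ground_truth`.
#' @export
simulate_movie <- function(cfg) {
  gt <- simulate_ground_truth(cfg)
  frames <- lapply(seq_len(cfg$n_frames) - 1L, function(tt) {
    sh <- dplyr::filter(gt$experiment$shapes, .data$t == tt)
    render_frame(sh, gt$debris, cfg,
                 noise_seed = (cfg$seed %% 100000L) * 20011L + tt * 977L)
  })
  list(frames = frames, ground_truth = gt)
}

#' Degrade ground-truth positions into imperfect detections
#'
#' Emulates an imperfect detector on top of perfect ground truth: each true
#' position is dropped independently with probability `miss_rate`, surviving
#' positions are jittered isotropically with standard deviation `jitter_um`,
#' and a Binomial(`n`, `fp_rate`) number of spurious uniform positions is
#' added per frame. Lets the linking and evaluation stages be tested
#' independently of the detector.
#'
#' @param gt A `ground_truth` object.
#' @param miss_rate,fp_rate Probabilities in `[0, 1]`.
#' @param jitter_um Isotropic jitter standard deviation in um.
#' @param seed Integer seed.
#' @return A positions tibble.
#' @export
degrade_ground_truth <- function(gt, miss_rate = 0, fp_rate = 0,
                                 jitter_um = 0, seed = 1L) {
  stopifnot(inherits(gt, "ground_truth"),
            miss_rate >= 0, miss_rate <= 1, fp_rate >= 0, fp_rate <= 1,
            jitter_um >= 0)
  cfg <- gt$config
  res <- cfg$resolution
  ext <- stack_extent_um(cfg)
  with_preserved_rng({
    set.seed(seed)
    out <- purrr::map_dfr(sort(unique(gt$experiment$positions$t)), function(tt) {
      p <- dplyr::filter(gt$experiment$positions, .data$t == tt)
      keep <- stats::runif(nrow(p)) >= miss_rate
      p <- p[keep, , drop = FALSE]
      if (nrow(p) && jitter_um > 0) {
        p$x <- p$x + stats::rnorm(nrow(p), 0, jitter_um) / res$pixel_size_xy
        p$y <- p$y + stats::rnorm(nrow(p), 0, jitter_um) / res$pixel_size_xy
        p$z <- p$z + stats::rnorm(nrow(p), 0, jitter_um) / res$z_step
      }
      n_fp <- stats::rbinom(1, sum(keep, na.rm = TRUE) + sum(!keep), fp_rate)
      if (n_fp > 0) {
        fp <- tibble::tibble(
          t = tt, i = NA_integer_,
          x = stats::runif(n_fp, 0, ext[1]) / res$pixel_size_xy,
          y = stats::runif(n_fp, 0, ext[2]) / res$pixel_size_xy,
          z = stats::runif(n_fp, 0, ext[3]) / res$z_step)
        p <- dplyr::bind_rows(p, fp)
      }
      p
    })
    positions_tbl(out$t, out$x, out$y, out$z)
  })
}
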
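#' Gaussian-fit parameters
#'
#' @param init_sigma_xy_px,init_sigma_z_slices Initial covariance: standard
#'   deviations in pixels (xy) and slices (z), converted to um with the movie
#'   resolution.
#' @param max_shift_um Fitted means are constrained to stay within this
#'   distance of their seeds.
#' @param maxiter Maximum optimiser iterations.
#' @param ftol Relative tolerance on the residual sum of squares.
#' @param max_voxels Residual voxels per cluster are deterministically
#'   subsampled down to this count to bound fit cost on huge clusters.
#' @return A `gaussfit_config` object.
#' @export
gaussfit_config <- function(init_sigma_xy_px = 3, init_sigma_z_slices = 1.5,
                            max_shift_um = 5, maxiter = 200, ftol = 1e-6,
                            max_voxels = 8000) {
  structure(list(init_sigma_xy_px = init_sigma_xy_px,
                 init_sigma_z_slices = init_sigma_z_slices,
                 max_shift_um = max_shift_um, maxiter = as.integer(maxiter),
                 ftol = ftol, max_voxels = as.integer(max_voxels)),
            class = "gaussfit_config")
}

# pack / unpack per-shape parameters: (a, mx, my, mz, l11, l22, l33, l21, l31, l32)
# where Sigma = L L', L lower-triangular with positive diagonal
params_to_shapes <- function(theta, n) {
  m <- matrix(theta, nrow = 10L)
  lapply(seq_len(n), function(k) {
    p <- m[, k]
    L <- matrix(c(p[5], p[8], p[9],
                  0, p[6], p[10],
                  0, 0, p[7]), 3, 3)
    list(a = p[1], mu = p[2:4], sigma = L %*% t(L))
  })
}

# subtract the blur covariance from a fitted shape (Gaussian deconvolution:
# blurring a Gaussian adds the blur covariance exactly); eigenvalues are
# floored to keep the result positive-definite, and the amplitude is
# rescaled so the integrated intensity is preserved
deconvolve_blur <- function(s, blur_cov) {
  if (all(blur_cov == 0)) return(s)
  corr <- s$sigma - blur_cov
  eg <- eigen(corr, symmetric = TRUE)
  eg$values <- pmax(eg$values, 0.05^2)
  corr <- eg$vectors %*% diag(eg$values) %*% t(eg$vectors)
  det_fit <- det(s$sigma); det_corr <- det(corr)
  a <- if (det_corr > 0 && det_fit > 0) s$a * sqrt(det_fit / det_corr) else s$a
  list(a = a, mu = s$mu, sigma = corr)
}

mixture_eval <- function(shapes, coords) {
  out <- numeric(nrow(coords))
  for (s in shapes) {
    d <- sweep(coords, 2L, s$mu)
    si <- tryCatch(solve(s$sigma), error = function(e) NULL)
    if (is.null(si)) next
    out <- out + s$a * exp(-0.5 * rowSums((d %*% si) * d))
  }
  out
}

#' Fit a 3D Gaussian mixture to one segmented cluster
#'
#' Fits one Gaussian per seed to the blurred image, jointly over all seeds of
#' the cluster, by bounded least squares on the voxels of the filled mask
#' belonging to the cluster's region. Each Gaussian is initialised at its
#' seed with the image intensity there and a default covariance; fitted means
#' are constrained to within `max_shift_um` of their seeds. If the optimiser
#' fails, the seed-initialised shapes are returned flagged `unreliable`.
#'
#' @param image The original 3D image.
#' @param masks A [segment_foreground()] result for this image.
#' @param cluster_id Cluster label to fit (must have at least one seed).
#' @param seeds The positions tibble the masks were built with.
#' @param res An [image_resolution()].
#' @param cfg A [gaussfit_config()].
#' @param seg_cfg The [segmentation_config()] (for the pre-fit blur).
#' @return A shapes tibble, one row per seed of the cluster.
#' @export
fit_cluster <- function(image, masks, cluster_id, seeds, res,
                        cfg = gaussfit_config(), seg_cfg = segmentation_config()) {
  stopifnot(inherits(masks, "segmentation_masks"), is_resolution(res))
  in_cluster <- masks$clusters$cluster == cluster_id
  if (!any(in_cluster)) {
    stop("fit_cluster: cluster has no seeds", call. = FALSE)
  }
  sd_seeds <- seeds[match(masks$clusters$i[in_cluster], seeds$i), , drop = FALSE]
  blurred <- gaussian_blur_3d(image, seg_cfg$blur_sigma_xy, seg_cfg$blur_sigma_z)
  vox <- which(masks$mask_filled & masks$regions == cluster_id)
  fit_shapes_to_voxels(blurred, vox, sd_seeds, res, cfg,
                       blur_cov = blur_covariance(seg_cfg, res))
}

# covariance added to every nucleus by the pre-fit blur, in um^2. Computed
# from the variance of the discrete kernels actually applied: for small
# sigma the sampled, truncated Gaussian has noticeably less variance than
# sigma^2 (e.g. 0.215 instead of 0.25 at sigma = 0.5), and subtracting the
# nominal value would bias the deconvolved covariances low.
blur_covariance <- function(seg_cfg, res) {
  kern_var <- function(sigma) {
    if (sigma <= 0) return(0)
    k <- gauss_kernel(sigma)
    r <- (length(k) - 1) / 2
    sum(k * seq(-r, r)^2)
  }
  diag(c(kern_var(seg_cfg$blur_sigma_xy) * res$pixel_size_xy^2,
         kern_var(seg_cfg$blur_sigma_xy) * res$pixel_size_xy^2,
         kern_var(seg_cfg$blur_sigma_z) * res$z_step^2))
}

# core fit shared by fit_cluster and fit_experiment; vox = linear indices of
# the voxels entering the residual. The fit happens in blurred-image space;
# blur_cov (the known blur covariance) is deconvolved from the reported
# shapes so they describe the nucleus, not the blurred image.
fit_shapes_to_voxels <- function(blurred, vox, sd_seeds, res, cfg,
                                 blur_cov = matrix(0, 3, 3)) {
  d <- dim(blurred)
  n <- nrow(sd_seeds)
  seed_um <- cbind(sd_seeds$x * res$pixel_size_xy,
                   sd_seeds$y * res$pixel_size_xy,
                   sd_seeds$z * res$z_step)
  init_theta <- function() {
    l1 <- cfg$init_sigma_xy_px * res$pixel_size_xy
    l3 <- cfg$init_sigma_z_slices * res$z_step
    unlist(lapply(seq_len(n), function(k) {
      yv <- min(max(round(sd_seeds$y[k]) + 1L, 1L), d[1])
      xv <- min(max(round(sd_seeds$x[k]) + 1L, 1L), d[2])
      zv <- min(max(round(sd_seeds$z[k]) + 1L, 1L), d[3])
      a0 <- max(blurred[yv, xv, zv], 1e-3)
      c(a0, seed_um[k, ], l1, l1, l3, 0, 0, 0)
    }))
  }
  theta0 <- init_theta()
  as_tbl <- function(theta, unreliable) {
    sh <- params_to_shapes(theta, n)
    purrr::map_dfr(seq_len(n), function(k) {
      s <- deconvolve_blur(sh[[k]], blur_cov)
      shapes_tbl(sd_seeds$t[k], sd_seeds$i[k], s$a,
                 s$mu[1], s$mu[2], s$mu[3],
                 s$sigma[1, 1], s$sigma[2, 2], s$sigma[3, 3],
                 s$sigma[1, 2], s$sigma[1, 3], s$sigma[2, 3],
                 unreliable = unreliable)
    })
  }
  if (!length(vox)) return(as_tbl(theta0, TRUE))
  if (length(vox) > cfg$max_voxels) {
    vox <- vox[seq(1L, length(vox), length.out = cfg$max_voxels)]
  }
  ai <- arrayInd(vox, d)
  coords <- cbind((ai[, 2] - 1) * res$pixel_size_xy,
                  (ai[, 1] - 1) * res$pixel_size_xy,
                  (ai[, 3] - 1) * res$z_step)
  target <- blurred[vox]
  amax <- 2 * max(target, 1e-3)
  lower <- rep(c(0, -Inf, -Inf, -Inf, 0.15, 0.15, 0.15, -8, -8, -8), n)
  upper <- rep(c(amax, Inf, Inf, Inf, 8, 8, 8, 8, 8, 8), n)
  for (k in seq_len(n)) {
    o <- (k - 1) * 10
    lower[o + 2:4] <- seed_um[k, ] - cfg$max_shift_um
    upper[o + 2:4] <- seed_um[k, ] + cfg$max_shift_um
  }
  resid_fn <- function(theta) {
    target - mixture_eval(params_to_shapes(theta, n), coords)
  }
  fit <- tryCatch(
    minpack.lm::nls.lm(par = theta0, lower = lower, upper = upper,
                       fn = resid_fn,
                       control = minpack.lm::nls.lm.control(
                         maxiter = cfg$maxiter, ftol = cfg$ftol)),
    error = function(e) NULL)
  if (is.null(fit) || !(fit$info %in% 1:4)) {
    theta <- if (!is.null(fit)) fit$par else theta0
    # keep whatever improvement was achieved but flag the fit
    bad <- is.null(fit) ||
      sum(resid_fn(theta)^2) > sum(resid_fn(theta0)^2)
    return(as_tbl(if (bad) theta0 else theta, TRUE))
  }
  as_tbl(fit$par, FALSE)
}

#' Fit Gaussian shapes for every frame of an experiment
#'
#' Runs [segment_foreground()] and [fit_cluster()] per frame, using the
#' experiment's detected positions as seeds, and returns the experiment with
#' its `shapes` slot filled. Seeds that end up in no cluster (rare, when
#' erosion removes the voxels around a seed) get their seed-initialised
#' shape, flagged unreliable.
#'
#' @param exp A [tracking_experiment()].
#' @param frames List of 3D image arrays indexed by frame (`frames[[t + 1]]`).
#' @param cfg A [gaussfit_config()].
#' @param seg_cfg A [segmentation_config()].
#' @return The experiment with `shapes` set.
#' @export
fit_experiment <- function(exp, frames, cfg = gaussfit_config(),
                           seg_cfg = segmentation_config()) {
  stopifnot(inherits(exp, "tracking_experiment"))
  all_shapes <- list()
  for (tt in sort(unique(exp$positions$t))) {
    image <- frames[[tt + 1L]]
    seeds <- dplyr::filter(exp$positions, .data$t == tt)
    masks <- segment_foreground(image, seeds, seg_cfg)
    blurred <- gaussian_blur_3d(image, seg_cfg$blur_sigma_xy, seg_cfg$blur_sigma_z)
    for (cl in unique(masks$clusters$cluster)) {
      in_cl <- masks$clusters$cluster == cl
      sd_seeds <- seeds[match(masks$clusters$i[in_cl], seeds$i), , drop = FALSE]
      vox <- if (cl > 0) which(masks$mask_filled & masks$regions == cl) else integer()
      all_shapes[[length(all_shapes) + 1L]] <-
        fit_shapes_to_voxels(blurred, vox, sd_seeds, exp$resolution, cfg,
                             blur_cov = blur_covariance(seg_cfg, exp$resolution))
    }
  }
  exp$shapes <- if (length(all_shapes)) dplyr::bind_rows(all_shapes) else shapes_tbl()
  exp$shapes <- dplyr::arrange(exp$shapes, .data$t, .data$i)
  validate_experiment(exp)
  exp
}
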
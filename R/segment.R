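#' Segmentation parameters
#'
#' @param block Odd side of the per-slice local-mean window for the adaptive
#'   threshold, in pixels.
#' @param offset_frac Threshold offset as a fraction of the image dynamic
#'   range; a voxel is foreground when it exceeds its local mean plus this
#'   offset.
#' @param curvature_sigma Standard deviation (voxels) of the Gaussian
#'   derivatives used for the iso-intensity curvature step.
#' @param blur_sigma_xy,blur_sigma_z Pre-fit blur of the image, in pixels /
#'   slices.
#' @param seed_radius_um How far from a seed to search for its cluster when
#'   erosion removed the voxel under the seed.
#' @return A `segmentation_config` object.
#' @export
segmentation_config <- function(block = 51, offset_frac = 0.02,
                                curvature_sigma = 1,
                                blur_sigma_xy = 2, blur_sigma_z = 0.5,
                                seed_radius_um = 5) {
  stopifnot(block >= 3, block %% 2 == 1, offset_frac >= 0,
            curvature_sigma > 0, blur_sigma_xy >= 0, blur_sigma_z >= 0,
            seed_radius_um > 0)
  structure(list(block = as.integer(block), offset_frac = offset_frac,
                 curvature_sigma = curvature_sigma,
                 blur_sigma_xy = blur_sigma_xy, blur_sigma_z = blur_sigma_z,
                 seed_radius_um = seed_radius_um),
            class = "segmentation_config")
}

gauss_kernel <- function(sigma, order = 0) {
  r <- max(1L, ceiling(3 * sigma))
  x <- seq(-r, r)
  g <- exp(-x^2 / (2 * sigma^2))
  g <- g / sum(g)
  switch(as.character(order),
         "0" = g,
         "1" = -x / sigma^2 * g,
         "2" = (x^2 - sigma^2) / sigma^4 * g)
}

box_kernel <- function(block) rep(1 / block, block)

# per-slice local mean with a block x block box window
local_mean_xy <- function(image, block) {
  k <- box_kernel(block)
  out <- conv_axis(image, dim(image), k, 0L)
  conv_axis(out, dim(out), k, 1L)
}

gaussian_blur_3d <- function(image, sigma_xy, sigma_z) {
  out <- image
  if (sigma_xy > 0) {
    k <- gauss_kernel(sigma_xy)
    out <- conv_axis(out, dim(out), k, 0L)
    out <- conv_axis(out, dim(out), k, 1L)
  }
  if (sigma_z > 0 && dim(image)[3] > 1) {
    out <- conv_axis(out, dim(out), gauss_kernel(sigma_z), 2L)
  }
  out
}

# sign of the iso-intensity Gaussian curvature: K = grad' adj(H) grad / |grad|^4;
# computed from Gaussian derivatives of the image, only the numerator's sign
# is used (the denominator is positive)
curvature_negative <- function(image, sigma) {
  d <- dim(image)
  g0 <- gauss_kernel(sigma, 0); g1 <- gauss_kernel(sigma, 1); g2 <- gauss_kernel(sigma, 2)
  dv <- function(oy, ox, oz) {
    out <- conv_axis(image, d, switch(oy + 1, g0, g1, g2), 0L)
    out <- conv_axis(out, d, switch(ox + 1, g0, g1, g2), 1L)
    if (d[3] > 1) out <- conv_axis(out, d, switch(oz + 1, g0, g1, g2), 2L)
    out
  }
  Iy <- dv(1, 0, 0); Ix <- dv(0, 1, 0); Iz <- dv(0, 0, 1)
  Iyy <- dv(2, 0, 0); Ixx <- dv(0, 2, 0); Izz <- dv(0, 0, 2)
  Ixy <- dv(1, 1, 0); Ixz <- dv(0, 1, 1); Iyz <- dv(1, 0, 1)
  adj11 <- Iyy * Izz - Iyz^2
  adj22 <- Ixx * Izz - Ixz^2
  adj33 <- Ixx * Iyy - Ixy^2
  adj12 <- Ixz * Iyz - Ixy * Izz
  adj13 <- Ixy * Iyz - Iyy * Ixz
  adj23 <- Ixy * Ixz - Ixx * Iyz
  num <- Ix^2 * adj11 + Iy^2 * adj22 + Iz^2 * adj33 +
    2 * (Ix * Iy * adj12 + Ix * Iz * adj13 + Iy * Iz * adj23)
  grad2 <- Ix^2 + Iy^2 + Iz^2
  num < 0 & grad2 > (1e-8 * max(abs(image)))^2
}

erode_cross_xy <- function(mask) {
  d <- dim(mask)
  out <- mask
  pad <- function(m, dy, dx) {
    r <- array(FALSE, dim = d)
    ys <- seq_len(d[1]); xs <- seq_len(d[2])
    ysrc <- ys + dy; xsrc <- xs + dx
    oky <- ysrc >= 1 & ysrc <= d[1]; okx <- xsrc >= 1 & xsrc <= d[2]
    r[ys[oky], xs[okx], ] <- m[ysrc[oky], xsrc[okx], , drop = FALSE]
    r
  }
  out & pad(mask, 1, 0) & pad(mask, -1, 0) & pad(mask, 0, 1) & pad(mask, 0, -1)
}

#' Segment foreground nuclei into seeded clusters
#'
#' The segmentation cascade used before Gaussian fitting:
#' (1) a per-slice adaptive threshold (local mean over a `block`-pixel
#' window plus an offset) produces the raw foreground mask; (2) voxels whose
#' iso-intensity Gaussian curvature in the original image is negative are
#' removed, cutting the saddle-like valleys between adjacent nuclei; (3)
#' holes are filled (3D); (4) three rounds of erosion with a 3x3x1
#' cross-shaped kernel split touching nuclei apart; (5) connected components
#' of the eroded mask become clusters and each seed (detected nucleus
#' center) is assigned to its cluster.
#'
#' @param image A 3D array `(ny, nx, nz)`.
#' @param seeds A positions tibble for this frame (may be empty).
#' @param cfg A [segmentation_config()].
#' @return A `segmentation_masks` object: logical arrays `mask`,
#'   `mask_filled`, `mask_eroded`, integer arrays `labels` (components of the
#'   eroded mask) and `regions` (labels grown back over the filled mask), and
#'   a `clusters` tibble mapping each seed to its cluster (0 = unassigned).
#' @export
segment_foreground <- function(image, seeds = positions_tbl(),
                               cfg = segmentation_config()) {
  stopifnot(length(dim(image)) == 3, inherits(cfg, "segmentation_config"))
  d <- dim(image)
  rng <- range(image)
  if (length(image) == 0 || rng[2] == rng[1]) {
    empty <- array(FALSE, dim = d)
    return(structure(list(mask = empty, mask_filled = empty, mask_eroded = empty,
                          labels = array(0L, dim = d), regions = array(0L, dim = d),
                          clusters = tibble::tibble(i = seeds$i, cluster = integer(nrow(seeds)))),
                     class = "segmentation_masks"))
  }
  offset <- cfg$offset_frac * (rng[2] - rng[1])
  block <- min(cfg$block, 2L * (min(d[1], d[2]) %/% 2L) - 1L)
  mask <- image > local_mean_xy(image, block) + offset
  mask <- mask & !curvature_negative(image, cfg$curvature_sigma)
  mask_filled <- array(fill_holes_3d(mask, d), dim = d)
  mask_eroded <- mask_filled
  for (k in 1:3) mask_eroded <- erode_cross_xy(mask_eroded)
  labels <- label3d(mask_eroded, d)
  regions <- grow_labels(labels, mask_filled, d)
  cluster <- integer(nrow(seeds))
  if (nrow(seeds)) {
    for (k in seq_len(nrow(seeds))) {
      cluster[k] <- seed_cluster(labels, seeds[k, ], cfg, d)
    }
  }
  structure(list(mask = array(as.logical(mask), dim = d),
                 mask_filled = mask_filled, mask_eroded = mask_eroded,
                 labels = labels, regions = regions,
                 clusters = tibble::tibble(i = seeds$i, cluster = cluster)),
            class = "segmentation_masks")
}

# cluster label at (or nearest to, within seed_radius_um) a seed position
seed_cluster <- function(labels, seed, cfg, d) {
  yv <- round(seed$y) + 1L; xv <- round(seed$x) + 1L; zv <- round(seed$z) + 1L
  if (yv < 1 || yv > d[1] || xv < 1 || xv > d[2] || zv < 1 || zv > d[3]) return(0L)
  if (labels[yv, xv, zv] > 0) return(labels[yv, xv, zv])
  # search a small box around the seed for the nearest labelled voxel
  r <- 8L
  ys <- max(1L, yv - r):min(d[1], yv + r)
  xs <- max(1L, xv - r):min(d[2], xv + r)
  zs <- max(1L, zv - 2L):min(d[3], zv + 2L)
  sub <- labels[ys, xs, zs, drop = FALSE]
  idx <- which(sub > 0, arr.ind = TRUE)
  if (!nrow(idx)) return(0L)
  dy <- ys[idx[, 1]] - yv; dx <- xs[idx[, 2]] - xv; dz <- (zs[idx[, 3]] - zv) * 6
  dist <- sqrt(dy^2 + dx^2 + dz^2)
  sub[idx[which.min(dist), , drop = FALSE]]
}

#' @export
print.segmentation_masks <- function(x, ...) {
  cat(sprintf("<segmentation_masks> %d foreground voxels, %d clusters, %d/%d seeds assigned\n",
              sum(x$mask_filled), max(x$labels),
              sum(x$clusters$cluster > 0), nrow(x$clusters)))
  invisible(x)
}
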
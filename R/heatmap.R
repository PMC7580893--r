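#' Build the training target heatmap for a set of nucleus centers
#'
#' Produces a mostly-black volume with a bright 2D Gaussian spot (standard
#' deviation 2 px, amplitude 1 at the center voxel) at each nucleus center.
#' Because z-resolution is much coarser than xy, each spot is written only
#' into its own z-slice and does not cross slices. Overlapping spots are
#' combined voxel-wise by maximum, keeping targets in `[0, 1]`.
#'
#' @param positions A positions tibble; `z` is rounded to the nearest slice.
#' @param shape Integer `(z, y, x)` voxel counts.
#' @param sigma_px Spot standard deviation in pixels (default 2).
#' @return A 3D array, dim `(ny, nx, nz)`, values in `[0, 1]`.
#' @export
make_target_heatmap <- function(positions, shape, sigma_px = 2) {
  check_positions(positions)
  nz <- shape[[1]]; ny <- shape[[2]]; nx <- shape[[3]]
  hm <- array(0, dim = c(ny, nx, nz))
  if (!nrow(positions)) return(hm)
  zi <- round(positions$z)
  if (any(positions$x < 0 | positions$x > nx - 1 |
          positions$y < 0 | positions$y > ny - 1 |
          zi < 0 | zi > nz - 1)) {
    stop("make_target_heatmap: position outside the volume", call. = FALSE)
  }
  r <- ceiling(4 * sigma_px)
  for (k in seq_len(nrow(positions))) {
    x0 <- positions$x[k]; y0 <- positions$y[k]; z0 <- zi[k]
    xs <- max(0, floor(x0 - r)):min(nx - 1, ceiling(x0 + r))
    ys <- max(0, floor(y0 - r)):min(ny - 1, ceiling(y0 + r))
    d2 <- outer((ys - y0)^2, (xs - x0)^2, "+")
    spot <- exp(-d2 / (2 * sigma_px^2))
    hm[ys + 1, xs + 1, z0 + 1] <- pmax(hm[ys + 1, xs + 1, z0 + 1], spot)
  }
  hm
}

#' Adjust image contrast about its mean
#'
#' Applies `I_new = (I - mean(I)) * c + mean(I)` with the mean taken over the
#' whole image. `c = 1` is the identity; `c < 1` flattens, `c > 1` stretches.
#'
#' @param image A numeric array.
#' @param c Contrast factor, > 0.
#' @return The adjusted array.
#' @examples
#' contrast_adjust(array(c(0, 100), c(2, 1, 1)), 0.5)  # 25, 75
#' @export
contrast_adjust <- function(image, c) {
  stopifnot(is.numeric(c), length(c) == 1L, c > 0)
  m <- mean(image)
  (image - m) * c + m
}

#' Randomly perturb a training image/target pair
#'
#' Applies an identical geometric transform to the image and its target
#' heatmap: independent x/y/z flips, an in-plane rotation by a uniform
#' 0-360 degree angle and a uniform 80-120% scaling (bilinear resampling per
#' z-slice about the slice center; the coarse z-step makes arbitrary 3D
#' rotations ill-defined). The image additionally gets a brightness shift of
#' at most 10% of its maximum intensity and a contrast factor in
#' `[0.5, 1.5]` (see [contrast_adjust()]). Targets are clamped at 0 after
#' interpolation. Deterministic given `seed`.
#'
#' @param image,target 3D arrays of identical shape.
#' @param seed Integer seed.
#' @return A list with elements `image` and `target`.
#' @export
augment_pair <- function(image, target, seed) {
  stopifnot(identical(dim(image), dim(target)))
  with_preserved_rng({
    set.seed(seed)
    flips <- stats::runif(3) < 0.5  # x, y, z
    theta <- stats::runif(1, 0, 2 * pi)
    scale <- stats::runif(1, 0.8, 1.2)
    bright <- stats::runif(1, -0.1, 0.1) * max(image)
    contrast <- stats::runif(1, 0.5, 1.5)

    geo <- function(v) {
      if (flips[1]) v <- v[, dim(v)[2]:1, , drop = FALSE]
      if (flips[2]) v <- v[dim(v)[1]:1, , , drop = FALSE]
      if (flips[3]) v <- v[, , dim(v)[3]:1, drop = FALSE]
      rotate_scale_xy(v, theta, scale)
    }
    img <- contrast_adjust(geo(image) + bright, contrast)
    tgt <- geo(target)
    tgt[tgt < 0] <- 0
    list(image = img, target = tgt)
  })
}

# rotate by theta and scale about the slice center, bilinear, zero fill
rotate_scale_xy <- function(v, theta, scale) {
  if (abs(theta) < 1e-12 && abs(scale - 1) < 1e-12) return(v)
  ny <- dim(v)[1]; nx <- dim(v)[2]; nz <- dim(v)[3]
  cy <- (ny - 1) / 2; cx <- (nx - 1) / 2
  # inverse map: output pixel -> input pixel
  yy <- rep(seq_len(ny) - 1 - cy, times = nx)
  xx <- rep(seq_len(nx) - 1 - cx, each = ny)
  ct <- cos(theta); st <- sin(theta)
  sx <- (ct * xx + st * yy) / scale + cx
  sy <- (-st * xx + ct * yy) / scale + cy
  x0 <- floor(sx); y0 <- floor(sy)
  fx <- sx - x0; fy <- sy - y0
  out <- array(0, dim = dim(v))
  at <- function(yi, xi, slice) {
    ok <- yi >= 0 & yi < ny & xi >= 0 & xi < nx
    val <- numeric(length(yi))
    val[ok] <- slice[cbind(yi[ok] + 1, xi[ok] + 1)]
    val
  }
  for (z in seq_len(nz)) {
    s <- v[, , z]
    val <- at(y0, x0, s) * (1 - fy) * (1 - fx) +
      at(y0 + 1, x0, s) * fy * (1 - fx) +
      at(y0, x0 + 1, s) * (1 - fy) * fx +
      at(y0 + 1, x0 + 1, s) * fy * fx
    out[, , z] <- val
  }
  out
}

#' Weighted mean squared error between a predicted and a target heatmap
#'
#' Target heatmaps are almost entirely zero, so a plain MSE would let the
#' network collapse to black images. Voxels where the target is nonzero
#' (fraction `f` of the volume) get raw weight `1 - f` and zero-target voxels
#' get raw weight `f`; the weighted square error is normalised by the total
#' weight (mean weight 1), which boosts the rare spot voxels by roughly
#' `1 / (2f)`. Degenerate all-zero (or all-nonzero) targets fall back to the
#' plain MSE.
#'
#' @param pred,target Numeric arrays of identical shape.
#' @return Scalar loss, >= 0, zero iff `pred == target`.
#' @export
weighted_mse <- function(pred, target) {
  stopifnot(identical(dim(pred), dim(target)))
  f <- mean(target != 0)
  e2 <- (pred - target)^2
  if (f == 0 || f == 1) return(mean(e2))
  w <- ifelse(target != 0, 1 - f, f)
  sum(w * e2) / sum(w)
}

# gradient of weighted_mse wrt pred (used by the trainer)
weighted_mse_grad <- function(pred, target) {
  f <- mean(target != 0)
  if (f == 0 || f == 1) {
    return(2 * (pred - target) / length(pred))
  }
  w <- ifelse(target != 0, 1 - f, f)
  2 * w * (pred - target) / sum(w)
}

#' Find nucleus centers as local maxima of a heatmap
#'
#' The heatmap is first linearly interpolated along z so that the voxel size
#' is isotropic (equal to the xy pixel size), then 3D local maxima above
#' `threshold_rel * max(heatmap)` are extracted and greedily thinned so that
#' surviving peaks are at least `min_distance_um` apart (strongest first).
#' The z coordinate of each peak is mapped back to the nearest original
#' image slice.
#'
#' @param hm A 3D heatmap array, dim `(ny, nx, nz)`.
#' @param res An [image_resolution()].
#' @param min_distance_um Minimum pairwise peak distance in um (> 0).
#' @param threshold_rel Relative intensity threshold in `(0, 1)`.
#' @param t Frame index stored in the returned positions (default 0).
#' @return A positions tibble.
#' @export
detect_peaks <- function(hm, res, min_distance_um = 2, threshold_rel = 0.1, t = 0L) {
  stopifnot(is_resolution(res), min_distance_um > 0)
  mx <- max(hm)
  if (mx <= 0) return(positions_tbl())
  iso <- interp_z_isotropic(hm, res)
  peaks <- local_max_3d(iso$vol, dim(iso$vol), threshold_rel * mx)
  if (!nrow(peaks)) return(positions_tbl())
  val <- iso$vol[peaks]
  ord <- order(-val, peaks[, 1], peaks[, 2], peaks[, 3])
  peaks <- peaks[ord, , drop = FALSE]
  # peak coordinates in um (isotropic grid: all axes at pixel_size_xy)
  pm <- (peaks - 1) * res$pixel_size_xy
  keep <- logical(nrow(peaks))
  kept <- matrix(numeric(), 0, 3)
  for (k in seq_len(nrow(peaks))) {
    if (!nrow(kept) ||
        min(sqrt(colSums((t(kept) - pm[k, ])^2))) >= min_distance_um) {
      keep[k] <- TRUE
      kept <- rbind(kept, pm[k, ])
    }
  }
  peaks <- peaks[keep, , drop = FALSE]
  z_slice <- round((peaks[, 3] - 1) * iso$step_ratio)
  z_slice[z_slice > dim(hm)[3] - 1] <- dim(hm)[3] - 1
  positions_tbl(t = rep(t, nrow(peaks)),
                x = peaks[, 2] - 1, y = peaks[, 1] - 1, z = z_slice)
}

# linear interpolation along z to isotropic voxels; returns the interpolated
# volume and the ratio original-slice-per-isotropic-step
interp_z_isotropic <- function(hm, res) {
  nz <- dim(hm)[3]
  step_ratio <- res$pixel_size_xy / res$z_step  # slices per isotropic step
  if (nz == 1L) return(list(vol = hm, step_ratio = 1))
  n_iso <- floor((nz - 1) / step_ratio) + 1L
  zi <- (seq_len(n_iso) - 1) * step_ratio  # in slice units
  lo <- pmin(floor(zi), nz - 2)
  fr <- zi - lo
  vol <- array(0, dim = c(dim(hm)[1], dim(hm)[2], n_iso))
  for (k in seq_len(n_iso)) {
    vol[, , k] <- hm[, , lo[k] + 1] * (1 - fr[k]) + hm[, , lo[k] + 2] * fr[k]
  }
  list(vol = vol, step_ratio = step_ratio)
}
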
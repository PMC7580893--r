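#' Voxel and time calibration of a movie
#'
#' Holds the physical size of a voxel and the time between frames, and is used
#' everywhere a pixel/slice/frame coordinate has to be converted to micrometers
#' or hours. Defaults are typical confocal settings for organoid time-lapse
#' imaging: 0.32 um/px in xy, 2 um between z-slices, 12 minutes per frame.
#'
#' @param pixel_size_xy Micrometers per pixel in x and y. Must be > 0.
#' @param z_step Micrometers between two consecutive z-slices. Must be > 0.
#' @param time_step Minutes between two consecutive frames. Must be > 0.
#' @return An object of class `image_resolution`.
#' @examples
#' res <- image_resolution()
#' res$pixel_size_xy
#' @export
image_resolution <- function(pixel_size_xy = 0.32, z_step = 2, time_step = 12) {
  for (v in c(pixel_size_xy, z_step, time_step)) {
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v <= 0) {
      stop("image_resolution: pixel_size_xy, z_step and time_step must be single positive finite numbers",
           call. = FALSE)
    }
  }
  structure(
    list(pixel_size_xy = pixel_size_xy, z_step = z_step, time_step = time_step),
    class = "image_resolution"
  )
}

#' @export
print.image_resolution <- function(x, ...) {
  cat(sprintf("<image_resolution> %.4g x %.4g um/px (xy), %.4g um/slice (z), %.4g min/frame\n",
              x$pixel_size_xy, x$pixel_size_xy, x$z_step, x$time_step))
  invisible(x)
}

is_resolution <- function(x) inherits(x, "image_resolution")

#' Convert pixel/slice coordinates to micrometers
#'
#' Maps the (x, y) pixel coordinates and z slice index of nucleus positions to
#' physical micrometer coordinates. Coordinates are 0-based and voxel-centered,
#' so the origin maps to (0, 0, 0) um.
#'
#' @param positions A positions tibble (columns `x`, `y`, `z`; see
#'   [positions_tbl()]) or a numeric vector `c(x, y, z)`.
#' @param res An [image_resolution()].
#' @return For a tibble input, the tibble with columns `x_um`, `y_um`, `z_um`
#'   added; for a vector input, a numeric 3-vector in micrometers.
#' @examples
#' to_micrometers(c(10, 0, 3), image_resolution())
#' @export
to_micrometers <- function(positions, res) {
  stopifnot(is_resolution(res))
  if (is.numeric(positions)) {
    if (length(positions) != 3L || any(!is.finite(positions))) {
      stop("to_micrometers: coordinates must be a finite (x, y, z) triple", call. = FALSE)
    }
    return(c(positions[1] * res$pixel_size_xy,
             positions[2] * res$pixel_size_xy,
             positions[3] * res$z_step))
  }
  check_positions(positions)
  if (any(!is.finite(positions$x) | !is.finite(positions$y) | !is.finite(positions$z))) {
    stop("to_micrometers: non-finite coordinates", call. = FALSE)
  }
  dplyr::mutate(positions,
                x_um = .data$x * res$pixel_size_xy,
                y_um = .data$y * res$pixel_size_xy,
                z_um = .data$z * res$z_step)
}

#' Convert a frame count to hours
#'
#' @param frames Number of frames (may be fractional).
#' @param res An [image_resolution()].
#' @return Hours elapsed.
#' @export
frames_to_hours <- function(frames, res) {
  stopifnot(is_resolution(res))
  frames * res$time_step / 60
}
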
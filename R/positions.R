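#' Build a positions tibble
#'
#' Nucleus-center detections are stored as a tibble with one row per detection:
#' `t` is the 0-based frame index, `i` a 1-based index within the frame (used
#' by links and shapes to refer to a position), and `x`, `y` (pixels) and `z`
#' (slice index, fractional values allowed) the 0-based voxel-centered
#' coordinates.
#'
#' @param t Integer frame indices (0-based).
#' @param x,y Pixel coordinates.
#' @param z Slice indices (fractional allowed).
#' @return A tibble with columns `t`, `i`, `x`, `y`, `z`, with `i` assigned
#'   per frame in input order.
#' @examples
#' positions_tbl(t = c(0, 0, 1), x = c(1, 2, 1.5), y = c(5, 6, 5.5), z = c(3, 3, 3))
#' @export
positions_tbl <- function(t = integer(), x = numeric(), y = numeric(), z = numeric()) {
  n <- max(length(t), length(x), length(y), length(z))
  if (n > 0) {
    recycle <- function(v) if (length(v) == 1L) rep(v, n) else v
    t <- recycle(t); x <- recycle(x); y <- recycle(y); z <- recycle(z)
  }
  stopifnot(length(t) == length(x), length(x) == length(y), length(y) == length(z))
  if (length(t) && (any(!is.finite(t)) || any(t < 0) || any(t != floor(t)))) {
    stop("positions_tbl: t must contain non-negative integers", call. = FALSE)
  }
  if (length(x) && any(!is.finite(c(x, y, z)))) {
    stop("positions_tbl: coordinates must be finite", call. = FALSE)
  }
  out <- tibble::tibble(t = as.integer(t), x = as.numeric(x),
                        y = as.numeric(y), z = as.numeric(z))
  out <- dplyr::mutate(dplyr::group_by(out, .data$t),
                       i = dplyr::row_number(), .after = "t")
  dplyr::ungroup(out)
}

check_positions <- function(positions) {
  if (!is.data.frame(positions) || !all(c("t", "i", "x", "y", "z") %in% names(positions))) {
    stop("expected a positions tibble with columns t, i, x, y, z", call. = FALSE)
  }
  invisible(positions)
}

check_links <- function(links) {
  if (!is.data.frame(links) || !all(c("t", "from", "to") %in% names(links))) {
    stop("expected a links tibble with columns t, from, to", call. = FALSE)
  }
  invisible(links)
}

#' Build a links tibble
#'
#' A link connects a position at frame `t` (index `from` within that frame) to
#' a position at frame `t + 1` (index `to`). A division shows up as two links
#' sharing the same `(t, from)`; no separate event object exists.
#'
#' @param t Integer frame index of the source position.
#' @param from Within-frame index (`i`) of the source at frame `t`.
#' @param to Within-frame index (`i`) of the target at frame `t + 1`.
#' @return A tibble with columns `t`, `from`, `to`.
#' @export
links_tbl <- function(t = integer(), from = integer(), to = integer()) {
  n <- max(length(t), length(from), length(to))
  if (n > 0) {
    recycle <- function(v) if (length(v) == 1L) rep(v, n) else v
    t <- recycle(t); from <- recycle(from); to <- recycle(to)
  }
  stopifnot(length(t) == length(from), length(from) == length(to))
  tibble::tibble(t = as.integer(t), from = as.integer(from), to = as.integer(to))
}

#' Pairwise micrometer distance between two sets of positions
#'
#' @param a,b Positions tibbles (or data frames with x, y, z columns).
#' @param res An [image_resolution()].
#' @return A `nrow(a)` x `nrow(b)` matrix of Euclidean distances in um.
#' @export
position_dist_um <- function(a, b, res) {
  ax <- a$x * res$pixel_size_xy; ay <- a$y * res$pixel_size_xy; az <- a$z * res$z_step
  bx <- b$x * res$pixel_size_xy; by <- b$y * res$pixel_size_xy; bz <- b$z * res$z_step
  dx <- outer(ax, bx, "-"); dy <- outer(ay, by, "-"); dz <- outer(az, bz, "-")
  sqrt(dx * dx + dy * dy + dz * dz)
}
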
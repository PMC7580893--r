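#' A fitted 3D Gaussian nucleus shape
#'
#' The intensity profile of one nucleus is modelled as
#' \deqn{G(x) = a \exp(-\tfrac12 (x-\mu)^T \Sigma^{-1} (x-\mu))}
#' with `a` the peak intensity (image units), `mu` the center in micrometers
#' and `sigma` a symmetric positive-definite 3x3 covariance in um^2.
#'
#' @param a Peak intensity, >= 0.
#' @param mu Numeric 3-vector, center in micrometers (x, y, z).
#' @param sigma Symmetric positive-definite 3x3 covariance matrix (um^2).
#' @return An object of class `gaussian_shape`.
#' @examples
#' gaussian_shape(100, c(5, 5, 4), diag(c(4, 4, 2)))
#' @export
gaussian_shape <- function(a, mu, sigma) {
  stopifnot(is.numeric(a), length(a) == 1L, is.finite(a), a >= 0,
            is.numeric(mu), length(mu) == 3L, all(is.finite(mu)))
  sigma <- as.matrix(sigma)
  if (!all(dim(sigma) == c(3L, 3L)) || max(abs(sigma - t(sigma))) > 1e-8) {
    stop("gaussian_shape: sigma must be a symmetric 3x3 matrix", call. = FALSE)
  }
  ev <- eigen(sigma, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= 0) stop("gaussian_shape: sigma must be positive-definite", call. = FALSE)
  structure(list(a = a, mu = as.numeric(mu), sigma = (sigma + t(sigma)) / 2),
            class = "gaussian_shape")
}

#' @export
print.gaussian_shape <- function(x, ...) {
  cat(sprintf("<gaussian_shape> a=%.4g, mu=(%.3g, %.3g, %.3g) um, diag(Sigma)=(%.3g, %.3g, %.3g) um^2\n",
              x$a, x$mu[1], x$mu[2], x$mu[3],
              x$sigma[1, 1], x$sigma[2, 2], x$sigma[3, 3]))
  invisible(x)
}

#' Evaluate a Gaussian nucleus model at points
#'
#' @param shape A [gaussian_shape()].
#' @param x A numeric 3-vector or an n x 3 matrix of micrometer coordinates.
#' @return Intensity value(s); `a` at the mean, decaying with the Mahalanobis
#'   distance.
#' @examples
#' s <- gaussian_shape(10, c(0, 0, 0), diag(3) * 4)
#' gaussian_eval(s, c(2, 0, 0))  # 10 * exp(-0.5)
#' @export
gaussian_eval <- function(shape, x) {
  stopifnot(inherits(shape, "gaussian_shape"))
  if (is.null(dim(x))) x <- matrix(x, ncol = 3L, byrow = TRUE)
  d <- sweep(x, 2L, shape$mu)
  si <- tryCatch(solve(shape$sigma), error = function(e)
    stop("gaussian_eval: singular covariance", call. = FALSE))
  q <- rowSums((d %*% si) * d)
  as.numeric(shape$a * exp(-0.5 * q))
}

#' Nucleus volume proxy from a Gaussian fit
#'
#' The product of the three diagonal covariance entries,
#' `Cov(x,x) * Cov(y,y) * Cov(z,z)`. This is a relative size measure (its
#' physical dimension is um^6, not a literal volume) and is the "volume" used
#' throughout linking and error checking.
#'
#' @param shape A [gaussian_shape()], or a shapes tibble (see
#'   [shapes_tbl()]) in which case a numeric vector is returned.
#' @return The volume proxy (scalar or vector).
#' @examples
#' volume_proxy(gaussian_shape(1, c(0, 0, 0), diag(c(4, 4, 1))))  # 16
#' @export
volume_proxy <- function(shape) {
  if (inherits(shape, "gaussian_shape")) {
    return(shape$sigma[1, 1] * shape$sigma[2, 2] * shape$sigma[3, 3])
  }
  if (is.data.frame(shape) && all(c("cxx", "cyy", "czz") %in% names(shape))) {
    return(shape$cxx * shape$cyy * shape$czz)
  }
  stop("volume_proxy: expected a gaussian_shape or a shapes tibble", call. = FALSE)
}

#' Build a shapes tibble
#'
#' Per-position fitted Gaussian parameters in flat form: `(t, i)` identify the
#' position, `a` is the peak intensity, `mx/my/mz` the mean (um), `cxx..cyz`
#' the six unique covariance entries (um^2) and `unreliable` marks fits whose
#' optimiser did not converge.
#'
#' @param t,i Position identifiers.
#' @param a Peak intensities.
#' @param mx,my,mz Means in micrometers.
#' @param cxx,cyy,czz,cxy,cxz,cyz Covariance entries in um^2.
#' @param unreliable Logical fit-failure flag.
#' @return A tibble.
#' @export
shapes_tbl <- function(t = integer(), i = integer(), a = numeric(),
                       mx = numeric(), my = numeric(), mz = numeric(),
                       cxx = numeric(), cyy = numeric(), czz = numeric(),
                       cxy = 0, cxz = 0, cyz = 0, unreliable = FALSE) {
  n <- length(t)
  tibble::tibble(t = as.integer(t), i = as.integer(i), a = as.numeric(a),
                 mx = as.numeric(mx), my = as.numeric(my), mz = as.numeric(mz),
                 cxx = as.numeric(cxx), cyy = as.numeric(cyy), czz = as.numeric(czz),
                 cxy = rep_len(as.numeric(cxy), n), cxz = rep_len(as.numeric(cxz), n),
                 cyz = rep_len(as.numeric(cyz), n),
                 unreliable = rep_len(as.logical(unreliable), n))
}

#' Extract one row of a shapes tibble as a gaussian_shape
#' @param shapes A shapes tibble.
#' @param row Row number.
#' @return A [gaussian_shape()].
#' @keywords internal
shape_from_row <- function(shapes, row) {
  r <- shapes[row, ]
  sigma <- matrix(c(r$cxx, r$cxy, r$cxz,
                    r$cxy, r$cyy, r$cyz,
                    r$cxz, r$cyz, r$czz), 3L, 3L)
  gaussian_shape(r$a, c(r$mx, r$my, r$mz), sigma)
}
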
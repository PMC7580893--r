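#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot the tracked positions and links of an experiment
#'
#' An xy view (in micrometers) of all detections, colored by time, with the
#' frame-to-frame links drawn as segments. Dense movies are easier to read
#' when restricted with `frames`.
#'
#' @param object A [tracking_experiment()].
#' @param frames Optional integer vector of frames to show.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.tracking_experiment <- function(object, frames = NULL, ...) {
  pos <- to_micrometers(object$positions, object$resolution)
  if (!is.null(frames)) pos <- dplyr::filter(pos, .data$t %in% frames)
  segs <- dplyr::inner_join(
    dplyr::inner_join(object$links,
                      dplyr::select(pos, "t", "i", x0 = "x_um", y0 = "y_um"),
                      by = c("t" = "t", "from" = "i")),
    dplyr::select(dplyr::mutate(pos, t0 = .data$t - 1L),
                  "t0", "i", x1 = "x_um", y1 = "y_um"),
    by = c("t" = "t0", "to" = "i"))
  ggplot2::ggplot(pos, ggplot2::aes(x = .data$x_um, y = .data$y_um)) +
    ggplot2::geom_segment(data = segs,
                          ggplot2::aes(x = .data$x0, y = .data$y0,
                                       xend = .data$x1, yend = .data$y1),
                          color = "grey60", linewidth = 0.3, inherit.aes = FALSE) +
    ggplot2::geom_point(ggplot2::aes(color = .data$t), size = 1) +
    ggplot2::scale_color_viridis_c(name = "frame") +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "x (µm)", y = "y (µm)",
                  title = "Tracked nucleus positions") +
    ggplot2::theme_minimal()
}

#' Plot the training loss curve of a detector
#'
#' @param object A `nuc_detector`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.nuc_detector <- function(object, ...) {
  ggplot2::ggplot(tidy.nuc_detector(object),
                  ggplot2::aes(x = .data$epoch, y = .data$loss)) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::labs(x = "epoch", y = "weighted MSE",
                  title = "Detector training loss") +
    ggplot2::theme_minimal()
}

#' Draw lineage trees
#'
#' Classic lineage-tree rendering: time runs downward, each unbranched track
#' is a vertical segment, divisions connect a mother track to its two
#' daughter tracks with a horizontal bar.
#'
#' @param exp A [tracking_experiment()] (or a `lineage_forest`).
#' @param res Resolution used to express time in hours (taken from the
#'   experiment when available).
#' @return A ggplot.
#' @export
plot_lineage <- function(exp, res = NULL) {
  if (inherits(exp, "tracking_experiment")) {
    if (is.null(res)) res <- exp$resolution
    seg <- track_segments(exp)
  } else {
    stop("plot_lineage: expected a tracking_experiment", call. = FALSE)
  }
  tracks <- attr(seg, "tracks")
  if (!nrow(tracks)) stop("plot_lineage: no tracks", call. = FALSE)
  children_of <- split(tracks$track, tracks$parent)
  xpos <- stats::setNames(rep(NA_real_, nrow(tracks)), tracks$track)
  leaf_x <- 0
  assign_x <- function(tr) {
    kids <- children_of[[as.character(tr)]]
    if (is.null(kids)) {
      leaf_x <<- leaf_x + 1
      xpos[as.character(tr)] <<- leaf_x
    } else {
      for (k in kids) assign_x(k)
      xpos[as.character(tr)] <<- mean(xpos[as.character(kids)])
    }
  }
  for (tr in tracks$track[tracks$parent == 0]) assign_x(tr)
  hrs <- function(t) if (is.null(res)) t else frames_to_hours(t, res)
  tracks$x <- xpos[as.character(tracks$track)]
  vert <- tracks
  pj <- match(tracks$parent, tracks$track)
  horiz <- tracks[tracks$parent > 0, ]
  if (nrow(horiz)) {
    horiz$px <- tracks$x[pj[tracks$parent > 0]]
    horiz$pt <- tracks$end[pj[tracks$parent > 0]]
  }
  gg <- ggplot2::ggplot() +
    ggplot2::geom_segment(data = vert,
                          ggplot2::aes(x = .data$x, xend = .data$x,
                                       y = hrs(.data$begin), yend = hrs(.data$end)),
                          linewidth = 0.6)
  if (nrow(horiz)) {
    gg <- gg +
      ggplot2::geom_segment(data = horiz,
                            ggplot2::aes(x = .data$px, xend = .data$x,
                                         y = hrs(.data$pt), yend = hrs(.data$pt)),
                            linewidth = 0.6) +
      ggplot2::geom_segment(data = horiz,
                            ggplot2::aes(x = .data$x, xend = .data$x,
                                         y = hrs(.data$pt), yend = hrs(.data$begin)),
                            linewidth = 0.6)
  }
  gg + ggplot2::scale_y_reverse() +
    ggplot2::labs(x = NULL, y = if (is.null(res)) "frame" else "time (h)",
                  title = "Lineage trees") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_blank(),
                   panel.grid.major.x = ggplot2::element_blank(),
                   panel.grid.minor.x = ggplot2::element_blank())
}

#' Plot the volume-proxy time series of tracked nuclei
#'
#' Follows the fitted volume proxy of each track over time; a steady curve
#' indicates a consistent Gaussian fit, isolated spikes are fit failures.
#'
#' @param exp A [tracking_experiment()] with shapes and links.
#' @param tracks Optional subset of track ids.
#' @return A ggplot.
#' @export
plot_volume_series <- function(exp, tracks = NULL) {
  stopifnot(inherits(exp, "tracking_experiment"))
  if (is.null(exp$shapes) || !nrow(exp$shapes)) {
    stop("plot_volume_series: experiment has no shapes", call. = FALSE)
  }
  seg <- track_segments(exp)
  df <- dplyr::inner_join(seg, exp$shapes, by = c("t", "i"))
  df$volume <- volume_proxy(df)
  if (!is.null(tracks)) df <- dplyr::filter(df, .data$track %in% tracks)
  ggplot2::ggplot(df, ggplot2::aes(x = frames_to_hours(.data$t, exp$resolution),
                                   y = .data$volume,
                                   group = .data$track,
                                   color = factor(.data$track))) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "time (h)", y = "volume proxy (µm² product)",
                  color = "track", title = "Nucleus volume proxy over time") +
    ggplot2::theme_minimal()
}
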
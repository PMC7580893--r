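#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom generics augment
#' @export
generics::augment

#' Tidy a tracking experiment into one row per position
#'
#' @param x A [tracking_experiment()].
#' @param ... Unused.
#' @return A tibble: the positions with micrometer coordinates, link degrees,
#'   a division flag and the number of (unsuppressed) warnings per position.
#' @export
tidy.tracking_experiment <- function(x, ...) {
  pos <- to_micrometers(x$positions, x$resolution)
  outdeg <- dplyr::count(x$links, .data$t, .data$from, name = "n_out")
  indeg <- dplyr::count(x$links, .data$t, .data$to, name = "n_in")
  pos <- dplyr::left_join(pos, dplyr::rename(outdeg, i = "from"), by = c("t", "i"))
  pos <- dplyr::left_join(pos, dplyr::rename(indeg, i = "to"),
                          by = c("t" = "t", "i" = "i"))
  warns <- dplyr::count(dplyr::filter(x$warnings, !.data$suppressed),
                        .data$t, .data$i, name = "n_warnings")
  pos <- dplyr::left_join(pos, warns, by = c("t", "i"))
  dplyr::mutate(pos,
                n_out = dplyr::coalesce(.data$n_out, 0L),
                n_in = dplyr::coalesce(.data$n_in, 0L),
                n_warnings = dplyr::coalesce(.data$n_warnings, 0L),
                dividing = .data$n_out == 2L)
}

#' One-row summary of a tracking experiment
#'
#' @param x A [tracking_experiment()].
#' @param ... Unused.
#' @return A tibble with frame, position, link, division, track and warning
#'   counts.
#' @export
glance.tracking_experiment <- function(x, ...) {
  n_tracks <- if (nrow(x$links)) {
    seg <- track_segments(x)
    nrow(attr(seg, "tracks"))
  } else {
    nrow(x$positions)
  }
  tibble::tibble(
    n_frames = x$n_frames,
    n_positions = nrow(x$positions),
    n_links = nrow(x$links),
    n_divisions = n_divisions(x),
    n_tracks = n_tracks,
    n_shapes = if (is.null(x$shapes)) 0L else nrow(x$shapes),
    n_warnings = sum(!x$warnings$suppressed),
    n_suppressed = sum(x$warnings$suppressed))
}

#' Tidy the training history of a detector
#'
#' @param x A `nuc_detector`.
#' @param ... Unused.
#' @return A tibble `epoch`, `loss`.
#' @export
tidy.nuc_detector <- function(x, ...) {
  tibble::tibble(epoch = seq_along(x$history), loss = x$history)
}

#' @rdname tidy.nuc_detector
#' @export
glance.nuc_detector <- function(x, ...) {
  tibble::tibble(depth = x$cfg$depth, base_filters = x$cfg$base_filters,
                 n_parameters = sum(vapply(x$weights, length, numeric(1))),
                 epochs_trained = length(x$history),
                 final_loss = if (length(x$history)) x$history[length(x$history)]
                              else NA_real_)
}

#' Tidy a match result into precision/recall/F1
#'
#' @param x A `match_result` from [match_detections()] or [match_links()].
#' @param ... Unused.
#' @return A one-row tibble: counts plus precision, recall and F1.
#' @export
tidy.match_result <- function(x, ...) {
  dplyr::mutate(precision_recall_f1(x, quiet = TRUE), rejected = x$rejected)
}

#' @rdname tidy.match_result
#' @export
glance.match_result <- function(x, ...) tidy.match_result(x)

#' Tidy a lineage forest
#'
#' @param x A [build_lineage_trees()] result.
#' @param ... Unused.
#' @return The underlying tibble with a `is_root` column.
#' @export
tidy.lineage_forest <- function(x, ...) {
  dplyr::mutate(tibble::as_tibble(x), is_root = is.na(.data$parent_t))
}
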
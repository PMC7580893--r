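#' Detect nucleus centers in every frame of a movie
#'
#' Runs the trained network over each frame ([predict_heatmap()]) and calls
#' peaks ([detect_peaks()]), assembling a [tracking_experiment()] with the
#' detections (no links yet).
#'
#' @param model A trained `nuc_detector`.
#' @param frames List of 3D image arrays.
#' @param res An [image_resolution()].
#' @param threshold_rel,min_distance_um Peak-calling parameters.
#' @return A [tracking_experiment()].
#' @export
detect_movie <- function(model, frames, res, threshold_rel = 0.1,
                         min_distance_um = 2) {
  pos <- purrr::map_dfr(seq_along(frames), function(k) {
    hm <- predict_heatmap(model, frames[[k]])
    detect_peaks(hm, res, min_distance_um = min_distance_um,
                 threshold_rel = threshold_rel, t = k - 1L)
  })
  positions <- positions_tbl(pos$t, pos$x, pos$y, pos$z)
  tracking_experiment(res, positions, n_frames = length(frames))
}

#' Calibrate the peak-calling threshold on annotated validation frames
#'
#' The relative peak threshold trades recall against precision, and its best
#' value depends on how confidently a given trained network separates nuclei
#' from background. Standard practice is to pick it on annotated validation
#' data that was not used for testing: this scans a grid of thresholds,
#' scores each by detection F1 (greedy matching at `max_dist_um`), and
#' returns the best (ties resolved toward the lower threshold, i.e. higher
#' recall).
#'
#' @param model A trained `nuc_detector`.
#' @param frames List of validation image arrays (frame `k` holds `t = k - 1`).
#' @param gt_positions Ground-truth positions tibble for those frames.
#' @param res An [image_resolution()].
#' @param grid Candidate thresholds.
#' @param min_distance_um Peak suppression radius used during scoring.
#' @param max_dist_um Matching tolerance.
#' @param tta Use flip-averaged predictions (see [predict_heatmap()]); must
#'   match how the model will be applied.
#' @return The selected threshold (scalar), with the F1 grid as attribute
#'   `f1`.
#' @export
calibrate_threshold <- function(model, frames, gt_positions, res,
                                grid = seq(0.1, 0.45, by = 0.05),
                                min_distance_um = 3, max_dist_um = 5,
                                tta = FALSE) {
  hms <- lapply(frames, function(f) predict_heatmap(model, f, tta = tta))
  f1s <- vapply(grid, function(th) {
    tp <- fp <- fn <- 0L
    for (k in seq_along(frames)) {
      pk <- detect_peaks(hms[[k]], res, min_distance_um, th, t = k - 1L)
      g <- dplyr::filter(gt_positions, .data$t == k - 1L)
      m <- match_detections(g, pk, res, max_dist_um)
      tp <- tp + m$tp; fp <- fp + m$fp; fn <- fn + m$fn
    }
    precision_recall_f1(tp, fp, fn, quiet = TRUE)$f1
  }, numeric(1))
  tied <- which(f1s >= max(f1s) - 1e-12)
  out <- grid[tied[ceiling(length(tied) / 2)]]
  attr(out, "f1") <- stats::setNames(f1s, grid)
  out
}

#' Link the detections of an experiment into tracks
#'
#' Builds the [link_problem()] from the experiment (using its shapes for the
#' volume terms when present) and solves it to global optimality with
#' [solve_links()].
#'
#' @param exp A [tracking_experiment()] with positions (and ideally shapes).
#' @param weights A [link_weights()].
#' @param factor Candidate cutoff factor.
#' @return The experiment with `links` replaced by the optimal link set.
#' @export
link_experiment <- function(exp, weights = link_weights(), factor = 2) {
  stopifnot(inherits(exp, "tracking_experiment"))
  if (!nrow(exp$positions)) return(exp)
  links <- solve_links(link_problem(exp, weights, factor))
  exp$links <- tibble::as_tibble(links)
  attr(exp, "link_objective") <- attr(links, "objective")
  validate_experiment(exp)
  exp
}
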
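#' Match detections against ground-truth nucleus centers
#'
#' Greedy assignment in ascending distance order: each detection may be
#' assigned to at most one ground-truth center (and vice versa) and only
#' within `max_dist_um`. Assigned pairs are true positives; unassigned
#' ground-truth centers are false negatives; unassigned detections within
#' `max_dist_um` of some ground-truth center are false positives, and
#' detections further than that from every center are rejected (treated as
#' lying outside the annotated region and not counted). Frames are matched
#' independently and the counts summed.
#'
#' @param gt,pred Positions tibbles.
#' @param res An [image_resolution()].
#' @param max_dist_um Matching threshold in um (default 5).
#' @return A `match_result`: tibble-like list with `tp`, `fp`, `fn`,
#'   `rejected` and the `assignment` tibble.
#' @export
match_detections <- function(gt, pred, res, max_dist_um = 5) {
  check_positions(gt); check_positions(pred)
  stopifnot(is_resolution(res))
  frames <- sort(unique(c(gt$t, pred$t)))
  tp <- fp <- fn <- rejected <- 0L
  assign_rows <- list()
  for (tt in frames) {
    g <- dplyr::filter(gt, .data$t == tt)
    p <- dplyr::filter(pred, .data$t == tt)
    if (!nrow(g)) {
      rejected <- rejected + nrow(p)  # nothing annotated in this frame
      next
    }
    if (!nrow(p)) {
      fn <- fn + nrow(g)
      next
    }
    dm <- position_dist_um(g, p, res)
    ord <- order(dm)
    g_used <- logical(nrow(g)); p_used <- logical(nrow(p))
    for (o in ord) {
      if (dm[o] > max_dist_um) break
      gi <- (o - 1L) %% nrow(g) + 1L
      pi <- (o - 1L) %/% nrow(g) + 1L
      if (g_used[gi] || p_used[pi]) next
      g_used[gi] <- TRUE; p_used[pi] <- TRUE
      tp <- tp + 1L
      assign_rows[[length(assign_rows) + 1L]] <- tibble::tibble(
        t = tt, gt_i = g$i[gi], pred_i = p$i[pi], dist_um = dm[o])
    }
    fn <- fn + sum(!g_used)
    if (any(!p_used)) {
      near_any <- apply(dm[, !p_used, drop = FALSE] <= max_dist_um, 2L, any)
      fp <- fp + sum(near_any)
      rejected <- rejected + sum(!near_any)
    }
  }
  structure(list(tp = tp, fp = fp, fn = fn, rejected = rejected,
                 assignment = if (length(assign_rows)) dplyr::bind_rows(assign_rows)
                              else tibble::tibble(t = integer(), gt_i = integer(),
                                                  pred_i = integer(), dist_um = numeric())),
            class = "match_result")
}

#' @export
print.match_result <- function(x, ...) {
  m <- precision_recall_f1(x$tp, x$fp, x$fn)
  cat(sprintf("<match_result> TP %d, FP %d, FN %d, rejected %d | precision %.3f, recall %.3f, F1 %.3f\n",
              x$tp, x$fp, x$fn, x$rejected, m$precision, m$recall, m$f1))
  invisible(x)
}

#' Match predicted links against ground-truth links
#'
#' A ground-truth link is recovered (a true positive) when some predicted
#' link connects detections within `max_dist_um` of both of its endpoints;
#' each ground-truth link consumes at most one predicted link and vice
#' versa. Unrecovered ground-truth links are false negatives. Leftover
#' predicted links are false positives, unless both endpoints are further
#' than `max_dist_um` from every ground-truth center at their frames, in
#' which case they are rejected (outside the annotated region).
#'
#' @param gt,pred [tracking_experiment()]s, or lists with `positions` and
#'   `links` tibbles.
#' @param res An [image_resolution()].
#' @param max_dist_um Matching threshold in um.
#' @return A `match_result` (no assignment detail).
#' @export
match_links <- function(gt, pred, res, max_dist_um = 5) {
  gp <- gt$positions; gl <- gt$links
  pp <- pred$positions; pl <- pred$links
  coords_um <- function(p) cbind(p$x * res$pixel_size_xy, p$y * res$pixel_size_xy,
                                 p$z * res$z_step)
  gum <- coords_um(gp); pum <- coords_um(pp)
  gkey <- pos_key(gp$t, gp$i); pkey <- pos_key(pp$t, pp$i)
  grow <- stats::setNames(seq_len(nrow(gp)), gkey)
  prow <- stats::setNames(seq_len(nrow(pp)), pkey)

  tp <- 0L; fn <- 0L
  p_used <- logical(nrow(pl))
  gl <- dplyr::arrange(gl, .data$t, .data$from, .data$to)
  for (k in seq_len(nrow(gl))) {
    a <- grow[pos_key(gl$t[k], gl$from[k])]
    b <- grow[pos_key(gl$t[k] + 1L, gl$to[k])]
    cand <- which(!p_used & pl$t == gl$t[k])
    if (length(cand)) {
      pa <- prow[pos_key(pl$t[cand], pl$from[cand])]
      pb <- prow[pos_key(pl$t[cand] + 1L, pl$to[cand])]
      da <- sqrt(rowSums((pum[pa, , drop = FALSE] -
                            matrix(gum[a, ], length(cand), 3, byrow = TRUE))^2))
      db <- sqrt(rowSums((pum[pb, , drop = FALSE] -
                            matrix(gum[b, ], length(cand), 3, byrow = TRUE))^2))
      ok <- da <= max_dist_um & db <= max_dist_um
      if (any(ok)) {
        pick <- cand[ok][which.min((da + db)[ok])]
        p_used[pick] <- TRUE
        tp <- tp + 1L
        next
      }
    }
    fn <- fn + 1L
  }
  fp <- 0L; rejected <- 0L
  for (k in which(!p_used)) {
    near_end <- function(key_t, key_i) {
      r <- prow[pos_key(key_t, key_i)]
      gt_frame <- which(gp$t == key_t)
      if (!length(gt_frame)) return(FALSE)
      d <- sqrt(rowSums((gum[gt_frame, , drop = FALSE] -
                           matrix(pum[r, ], length(gt_frame), 3, byrow = TRUE))^2))
      any(d <= max_dist_um)
    }
    if (near_end(pl$t[k], pl$from[k]) || near_end(pl$t[k] + 1L, pl$to[k])) {
      fp <- fp + 1L
    } else {
      rejected <- rejected + 1L
    }
  }
  structure(list(tp = tp, fp = fp, fn = fn, rejected = rejected,
                 assignment = NULL),
            class = "match_result")
}

#' Precision, recall and F1 score from match counts
#'
#' `precision = TP / (TP + FP)`, `recall = TP / (TP + FN)` and the F1 score
#' is their harmonic mean `2 p r / (p + r)`. Degenerate zero denominators
#' yield 0 with a notice.
#'
#' @param tp,fp,fn Counts, or a `match_result` as first argument.
#' @param quiet Suppress the degenerate-case notice.
#' @return A one-row tibble: `tp`, `fp`, `fn`, `precision`, `recall`, `f1`.
#' @examples
#' precision_recall_f1(96, 2, 4)
#' @export
precision_recall_f1 <- function(tp, fp = NULL, fn = NULL, quiet = FALSE) {
  if (inherits(tp, "match_result")) {
    m <- tp; tp <- m$tp; fp <- m$fp; fn <- m$fn
  }
  if (tp + fp == 0 || tp + fn == 0) {
    if (!quiet && tp + fp + fn == 0) message("precision_recall_f1: no counts at all")
    precision <- if (tp + fp > 0) tp / (tp + fp) else 0
    recall <- if (tp + fn > 0) tp / (tp + fn) else 0
    f1 <- 0
  } else {
    precision <- tp / (tp + fp)
    recall <- tp / (tp + fn)
    f1 <- if (precision + recall > 0) 2 * precision * recall / (precision + recall) else 0
  }
  tibble::tibble(tp = tp, fp = fp, fn = fn,
                 precision = precision, recall = recall, f1 = f1)
}

#' Draw spherical pseudo-masks around nucleus centers
#'
#' External mask-based scorers need segmentation masks, while this tracker
#' only produces points; a sphere of `radius_um` is therefore drawn around
#' each position on the anisotropic voxel grid. Where spheres overlap, each
#' voxel is assigned to the closest position. Labels are the within-frame
#' position indices.
#'
#' @param positions Positions tibble for one frame.
#' @param res An [image_resolution()].
#' @param shape `(z, y, x)` voxel counts.
#' @param radius_um Sphere radius in um (default 5).
#' @param labels Optional integer labels per position (defaults to the
#'   within-frame indices `positions$i`).
#' @return An integer array `(ny, nx, nz)`; 0 is background.
#' @export
make_pseudo_masks <- function(positions, res, shape, radius_um = 5, labels = NULL) {
  check_positions(positions)
  if (is.null(labels)) labels <- positions$i
  stopifnot(length(labels) == nrow(positions))
  nz <- shape[[1]]; ny <- shape[[2]]; nx <- shape[[3]]
  lab <- array(0L, dim = c(ny, nx, nz))
  if (!nrow(positions)) return(lab)
  best <- array(Inf, dim = c(ny, nx, nz))
  rx <- ceiling(radius_um / res$pixel_size_xy)
  rz <- ceiling(radius_um / res$z_step)
  for (k in seq_len(nrow(positions))) {
    x0 <- positions$x[k]; y0 <- positions$y[k]; z0 <- positions$z[k]
    xs <- max(0, floor(x0 - rx)):min(nx - 1, ceiling(x0 + rx))
    ys <- max(0, floor(y0 - rx)):min(ny - 1, ceiling(y0 + rx))
    zs <- max(0, floor(z0 - rz)):min(nz - 1, ceiling(z0 + rz))
    if (!length(xs) || !length(ys) || !length(zs)) next
    dx2 <- ((xs - x0) * res$pixel_size_xy)^2
    dy2 <- ((ys - y0) * res$pixel_size_xy)^2
    dz2 <- ((zs - z0) * res$z_step)^2
    d <- sqrt(outer(outer(dy2, dx2, "+"), dz2, "+"))
    sub_b <- best[ys + 1, xs + 1, zs + 1, drop = FALSE]
    dim(sub_b) <- dim(d)
    upd <- d <= radius_um & d < sub_b
    if (any(upd)) {
      sub_l <- lab[ys + 1, xs + 1, zs + 1, drop = FALSE]
      dim(sub_l) <- dim(d)
      sub_l[upd] <- labels[k]
      sub_b[upd] <- d[upd]
      lab[ys + 1, xs + 1, zs + 1] <- sub_l
      best[ys + 1, xs + 1, zs + 1] <- sub_b
    }
  }
  lab
}
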
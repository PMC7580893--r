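#' Decompose a link graph into unbranched tracks
#'
#' A track is a maximal chain of positions connected by links without a
#' division in the middle: new tracks start at lineage roots and at division
#' daughters, and end at division mothers or track ends. Used by the Cell
#' Tracking Challenge export.
#'
#' @param exp A [tracking_experiment()].
#' @return A tibble with one row per tracked position: `track`, `t`, `i`,
#'   plus an attribute `tracks`, a tibble `track`, `begin`, `end`, `parent`
#'   (0 for founders).
#' @export
track_segments <- function(exp) {
  stopifnot(inherits(exp, "tracking_experiment"))
  forest <- build_lineage_trees(exp, include_singletons = TRUE)
  links <- exp$links
  outdeg_tbl <- dplyr::count(links, .data$t, .data$from)
  outdeg <- stats::setNames(outdeg_tbl$n, pos_key(outdeg_tbl$t, outdeg_tbl$from))
  key <- pos_key(forest$t, forest$i)
  parent_key <- pos_key(forest$parent_t, forest$parent_i)
  row_of <- stats::setNames(seq_len(nrow(forest)), key)

  # a position starts a new track if it is a root or its parent divided
  parent_out <- outdeg[parent_key]
  starts <- is.na(forest$parent_t) | (!is.na(parent_out) & parent_out == 2L)
  track_id <- rep(NA_integer_, nrow(forest))
  track_id[starts] <- seq_len(sum(starts))
  ord <- order(forest$t, forest$i)
  for (k in ord) {
    if (is.na(track_id[k])) {
      track_id[k] <- track_id[row_of[parent_key[k]]]
    }
  }
  seg <- tibble::tibble(track = track_id, t = forest$t, i = forest$i)
  spans <- dplyr::summarise(dplyr::group_by(seg, .data$track),
                            begin = min(.data$t), end = max(.data$t),
                            .groups = "drop")
  # parent track of each non-root track start
  first_rows <- which(starts & !is.na(forest$parent_t))
  par <- integer(nrow(spans))
  for (k in first_rows) {
    par[spans$track == track_id[k]] <- track_id[row_of[parent_key[k]]]
  }
  attr(seg, "tracks") <- dplyr::mutate(spans, parent = par)
  seg
}

#' Export / import tracking data in the Cell Tracking Challenge layout
#'
#' `export_ctc()` writes one 16-bit labelled TIFF stack per frame
#' (`mask%03d.tif`, spherical pseudo-masks labelled by track, see
#' [make_pseudo_masks()]) plus the standard four-column track table
#' `res_track.txt` (`label begin end parent`, space separated, parent 0 for
#' founders). `import_ctc()` reads such a directory back, taking each
#' label's per-frame centroid as the position; lineage topology round-trips
#' exactly and positions round-trip to voxel resolution.
#'
#' @param exp A [tracking_experiment()] with a lineage-consistent link graph
#'   (merges refuse to export).
#' @param out_dir Output directory (created if needed).
#' @param shape `(z, y, x)` voxel counts of the movie.
#' @param radius_um Pseudo-mask sphere radius.
#' @return `export_ctc()` returns `out_dir` invisibly; `import_ctc()` a
#'   [tracking_experiment()].
#' @export
export_ctc <- function(exp, out_dir, shape, radius_um = 5) {
  stopifnot(inherits(exp, "tracking_experiment"))
  if (nrow(exp$links)) {
    if (anyDuplicated(pos_key(exp$links$t + 1L, exp$links$to))) {
      stop("export_ctc: link graph contains a merge, refusing to export", call. = FALSE)
    }
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  seg <- track_segments(exp)
  tracks <- attr(seg, "tracks")
  lab_of <- stats::setNames(seg$track, pos_key(seg$t, seg$i))
  for (tt in seq_len(exp$n_frames) - 1L) {
    p <- dplyr::filter(exp$positions, .data$t == tt)
    labels <- unname(lab_of[pos_key(p$t, p$i)])
    vol <- make_pseudo_masks(p, exp$resolution, shape, radius_um, labels = labels)
    write_label_tiff(vol, file.path(out_dir, sprintf("mask%03d.tif", tt)))
  }
  tr <- dplyr::arrange(tracks, .data$track)
  writeLines(sprintf("%d %d %d %d", tr$track, tr$begin, tr$end, tr$parent),
             file.path(out_dir, "res_track.txt"))
  invisible(out_dir)
}

#' @rdname export_ctc
#' @param dir Directory holding `mask%03d.tif` files and `res_track.txt`.
#' @param res The [image_resolution()] of the movie (the CTC layout does not
#'   store calibration).
#' @export
import_ctc <- function(dir, res = image_resolution()) {
  table_path <- file.path(dir, "res_track.txt")
  if (!file.exists(table_path)) {
    stop("import_ctc: res_track.txt not found in ", dir, call. = FALSE)
  }
  tr <- utils::read.table(table_path,
                          col.names = c("track", "begin", "end", "parent"))
  mask_files <- sort(list.files(dir, pattern = "^mask[0-9]+\\.tif$", full.names = TRUE))
  pos_rows <- list()
  for (f in mask_files) {
    tt <- as.integer(sub("^mask([0-9]+)\\.tif$", "\\1", basename(f)))
    vol <- read_label_tiff(f)
    labs <- sort(setdiff(unique(as.integer(vol)), 0L))
    if (!length(labs)) next
    cent <- t(vapply(labs, function(L) {
      idx <- which(vol == L, arr.ind = TRUE)
      c(mean(idx[, 2]) - 1, mean(idx[, 1]) - 1, mean(idx[, 3]) - 1)  # x, y, z
    }, numeric(3)))
    pos_rows[[length(pos_rows) + 1L]] <- tibble::tibble(
      t = tt, track = labs, x = cent[, 1], y = cent[, 2], z = cent[, 3])
  }
  pos <- dplyr::bind_rows(pos_rows)
  pos <- dplyr::arrange(pos, .data$t, .data$track)
  positions <- positions_tbl(pos$t, pos$x, pos$y, pos$z)
  pos$i <- positions$i
  idx <- stats::setNames(pos$i, paste(pos$t, pos$track))

  lt <- integer(); lf <- integer(); lto <- integer()
  for (k in seq_len(nrow(tr))) {
    span <- tr$begin[k]:tr$end[k]
    if (length(span) > 1) {
      for (tt in span[-length(span)]) {
        a <- idx[paste(tt, tr$track[k])]; b <- idx[paste(tt + 1L, tr$track[k])]
        if (!is.na(a) && !is.na(b)) {
          lt <- c(lt, tt); lf <- c(lf, unname(a)); lto <- c(lto, unname(b))
        }
      }
    }
    if (tr$parent[k] > 0) {
      pend <- tr$end[tr$track == tr$parent[k]]
      if (length(pend) && tr$begin[k] == pend + 1L) {
        a <- idx[paste(pend, tr$parent[k])]; b <- idx[paste(tr$begin[k], tr$track[k])]
        if (!is.na(a) && !is.na(b)) {
          lt <- c(lt, pend); lf <- c(lf, unname(a)); lto <- c(lto, unname(b))
        }
      }
    }
  }
  tracking_experiment(res, positions, links_tbl(lt, lf, lto),
                      n_frames = if (length(mask_files))
                        max(as.integer(sub("^mask([0-9]+)\\.tif$", "\\1",
                                           basename(mask_files)))) + 1L else 0L)
}

# 16-bit label TIFF helpers (labels stored as value/65535)
write_label_tiff <- function(vol, path) {
  if (max(vol) > 65535L) stop("write_label_tiff: more than 65535 labels", call. = FALSE)
  pages <- lapply(seq_len(dim(vol)[3]), function(z) vol[, , z] / 65535)
  tiff::writeTIFF(pages, path, bits.per.sample = 16L, compression = "none")
  invisible(path)
}

read_label_tiff <- function(path) {
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  vol <- array(0L, dim = c(nrow(pages[[1]]), ncol(pages[[1]]), length(pages)))
  for (z in seq_along(pages)) vol[, , z] <- as.integer(round(pages[[z]] * 65535))
  vol
}

#' Write / read a synthetic movie as a multi-page TIFF series
#'
#' One 16-bit grayscale multi-page TIFF per time point (`pattern` with the
#' frame index, default `t%03d.tif`), intensities scaled from `[0, 1]`.
#'
#' @param frames List of 3D arrays `(ny, nx, nz)` with values in `[0, 1]`.
#' @param dir Directory.
#' @param pattern `sprintf` pattern with one integer slot.
#' @return `write_movie_tiffs()` the file paths invisibly;
#'   `read_movie_tiffs()` a list of arrays.
#' @export
write_movie_tiffs <- function(frames, dir, pattern = "t%03d.tif") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(length(frames))
  for (k in seq_along(frames)) {
    vol <- pmin(pmax(frames[[k]], 0), 1)
    pages <- lapply(seq_len(dim(vol)[3]), function(z) vol[, , z])
    paths[k] <- file.path(dir, sprintf(pattern, k - 1L))
    tiff::writeTIFF(pages, paths[k], bits.per.sample = 16L, compression = "none")
  }
  invisible(paths)
}

#' @rdname write_movie_tiffs
#' @param paths Explicit file paths (alternative to `dir` + `pattern`).
#' @export
read_movie_tiffs <- function(dir = NULL, pattern = "t%03d.tif", paths = NULL) {
  if (is.null(paths)) {
    rx <- utils::glob2rx(gsub("%0?[0-9]*d", "*", pattern))
    paths <- sort(list.files(dir, pattern = rx, full.names = TRUE))
  }
  lapply(paths, function(p) {
    pages <- tiff::readTIFF(p, all = TRUE)
    if (!is.list(pages)) pages <- list(pages)
    vol <- array(0, dim = c(nrow(pages[[1]]), ncol(pages[[1]]), length(pages)))
    for (z in seq_along(pages)) vol[, , z] <- pages[[z]]
    vol
  })
}
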
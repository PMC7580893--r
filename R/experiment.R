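#' A tracking experiment: detections, links, shapes and warnings
#'
#' The unit of data the whole pipeline reads and writes. It bundles the movie
#' calibration, the per-frame nucleus detections, the frame-to-frame links
#' (divisions are positions with two outgoing links), optional fitted Gaussian
#' shapes and curation warnings.
#'
#' @param resolution An [image_resolution()].
#' @param positions A positions tibble ([positions_tbl()]).
#' @param links A links tibble ([links_tbl()]); every endpoint must exist in
#'   `positions`.
#' @param shapes Optional shapes tibble ([shapes_tbl()]); may only reference
#'   existing positions.
#' @param warnings Optional warnings tibble (columns `t`, `i`, `rule_id`,
#'   `message`, `suppressed`).
#' @param n_frames Number of frames in the movie; defaults to `max(t) + 1`.
#'   Needed so track-end exemptions at the final frame survive empty frames.
#' @return An object of class `tracking_experiment`.
#' @examples
#' pos <- positions_tbl(t = c(0, 1), x = c(10, 11), y = c(10, 10), z = c(3, 3))
#' exp <- tracking_experiment(image_resolution(), pos, links_tbl(0, 1, 1))
#' exp
#' @export
tracking_experiment <- function(resolution, positions,
                                links = links_tbl(), shapes = NULL,
                                warnings = NULL, n_frames = NULL) {
  stopifnot(is_resolution(resolution))
  check_positions(positions)
  check_links(links)
  if (is.null(warnings)) warnings <- warnings_tbl()
  if (is.null(n_frames)) {
    n_frames <- if (nrow(positions)) max(positions$t) + 1L else 0L
  }
  exp <- structure(
    list(resolution = resolution,
         positions = tibble::as_tibble(positions),
         links = tibble::as_tibble(links),
         shapes = if (!is.null(shapes)) tibble::as_tibble(shapes) else NULL,
         warnings = tibble::as_tibble(warnings),
         n_frames = as.integer(n_frames)),
    class = "tracking_experiment"
  )
  validate_experiment(exp)
  exp
}

#' @export
print.tracking_experiment <- function(x, ...) {
  nd <- n_divisions(x)
  cat(sprintf("<tracking_experiment> %d frames, %d positions, %d links, %d divisions",
              x$n_frames, nrow(x$positions), nrow(x$links), nd))
  if (!is.null(x$shapes)) cat(sprintf(", %d shapes", nrow(x$shapes)))
  if (nrow(x$warnings)) cat(sprintf(", %d warnings", nrow(x$warnings)))
  cat("\n")
  invisible(x)
}

warnings_tbl <- function(t = integer(), i = integer(), rule_id = integer(),
                         message = character(), suppressed = logical()) {
  tibble::tibble(t = as.integer(t), i = as.integer(i),
                 rule_id = as.integer(rule_id),
                 message = as.character(message),
                 suppressed = as.logical(suppressed))
}

# keys "t.i" used to test membership of (t, i) references in a position set
pos_key <- function(t, i) paste(t, i, sep = ".")

validate_experiment <- function(exp) {
  pk <- pos_key(exp$positions$t, exp$positions$i)
  if (anyDuplicated(pk)) stop("tracking_experiment: duplicated (t, i) position", call. = FALSE)
  lk <- exp$links
  if (nrow(lk)) {
    bad <- !(pos_key(lk$t, lk$from) %in% pk) | !(pos_key(lk$t + 1L, lk$to) %in% pk)
    if (any(bad)) {
      stop(sprintf("tracking_experiment: %d link endpoint(s) missing from positions", sum(bad)),
           call. = FALSE)
    }
  }
  if (!is.null(exp$shapes) && nrow(exp$shapes)) {
    if (!all(pos_key(exp$shapes$t, exp$shapes$i) %in% pk)) {
      stop("tracking_experiment: shapes reference unknown positions", call. = FALSE)
    }
  }
  if (nrow(exp$positions) && max(exp$positions$t) + 1L > exp$n_frames) {
    stop("tracking_experiment: positions outside the movie frame range", call. = FALSE)
  }
  invisible(exp)
}

#' Number of cell divisions in an experiment
#'
#' A division is a position with two outgoing links.
#' @param exp A [tracking_experiment()].
#' @return Integer count.
#' @export
n_divisions <- function(exp) {
  stopifnot(inherits(exp, "tracking_experiment"))
  if (!nrow(exp$links)) return(0L)
  deg <- dplyr::count(exp$links, .data$t, .data$from)
  sum(deg$n == 2L)
}

#' Save and load tracking experiments as JSON
#'
#' The on-disk schema is versioned (`format_version` 1) and uses compact
#' arrays: per-frame positions as `[x, y, z]` triples keyed by frame index,
#' links as `[t, index_t, index_t1]` triples with 0-based indices into the
#' frame arrays, shapes as 13-value rows and warnings as 5-value rows.
#' Coordinates are written at full IEEE precision so `load_json(save_json(x))`
#' is bit-identical.
#'
#' @param exp A [tracking_experiment()].
#' @param path File path to write to / read from.
#' @return `save_json()` returns `path` invisibly; `load_json()` returns a
#'   [tracking_experiment()].
#' @export
save_json <- function(exp, path) {
  stopifnot(inherits(exp, "tracking_experiment"))
  frames <- sort(unique(exp$positions$t))
  # within-frame indices `i` may be non-contiguous after manual edits; the
  # JSON stores 0-based ranks into each frame's array instead
  ranked <- dplyr::mutate(
    dplyr::group_by(dplyr::arrange(exp$positions, .data$t, .data$i), .data$t),
    rank0 = dplyr::row_number() - 1L)
  ranked <- dplyr::ungroup(ranked)
  rank_of <- stats::setNames(ranked$rank0, pos_key(ranked$t, ranked$i))
  pos_list <- stats::setNames(
    lapply(frames, function(tt) {
      p <- ranked[ranked$t == tt, ]
      unname(lapply(seq_len(nrow(p)), function(k) c(p$x[k], p$y[k], p$z[k])))
    }),
    as.character(frames)
  )
  obj <- list(
    format_version = 1L,
    resolution = list(pixel_size_xy = exp$resolution$pixel_size_xy,
                      z_step = exp$resolution$z_step,
                      time_step = exp$resolution$time_step),
    n_frames = exp$n_frames,
    positions = pos_list,
    links = unname(lapply(seq_len(nrow(exp$links)), function(k)
      c(exp$links$t[k],
        unname(rank_of[pos_key(exp$links$t[k], exp$links$from[k])]),
        unname(rank_of[pos_key(exp$links$t[k] + 1L, exp$links$to[k])])))),
    shapes = if (is.null(exp$shapes)) NULL else
      unname(lapply(seq_len(nrow(exp$shapes)), function(k) {
        s <- exp$shapes[k, ]
        list(s$t, unname(rank_of[pos_key(s$t, s$i)]), s$a, s$mx, s$my, s$mz,
             s$cxx, s$cyy, s$czz, s$cxy, s$cxz, s$cyz, s$unreliable)
      })),
    warnings = unname(lapply(seq_len(nrow(exp$warnings)), function(k) {
      w <- exp$warnings[k, ]
      list(w$t, unname(rank_of[pos_key(w$t, w$i)]), w$rule_id, w$message, w$suppressed)
    }))
  )
  obj <- obj[!vapply(obj, is.null, logical(1))]
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = I(17), null = "null")
  invisible(path)
}

#' @rdname save_json
#' @export
load_json <- function(path) {
  force(path)
  obj <- tryCatch(jsonlite::read_json(path),
                  error = function(e) stop("load_json: malformed JSON: ",
                                           conditionMessage(e), call. = FALSE))
  for (key in c("format_version", "resolution", "positions")) {
    if (is.null(obj[[key]])) {
      stop(sprintf("load_json: required key \"%s\" missing", key), call. = FALSE)
    }
  }
  if (!identical(as.integer(obj$format_version), 1L)) {
    stop(sprintf("load_json: unsupported \"format_version\" %s", obj$format_version),
         call. = FALSE)
  }
  r <- obj$resolution
  for (key in c("pixel_size_xy", "z_step", "time_step")) {
    if (is.null(r[[key]])) {
      stop(sprintf("load_json: required key \"resolution.%s\" missing", key), call. = FALSE)
    }
  }
  res <- image_resolution(r$pixel_size_xy, r$z_step, r$time_step)

  frames <- as.integer(names(obj$positions))
  empty_pos <- tibble::tibble(t = integer(), x = numeric(),
                              y = numeric(), z = numeric())
  pos <- purrr::map2_dfr(obj$positions, frames, function(rows, tt) {
    if (!length(rows)) return(empty_pos)
    m <- do.call(rbind, lapply(rows, function(p) as.numeric(unlist(p))))
    tibble::tibble(t = tt, x = m[, 1], y = m[, 2], z = m[, 3])
  })
  if (!nrow(pos)) pos <- empty_pos
  positions <- positions_tbl(pos$t, pos$x, pos$y, pos$z)

  links <- links_tbl()
  if (length(obj$links)) {
    m <- do.call(rbind, lapply(obj$links, function(l) as.numeric(unlist(l))))
    links <- links_tbl(m[, 1], m[, 2] + 1L, m[, 3] + 1L)
  }
  shapes <- NULL
  if (!is.null(obj$shapes)) {
    if (length(obj$shapes)) {
      m <- do.call(rbind, lapply(obj$shapes, function(s) {
        c(as.numeric(unlist(s[1:12])), as.numeric(as.logical(s[[13]])))
      }))
      shapes <- shapes_tbl(m[, 1], m[, 2] + 1L, m[, 3], m[, 4], m[, 5], m[, 6],
                           m[, 7], m[, 8], m[, 9], m[, 10], m[, 11], m[, 12],
                           as.logical(m[, 13]))
    } else {
      shapes <- shapes_tbl()
    }
  }
  warns <- warnings_tbl()
  if (length(obj$warnings)) {
    warns <- purrr::map_dfr(obj$warnings, function(w) {
      warnings_tbl(as.integer(w[[1]]), as.integer(w[[2]]) + 1L,
                   as.integer(w[[3]]), as.character(w[[4]]), as.logical(w[[5]]))
    })
  }
  n_frames <- if (!is.null(obj$n_frames)) as.integer(obj$n_frames) else NULL
  tracking_experiment(res, positions, links, shapes, warns, n_frames = n_frames)
}
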
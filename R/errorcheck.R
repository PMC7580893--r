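#' Thresholds of the tracking error checker
#'
#' @param min_hours_between_divisions Minimum time between two divisions on
#'   the same lineage branch, hours.
#' @param max_movement_um Maximum plausible movement between two consecutive
#'   frames, micrometers.
#' @param max_volume_shrink_factor Maximum plausible frame-to-frame shrink of
#'   the volume proxy.
#' @return An `error_thresholds` object.
#' @export
error_thresholds <- function(min_hours_between_divisions = 10,
                             max_movement_um = 10,
                             max_volume_shrink_factor = 3) {
  stopifnot(min_hours_between_divisions > 0, max_movement_um > 0,
            max_volume_shrink_factor > 0)
  structure(list(min_hours_between_divisions = min_hours_between_divisions,
                 max_movement_um = max_movement_um,
                 max_volume_shrink_factor = max_volume_shrink_factor),
            class = "error_thresholds")
}

#' Flag improbable tracking events
#'
#' Checks the six curation rules and returns one warning per violation:
#' \enumerate{
#'   \item every nucleus must have a link to the previous and to the next
#'     frame (cells appearing from or disappearing into nothing; exempt at
#'     the first/last frame of the movie);
#'   \item at least `min_hours_between_divisions` must pass before a cell on
#'     the same lineage branch divides again (identity switches);
#'   \item no movement larger than `max_movement_um` between two frames;
#'   \item a dividing nucleus must be larger than its daughters combined
#'     (misdetected divisions; needs shapes);
#'   \item the volume proxy may not shrink more than
#'     `max_volume_shrink_factor`-fold along a link (identity switches and
#'     missed divisions; needs shapes);
#'   \item no merges and no more than two daughters (cannot arise from the
#'     solver, but manual edits can produce them).
#' }
#' Warnings previously suppressed in `exp$warnings` (same position and rule)
#' stay suppressed. When shapes are absent rules 4 and 5 are skipped with a
#' notice.
#'
#' @param exp A [tracking_experiment()].
#' @param th An [error_thresholds()].
#' @param quiet Suppress the missing-shapes notice.
#' @return A warnings tibble (`t`, `i`, `rule_id`, `message`, `suppressed`).
#' @export
check_experiment <- function(exp, th = error_thresholds(), quiet = FALSE) {
  stopifnot(inherits(exp, "tracking_experiment"), inherits(th, "error_thresholds"))
  pos <- exp$positions
  links <- exp$links
  res <- exp$resolution
  out <- list()
  warn <- function(t, i, rule, msg) {
    out[[length(out) + 1L]] <<- warnings_tbl(t, i, rule, msg, FALSE)
  }
  t_last <- exp$n_frames - 1L

  has_out <- pos_key(pos$t, pos$i) %in% pos_key(links$t, links$from)
  has_in <- pos_key(pos$t, pos$i) %in% pos_key(links$t + 1L, links$to)

  # rule 1: track starts / ends away from the movie boundary
  for (k in which(!has_in & pos$t > 0L)) {
    warn(pos$t[k], pos$i[k], 1L, "cell appears without a link to the previous time point")
  }
  for (k in which(!has_out & pos$t < t_last)) {
    warn(pos$t[k], pos$i[k], 1L, "cell disappears without a link to the next time point")
  }

  if (nrow(links)) {
    key <- pos_key(pos$t, pos$i)
    px <- stats::setNames(pos$x, key); py <- stats::setNames(pos$y, key)
    pz <- stats::setNames(pos$z, key)
    fk <- pos_key(links$t, links$from); tk <- pos_key(links$t + 1L, links$to)
    dx <- (px[fk] - px[tk]) * res$pixel_size_xy
    dy <- (py[fk] - py[tk]) * res$pixel_size_xy
    dz <- (pz[fk] - pz[tk]) * res$z_step
    move <- sqrt(dx^2 + dy^2 + dz^2)
    # rule 3: implausible movement
    for (k in which(move > th$max_movement_um)) {
      warn(links$t[k] + 1L, links$to[k], 3L,
           sprintf("cell moved %.1f um in one time step (max %.1f)",
                   move[k], th$max_movement_um))
    }

    outdeg <- dplyr::count(links, .data$t, .data$from)
    indeg <- dplyr::count(links, .data$t, .data$to)
    # rule 6: merges and more-than-two daughters
    for (k in which(indeg$n > 1L)) {
      warn(indeg$t[k] + 1L, indeg$to[k], 6L, "two cells merge into this cell")
    }
    for (k in which(outdeg$n > 2L)) {
      warn(outdeg$t[k], outdeg$from[k], 6L,
           sprintf("cell has %d daughters (max 2)", outdeg$n[k]))
    }

    # rule 2: divisions too close together on one lineage branch
    mothers <- outdeg[outdeg$n == 2L, c("t", "from")]
    if (nrow(mothers) > 1L) {
      parent_of <- stats::setNames(fk, tk)  # child key -> parent key
      is_mother <- stats::setNames(rep(TRUE, nrow(mothers)),
                                   pos_key(mothers$t, mothers$from))
      tvec <- stats::setNames(pos$t, key)
      for (k in seq_len(nrow(mothers))) {
        mk <- pos_key(mothers$t[k], mothers$from[k])
        cur <- parent_of[mk]
        while (!is.na(cur)) {
          if (isTRUE(is_mother[cur])) {
            dt_h <- frames_to_hours(mothers$t[k] - tvec[cur], res)
            if (dt_h < th$min_hours_between_divisions) {
              warn(mothers$t[k], mothers$from[k], 2L,
                   sprintf("cell divides again after %.1f h (min %.1f)",
                           dt_h, th$min_hours_between_divisions))
            }
            break
          }
          cur <- parent_of[cur]
        }
      }
    }

    # rules 4 and 5 need volume proxies
    if (!is.null(exp$shapes) && nrow(exp$shapes)) {
      vol <- stats::setNames(volume_proxy(exp$shapes),
                             pos_key(exp$shapes$t, exp$shapes$i))
      # rule 5: per-link shrink
      vfrom <- vol[fk]; vto <- vol[tk]
      shrink <- vfrom / vto
      for (k in which(is.finite(shrink) & shrink > th$max_volume_shrink_factor)) {
        warn(links$t[k] + 1L, links$to[k], 5L,
             sprintf("nucleus volume shrank %.1f-fold along a link (max %.1f)",
                     shrink[k], th$max_volume_shrink_factor))
      }
      # rule 4: mother must exceed daughters combined
      mothers <- outdeg[outdeg$n == 2L, c("t", "from")]
      for (k in seq_len(nrow(mothers))) {
        dl <- links[links$t == mothers$t[k] & links$from == mothers$from[k], ]
        vm <- vol[pos_key(mothers$t[k], mothers$from[k])]
        vd <- sum(vol[pos_key(dl$t + 1L, dl$to)])
        if (is.finite(vm) && is.finite(vd) && vm <= vd) {
          warn(mothers$t[k], mothers$from[k], 4L,
               "dividing nucleus is not larger than its daughters combined")
        }
      }
    } else if (!quiet) {
      message("check_experiment: no shapes available, skipping volume rules 4-5")
    }
  }

  warnings <- if (length(out)) dplyr::bind_rows(out) else warnings_tbl()
  warnings <- dplyr::arrange(warnings, .data$t, .data$i, .data$rule_id)
  # carry over suppression decisions
  if (nrow(exp$warnings) && nrow(warnings)) {
    sup <- exp$warnings[exp$warnings$suppressed, c("t", "i", "rule_id")]
    if (nrow(sup)) {
      mk <- paste(warnings$t, warnings$i, warnings$rule_id)
      warnings$suppressed <- mk %in% paste(sup$t, sup$i, sup$rule_id)
    }
  }
  warnings
}

edit_neighborhood <- function(exp, edited) {
  keys <- pos_key(edited$t, edited$i)
  lk <- exp$links
  nb <- rbind(edited[, c("t", "i")],
              stats::setNames(lk[pos_key(lk$t + 1L, lk$to) %in% keys, c("t", "from")],
                              c("t", "i")),
              dplyr::tibble(t = lk$t[pos_key(lk$t, lk$from) %in% keys] + 1L,
                            i = lk$to[pos_key(lk$t, lk$from) %in% keys]))
  unique(nb)
}

#' Re-check warnings around edited positions
#'
#' After a manual edit, warnings are recomputed for the edited positions and
#' their link neighbours only; the result equals a full [check_experiment()]
#' restricted to that neighbourhood, so interactive edits get immediate
#' feedback without re-checking the whole movie.
#'
#' @param exp The edited [tracking_experiment()].
#' @param edited Tibble with columns `t`, `i`: the edited positions (for a
#'   deletion, pass the former link neighbours). Every entry must exist.
#' @param th An [error_thresholds()].
#' @return A list: `warnings` (neighbourhood warnings after the edit),
#'   `added` and `removed` (deltas against `exp$warnings` in that
#'   neighbourhood).
#' @export
recheck_after_edit <- function(exp, edited, th = error_thresholds()) {
  stopifnot(inherits(exp, "tracking_experiment"), is.data.frame(edited))
  pk <- pos_key(exp$positions$t, exp$positions$i)
  missing <- !(pos_key(edited$t, edited$i) %in% pk)
  if (any(missing)) {
    stop(sprintf("recheck_after_edit: edited position (t=%d, i=%d) not found",
                 edited$t[which(missing)[1]], edited$i[which(missing)[1]]),
         call. = FALSE)
  }
  nb <- edit_neighborhood(exp, edited)
  nbk <- pos_key(nb$t, nb$i)
  full <- check_experiment(exp, th, quiet = TRUE)
  new_w <- full[pos_key(full$t, full$i) %in% nbk, ]
  old_w <- exp$warnings[pos_key(exp$warnings$t, exp$warnings$i) %in% nbk, ]
  wkey <- function(w) paste(w$t, w$i, w$rule_id)
  list(warnings = new_w,
       added = new_w[!(wkey(new_w) %in% wkey(old_w)), ],
       removed = old_w[!(wkey(old_w) %in% wkey(new_w)), ])
}

#' Manual editing operations
#'
#' Small API equivalents of interactive curation edits: move, add or delete
#' a position, add or remove a link, or suppress a warning. Each returns the
#' modified experiment; warnings are not recomputed automatically (use
#' [recheck_after_edit()] or [check_experiment()]).
#'
#' @param exp A [tracking_experiment()].
#' @param t,i Position identifiers.
#' @param x,y,z New / initial coordinates.
#' @param from,to Link endpoints (within-frame indices).
#' @param rule_id Rule of the warning to suppress.
#' @return The modified experiment.
#' @name editing
NULL

#' @rdname editing
#' @export
move_position <- function(exp, t, i, x, y, z) {
  hit <- exp$positions$t == t & exp$positions$i == i
  if (!any(hit)) stop("move_position: position not found", call. = FALSE)
  exp$positions$x[hit] <- x; exp$positions$y[hit] <- y; exp$positions$z[hit] <- z
  exp
}

#' @rdname editing
#' @export
add_position <- function(exp, t, x, y, z) {
  old <- exp$positions$i[exp$positions$t == t]
  i <- if (length(old)) max(old) + 1L else 1L
  exp$positions <- dplyr::bind_rows(
    exp$positions, tibble::tibble(t = as.integer(t), i = i, x = x, y = y, z = z))
  exp$n_frames <- max(exp$n_frames, as.integer(t) + 1L)
  validate_experiment(exp)
  exp
}

#' @rdname editing
#' @export
delete_position <- function(exp, t, i) {
  hit <- exp$positions$t == t & exp$positions$i == i
  if (!any(hit)) stop("delete_position: position not found", call. = FALSE)
  exp$positions <- exp$positions[!hit, ]
  drop <- (exp$links$t == t & exp$links$from == i) |
    (exp$links$t + 1L == t & exp$links$to == i)
  exp$links <- exp$links[!drop, ]
  if (!is.null(exp$shapes)) {
    exp$shapes <- exp$shapes[!(exp$shapes$t == t & exp$shapes$i == i), ]
  }
  exp$warnings <- exp$warnings[!(exp$warnings$t == t & exp$warnings$i == i), ]
  exp
}

#' @rdname editing
#' @export
add_link <- function(exp, t, from, to) {
  exp$links <- dplyr::bind_rows(exp$links, links_tbl(t, from, to))
  validate_experiment(exp)
  exp
}

#' @rdname editing
#' @export
remove_link <- function(exp, t, from, to) {
  hit <- exp$links$t == t & exp$links$from == from & exp$links$to == to
  if (!any(hit)) stop("remove_link: link not found", call. = FALSE)
  exp$links <- exp$links[!hit, ]
  exp
}

#' @rdname editing
#' @export
suppress_warning <- function(exp, t, i, rule_id) {
  hit <- exp$warnings$t == t & exp$warnings$i == i & exp$warnings$rule_id == rule_id
  if (!any(hit)) stop("suppress_warning: warning not found", call. = FALSE)
  exp$warnings$suppressed[hit] <- TRUE
  exp
}
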
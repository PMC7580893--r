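#' Weights of the link scoring system
#'
#' Multiplicative factors for the five cost rules of the global linking
#' objective: ordinary links (`w_link`, applied to the movement-plus-volume
#' score), track ends (`w_end`), track starts (`w_start`), ignored positions
#' (`w_ignore`) and divisions (`w_division`). Defaults are 20, 100, 150, 150
#' and 30. High start/end penalties relative to the ignore penalty suppress
#' the many short spurious tracks that dead-cell debris would otherwise
#' create.
#'
#' @param w_link,w_end,w_start,w_ignore,w_division Non-negative factors.
#' @return A `link_weights` object.
#' @export
link_weights <- function(w_link = 20, w_end = 100, w_start = 150,
                         w_ignore = 150, w_division = 30) {
  w <- c(w_link = w_link, w_end = w_end, w_start = w_start,
         w_ignore = w_ignore, w_division = w_division)
  stopifnot(all(is.finite(w)), all(w >= 0))
  structure(as.list(w), class = "link_weights")
}

#' Nearest-neighbour baseline linking
#'
#' Links every position at frame `t + 1` to its nearest position (in um) at
#' frame `t`. Two positions sharing a nearest parent yield a division "for
#' free" -- but nothing prevents three or more daughters, which is one reason
#' this baseline produces unrealistic lineages on dense data.
#'
#' @param positions A positions tibble.
#' @param res An [image_resolution()].
#' @return A links tibble.
#' @export
nearest_neighbor_link <- function(positions, res) {
  check_positions(positions)
  stopifnot(is_resolution(res))
  frames <- sort(unique(positions$t))
  out <- list()
  for (tt in frames[-length(frames)]) {
    a <- dplyr::filter(positions, .data$t == tt)
    b <- dplyr::filter(positions, .data$t == tt + 1L)
    if (!nrow(a) || !nrow(b)) next
    dm <- position_dist_um(a, b, res)
    nn <- apply(dm, 2L, which.min)
    out[[length(out) + 1L]] <- links_tbl(rep(tt, nrow(b)), a$i[nn], b$i)
  }
  if (!length(out)) return(links_tbl())
  dplyr::bind_rows(out)
}

#' Generate candidate links between consecutive frames
#'
#' For every position, looking both backward and forward, all positions in
#' the adjacent frame at most `factor` times further away than its nearest
#' neighbour become candidates; the union over both directions is returned.
#' With `factor = 1` only nearest neighbours (in either direction) survive.
#'
#' @param positions A positions tibble.
#' @param res An [image_resolution()].
#' @param factor Cutoff multiple of the nearest-neighbour distance (>= 1).
#' @return A tibble of candidates: `t`, `from`, `to`, `dx_um`.
#' @export
generate_candidates <- function(positions, res, factor = 2) {
  check_positions(positions)
  stopifnot(factor >= 1)
  frames <- sort(unique(positions$t))
  out <- list()
  for (tt in frames[-length(frames)]) {
    a <- dplyr::filter(positions, .data$t == tt)
    b <- dplyr::filter(positions, .data$t == tt + 1L)
    if (!nrow(a) || !nrow(b)) next
    dm <- position_dist_um(a, b, res)
    fw <- dm <= factor * apply(dm, 1L, min)          # per source
    bw <- t(t(dm) <= factor * apply(dm, 2L, min))    # per target
    keep <- which(fw | bw, arr.ind = TRUE)
    out[[length(out) + 1L]] <- tibble::tibble(
      t = tt, from = a$i[keep[, 1]], to = b$i[keep[, 2]],
      dx_um = dm[keep])
  }
  if (!length(out)) {
    return(tibble::tibble(t = integer(), from = integer(), to = integer(),
                          dx_um = numeric()))
  }
  dplyr::arrange(dplyr::bind_rows(out), .data$t, .data$from, .data$to)
}

#' Cost of one candidate link
#'
#' The movement-plus-volume score `w_link * (dX + dV / 3)`, halved when a
#' division is allowed at the source (around a division nuclei move fast and
#' change volume, so those changes are penalised less).
#'
#' @param dx_um Positional change in um.
#' @param dv Volume-proxy change (absolute difference).
#' @param w A [link_weights()].
#' @param division_allowed Halve the score (default `FALSE`).
#' @return Scalar cost.
#' @examples
#' link_cost(3, 6, link_weights())         # (3 + 2) * 20 = 100
#' link_cost(3, 6, link_weights(), TRUE)   # 50
#' @export
link_cost <- function(dx_um, dv = 0, w = link_weights(), division_allowed = FALSE) {
  base <- w$w_link * (dx_um + dv / 3)
  ifelse(division_allowed, base / 2, base)
}

#' Score a putative division from volume and intensity changes
#'
#' A mother splitting in two should be roughly as voluminous as both
#' daughters combined and roughly as bright as each daughter. The score
#' averages the two ratios, \eqn{s = \frac12 \frac{2 V_m}{V_{d1} + V_{d2}} +
#' \frac12 \frac{2 I_m}{I_{d1} + I_{d2}}}; a score below 1 marks the division
#' as unlikely, and divisions are only permitted where `s >= 1`. When volume
#' proxies are missing (failed fits) the score falls back to the intensity
#' ratio alone; zero denominators are capped at a large finite value.
#'
#' @param v_mother,v_d1,v_d2 Volume proxies (may be `NA`).
#' @param i_mother,i_d1,i_d2 Peak intensities (may be `NA`).
#' @return Scalar score `s`.
#' @examples
#' division_score(2, 1, 1, 1, 1, 1)  # volume ratio 1, intensity ratio 1 -> 1
#' @export
division_score <- function(v_mother, v_d1, v_d2, i_mother, i_d1, i_d2) {
  cap <- 1e6
  ratio <- function(num, den) {
    if (!is.finite(num) || !is.finite(den)) return(NA_real_)
    if (den <= 0) return(cap)
    min(num / den, cap)
  }
  rv <- ratio(2 * v_mother, v_d1 + v_d2)
  ri <- ratio(2 * i_mother, i_d1 + i_d2)
  if (is.na(rv) && is.na(ri)) return(1)  # no evidence either way
  if (is.na(rv)) return(ri)
  if (is.na(ri)) return(rv)
  0.5 * rv + 0.5 * ri
}

#' Assemble a link problem
#'
#' Bundles per-frame positions (with volume proxies and intensities where
#' shapes are available), candidate links with their base costs, gated
#' division-candidate pairs and the weights, ready for [solve_links()] or
#' [brute_force_link()].
#'
#' @param exp A [tracking_experiment()] (its `shapes`, when present, provide
#'   volume proxies and intensities), or a positions tibble.
#' @param weights A [link_weights()].
#' @param factor Candidate cutoff factor (see [generate_candidates()]).
#' @param res Resolution; defaults to `exp$resolution` when `exp` is an
#'   experiment.
#' @param t_first,t_last First and last frame of the movie (tracks starting
#'   at `t_first` pay no start penalty, tracks ending at `t_last` no end
#'   penalty). Default: the experiment's frame range, or the range of the
#'   given positions.
#' @return A `link_problem` object.
#' @export
link_problem <- function(exp, weights = link_weights(), factor = 2, res = NULL,
                         t_first = NULL, t_last = NULL) {
  if (inherits(exp, "tracking_experiment")) {
    positions <- exp$positions
    shapes <- exp$shapes
    if (is.null(res)) res <- exp$resolution
    if (is.null(t_first)) t_first <- 0L
    if (is.null(t_last)) t_last <- exp$n_frames - 1L
  } else {
    positions <- exp
    shapes <- NULL
    if (is.null(res)) stop("link_problem: res required with bare positions", call. = FALSE)
  }
  check_positions(positions)
  positions <- dplyr::arrange(positions, .data$t, .data$i)
  if (!is.null(shapes) && nrow(shapes)) {
    sh <- dplyr::mutate(shapes, volume = volume_proxy(shapes))
    positions <- dplyr::left_join(
      positions, dplyr::select(sh, "t", "i", "volume", intensity = "a"),
      by = c("t", "i"))
  } else {
    positions$volume <- NA_real_
    positions$intensity <- NA_real_
  }
  cand <- generate_candidates(positions, res, factor)
  key <- pos_key(positions$t, positions$i)
  vol <- stats::setNames(positions$volume, key)
  inten <- stats::setNames(positions$intensity, key)
  dv <- abs(vol[pos_key(cand$t, cand$from)] - vol[pos_key(cand$t + 1L, cand$to)])
  dv[is.na(dv)] <- 0  # missing volume proxies contribute no volume term
  cand$cost <- link_cost(cand$dx_um, dv, weights)

  # division candidates: unordered target pairs among links sharing a source,
  # gated at score >= 1
  pairs <- list()
  if (nrow(cand)) {
    grp <- split(seq_len(nrow(cand)), paste(cand$t, cand$from))
    for (g in grp) {
      if (length(g) < 2) next
      cmb <- utils::combn(g, 2)
      for (k in seq_len(ncol(cmb))) {
        l1 <- cmb[1, k]; l2 <- cmb[2, k]
        if (cand$to[l1] == cand$to[l2]) next
        mk <- pos_key(cand$t[l1], cand$from[l1])
        d1 <- pos_key(cand$t[l1] + 1L, cand$to[l1])
        d2 <- pos_key(cand$t[l2] + 1L, cand$to[l2])
        s <- division_score(vol[mk], vol[d1], vol[d2],
                            inten[mk], inten[d1], inten[d2])
        if (s >= 1) {
          pairs[[length(pairs) + 1L]] <- tibble::tibble(
            t = cand$t[l1], from = cand$from[l1],
            to1 = min(cand$to[l1], cand$to[l2]),
            to2 = max(cand$to[l1], cand$to[l2]), s = s)
        }
      }
    }
  }
  pairs <- if (length(pairs)) dplyr::bind_rows(pairs) else
    tibble::tibble(t = integer(), from = integer(), to1 = integer(),
                   to2 = integer(), s = numeric())
  if (is.null(t_first)) t_first <- if (nrow(positions)) min(positions$t) else 0L
  if (is.null(t_last)) t_last <- if (nrow(positions)) max(positions$t) else 0L
  structure(list(positions = positions, candidates = cand, pairs = pairs,
                 weights = weights, res = res,
                 t_first = as.integer(t_first), t_last = as.integer(t_last)),
            class = "link_problem")
}

#' @export
print.link_problem <- function(x, ...) {
  cat(sprintf("<link_problem> %d positions, %d candidate links, %d gated division pairs\n",
              nrow(x$positions), nrow(x$candidates), nrow(x$pairs)))
  invisible(x)
}

#' Objective value of a link selection under a problem's cost model
#'
#' Computes the canonical objective: selected link costs (halved at realized
#' divisions), minus the division reward `w_division * (s - 1)` per realized
#' division, plus start/end penalties for non-boundary track starts/ends and
#' the cheaper of ignoring or keeping each unlinked position. Infeasible
#' selections (merges, out-degree > 2, ungated divisions) return `Inf`.
#'
#' @param problem A [link_problem()].
#' @param links A links tibble (a subset of the problem's candidates).
#' @return Scalar objective (Inf if infeasible).
#' @export
solution_objective <- function(problem, links) {
  stopifnot(inherits(problem, "link_problem"))
  check_links(links)
  w <- problem$weights
  pos <- problem$positions
  if (nrow(links)) {
    ck <- paste(problem$candidates$t, problem$candidates$from, problem$candidates$to)
    lk <- paste(links$t, links$from, links$to)
    if (anyDuplicated(lk) || !all(lk %in% ck)) return(Inf)
    if (anyDuplicated(paste(links$t + 1L, links$to))) return(Inf)  # merge
    outdeg <- dplyr::count(links, .data$t, .data$from)
    if (any(outdeg$n > 2L)) return(Inf)
  }
  cost <- 0
  div_key <- character()
  if (nrow(links)) {
    outdeg <- dplyr::count(links, .data$t, .data$from)
    mothers <- outdeg[outdeg$n == 2L, ]
    pk <- paste(problem$pairs$t, problem$pairs$from, problem$pairs$to1, problem$pairs$to2)
    for (k in seq_len(nrow(mothers))) {
      dl <- links[links$t == mothers$t[k] & links$from == mothers$from[k], ]
      key <- paste(mothers$t[k], mothers$from[k], min(dl$to), max(dl$to))
      hit <- match(key, pk)
      if (is.na(hit)) return(Inf)  # ungated division
      cost <- cost - w$w_division * (problem$pairs$s[hit] - 1)
      div_key <- c(div_key, paste(mothers$t[k], mothers$from[k]))
    }
    ci <- match(paste(links$t, links$from, links$to),
                paste(problem$candidates$t, problem$candidates$from, problem$candidates$to))
    base <- problem$candidates$cost[ci]
    halve <- paste(links$t, links$from) %in% div_key
    cost <- cost + sum(ifelse(halve, base / 2, base))
  }
  has_out <- pos_key(pos$t, pos$i) %in% pos_key(links$t, links$from)
  has_in <- pos_key(pos$t, pos$i) %in% pos_key(links$t + 1L, links$to)
  for (k in seq_len(nrow(pos))) {
    sp <- if (pos$t[k] > problem$t_first) w$w_start else 0
    ep <- if (pos$t[k] < problem$t_last) w$w_end else 0
    if (!has_out[k] && !has_in[k]) {
      cost <- cost + min(w$w_ignore, sp + ep)
    } else {
      if (!has_in[k]) cost <- cost + sp
      if (!has_out[k]) cost <- cost + ep
    }
  }
  cost
}
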
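#' Solve a link problem to global optimality
#'
#' Encodes the problem as a 0/1 integer program -- one binary per candidate
#' link, per gated division pair, per ignore decision and per non-boundary
#' start/end penalty -- and solves it exactly with the HiGHS mixed-integer
#' solver (reached through the `python`/`scipy` runtime, see
#' `SystemRequirements`). The objective minimises selected link costs (halved
#' at realized divisions), division rewards `-w_division * (s - 1)`, start
#' and end penalties and ignore penalties; constraints enforce in-degree at
#' most 1, out-degree at most 2, and out-degree 2 only on a gated division
#' pair. Among equal-cost optima a tiny deterministic perturbation prefers
#' the lexicographically earliest link set; the returned objective is
#' computed from the unperturbed costs.
#'
#' @param problem A [link_problem()].
#' @return A links tibble with attributes `objective` (the optimal value
#'   under [solution_objective()]) and `status`.
#' @export
solve_links <- function(problem) {
  solve_link_problems(list(problem))[[1]]
}

#' @rdname solve_links
#' @param problems A list of [link_problem()] objects, solved in one solver
#'   invocation (much faster than repeated [solve_links()] calls).
#' @export
solve_link_problems <- function(problems) {
  stopifnot(all(vapply(problems, inherits, logical(1), "link_problem")))
  specs <- lapply(problems, build_link_milp)
  nonempty <- which(vapply(specs, function(s) s$n > 0, logical(1)))
  sols <- if (length(nonempty)) milp_solve_batch(specs[nonempty]) else list()
  out <- vector("list", length(problems))
  si <- 0L
  for (k in seq_along(problems)) {
    if (!(k %in% nonempty)) {
      links <- links_tbl()
    } else {
      si <- si + 1L
      sol <- sols[[si]]
      if (sol$status != 0) {
        stop("solve_links: solver failed with status ", sol$status, call. = FALSE)
      }
      spec <- specs[[k]]
      sel <- which(round(sol$x[seq_len(spec$n_links)]) == 1)
      cand <- problems[[k]]$candidates
      links <- links_tbl(cand$t[sel], cand$from[sel], cand$to[sel])
    }
    obj <- solution_objective(problems[[k]], links)
    attr(links, "objective") <- obj
    attr(links, "status") <- "optimal"
    out[[k]] <- links
  }
  out
}

# 0/1 integer program for one link problem.
# Variable layout: [links, pairs, ignore, start, end].
build_link_milp <- function(p) {
  cand <- p$candidates
  pos <- p$positions
  pairs <- p$pairs
  w <- p$weights
  nl <- nrow(cand); np <- nrow(pairs); npos <- nrow(pos)
  pk <- pos_key(pos$t, pos$i)
  pidx <- stats::setNames(seq_len(npos), pk)
  need_start <- pos$t > p$t_first
  need_end <- pos$t < p$t_last
  v_link <- seq_len(nl)
  v_pair <- nl + seq_len(np)
  v_ign <- nl + np + seq_len(npos)
  v_start <- nl + np + npos + seq_len(npos)
  v_end <- nl + np + 2L * npos + seq_len(npos)
  n <- nl + np + 3L * npos
  if (n == 0) return(list(n = 0L, n_links = 0L))

  # pair k refers to the two candidate links (from -> to1), (from -> to2)
  pair_l1 <- pair_l2 <- integer(np)
  if (np) {
    ck <- paste(cand$t, cand$from, cand$to)
    pair_l1 <- match(paste(pairs$t, pairs$from, pairs$to1), ck)
    pair_l2 <- match(paste(pairs$t, pairs$from, pairs$to2), ck)
  }

  obj <- numeric(n)
  obj[v_link] <- cand$cost + 1e-9 * seq_len(nl)  # lexicographic tie-break
  if (np) {
    obj[v_pair] <- -(cand$cost[pair_l1] + cand$cost[pair_l2]) / 2 -
      w$w_division * (pairs$s - 1)
  }
  obj[v_ign] <- w$w_ignore
  obj[v_start] <- ifelse(need_start, w$w_start, 0)
  obj[v_end] <- ifelse(need_end, w$w_end, 0)
  # start/end indicators of boundary-frame positions are meaningless; pin
  # them to zero so the solver sees no spurious symmetric optima
  vub <- rep(1, n)
  vub[v_start[!need_start]] <- 0
  vub[v_end[!need_end]] <- 0

  ri <- integer(0); rj <- integer(0); rv <- numeric(0)
  lb <- numeric(0); ub <- numeric(0)
  nrow_ <- 0L
  add_row <- function(js, vs, lo, hi) {
    nrow_ <<- nrow_ + 1L
    ri <<- c(ri, rep(nrow_ - 1L, length(js)))
    rj <<- c(rj, js - 1L)
    rv <<- c(rv, vs)
    lb <<- c(lb, lo); ub <<- c(ub, hi)
  }

  src <- pidx[pos_key(cand$t, cand$from)]
  tgt <- pidx[pos_key(cand$t + 1L, cand$to)]
  in_of <- split(v_link, tgt)
  out_of <- split(v_link, src)
  pairs_of <- if (np) split(v_pair, pidx[pos_key(pairs$t, pairs$from)]) else list()

  # links exclude ignoring either endpoint
  for (l in seq_len(nl)) {
    add_row(c(v_link[l], v_ign[src[l]]), c(1, 1), -Inf, 1)
    add_row(c(v_link[l], v_ign[tgt[l]]), c(1, 1), -Inf, 1)
  }
  for (q in seq_len(npos)) {
    qi <- in_of[[as.character(q)]]
    oi <- out_of[[as.character(q)]]
    di <- pairs_of[[as.character(q)]]
    if (!is.null(qi)) add_row(qi, rep(1, length(qi)), -Inf, 1)  # no merges
    # cover: in-link, start penalty, or ignored
    if (need_start[q]) add_row(c(qi, v_start[q], v_ign[q]),
                               rep(1, length(qi) + 2L), 1, Inf)
    # cover: out-link, end penalty, or ignored
    if (need_end[q]) add_row(c(oi, v_end[q], v_ign[q]),
                             rep(1, length(oi) + 2L), 1, Inf)
    # out-degree at most 1 + realized divisions; at most one division
    if (!is.null(oi)) {
      add_row(c(oi, di), c(rep(1, length(oi)), rep(-1, length(di))), -Inf, 1)
    }
    if (!is.null(di) && length(di) > 1) add_row(di, rep(1, length(di)), -Inf, 1)
  }
  # a division pair requires both of its links
  for (k in seq_len(np)) {
    add_row(c(v_pair[k], v_link[pair_l1[k]]), c(1, -1), -Inf, 0)
    add_row(c(v_pair[k], v_link[pair_l2[k]]), c(1, -1), -Inf, 0)
  }
  list(n = n, n_links = nl, obj = obj, vub = vub,
       i = ri, j = rj, v = rv, lb = lb, ub = ub, nrow = nrow_)
}

milp_python_bin <- function() {
  for (cand in c("python3", "python")) {
    p <- Sys.which(cand)
    if (nzchar(p)) return(p)
  }
  stop("solve_links: no python interpreter found on PATH (required for the ",
       "HiGHS integer-programming backend)", call. = FALSE)
}

milp_solve_batch <- function(specs) {
  script <- system.file("python", "milp_solve.py", package = "nuctrackr")
  if (!nzchar(script)) stop("milp_solve.py not found in the installed package", call. = FALSE)
  inp <- tempfile(fileext = ".json")
  outp <- tempfile(fileext = ".json")
  on.exit(unlink(c(inp, outp)), add = TRUE)
  payload <- list(problems = lapply(specs, function(s) {
    list(n = s$n, nrow = s$nrow, c = as.numeric(s$obj),
         vub = as.numeric(s$vub),
         i = as.integer(s$i), j = as.integer(s$j), v = as.numeric(s$v),
         lb = as.numeric(s$lb), ub = as.numeric(s$ub))
  }))
  jsonlite::write_json(payload, inp, auto_unbox = TRUE, digits = NA, null = "null")
  code <- system2(milp_python_bin(), c(script, inp, outp),
                  stdout = FALSE, stderr = "")
  if (code != 0 || !file.exists(outp)) {
    stop("solve_links: integer-programming backend failed (exit ", code, ")",
         call. = FALSE)
  }
  res <- jsonlite::read_json(outp, simplifyVector = FALSE)
  lapply(res$results, function(r) {
    list(status = as.integer(r$status),
         x = as.numeric(unlist(r$x)))
  })
}

#' Exhaustively solve a small link problem (test oracle)
#'
#' Exact enumeration organised as a dynamic programme over frames: every
#' feasible assignment of out-options (none, one candidate link, or a gated
#' division pair, with disjoint targets) of one frame's positions is
#' enumerated explicitly, and states are the subsets of next-frame positions
#' that received an in-link (at most 2^8 for the permitted instance sizes).
#' Guaranteed to return a global optimum of the same objective as
#' [solve_links()]; implemented independently of it as a cross-check at tiny
#' problem sizes.
#'
#' @param problem A [link_problem()] with at most `max_positions` positions
#'   and at most `max_per_frame` positions per frame.
#' @param max_positions,max_per_frame Size guards (default 25 / 8).
#' @return A links tibble with attribute `objective`.
#' @export
brute_force_link <- function(problem, max_positions = 25L, max_per_frame = 8L) {
  stopifnot(inherits(problem, "link_problem"))
  pos <- problem$positions
  if (nrow(pos) > max_positions) {
    stop("brute_force_link: instance too large (", nrow(pos), " positions)",
         call. = FALSE)
  }
  if (nrow(pos) && max(table(pos$t)) > max_per_frame) {
    stop("brute_force_link: instance too large (more than ", max_per_frame,
         " positions in one frame)", call. = FALSE)
  }
  w <- problem$weights
  cand <- problem$candidates
  pairs <- problem$pairs
  if (!nrow(pos)) {
    out <- links_tbl(); attr(out, "objective") <- 0
    attr(out, "status") <- "optimal"
    return(out)
  }
  t_first <- problem$t_first; t_last <- problem$t_last
  start_pen <- ifelse(pos$t > t_first, w$w_start, 0)
  end_pen <- ifelse(pos$t < t_last, w$w_end, 0)
  settle <- function(row, has_in, has_out) {
    if (!has_in && !has_out) return(min(w$w_ignore, start_pen[row] + end_pen[row]))
    (if (!has_in) start_pen[row] else 0) + (if (!has_out) end_pen[row] else 0)
  }
  ck <- paste(cand$t, cand$from, cand$to)

  # all feasible option-combinations of one frame's positions: each config
  # records total link cost, per-position out flags, the bitmask of
  # next-frame targets consumed, and the chosen candidate rows
  stage_configs <- function(tt, P, P1) {
    n <- nrow(P)
    opts_of <- vector("list", max(n, 0L))
    for (q in seq_len(n)) {
      opts <- list(list(cost = 0, tmask = 0L, links = integer(), out = FALSE))
      ls <- which(cand$t == tt & cand$from == P$i[q])
      for (l in ls) {
        tl <- match(cand$to[l], P1$i)
        opts[[length(opts) + 1L]] <- list(cost = cand$cost[l],
                                          tmask = bitwShiftL(1L, tl - 1L),
                                          links = l, out = TRUE)
      }
      ph <- which(pairs$t == tt & pairs$from == P$i[q])
      for (k in ph) {
        l1 <- match(paste(tt, P$i[q], pairs$to1[k]), ck)
        l2 <- match(paste(tt, P$i[q], pairs$to2[k]), ck)
        t1 <- match(cand$to[l1], P1$i); t2 <- match(cand$to[l2], P1$i)
        opts[[length(opts) + 1L]] <- list(
          cost = (cand$cost[l1] + cand$cost[l2]) / 2 -
            w$w_division * (pairs$s[k] - 1),
          tmask = bitwOr(bitwShiftL(1L, t1 - 1L), bitwShiftL(1L, t2 - 1L)),
          links = c(l1, l2), out = TRUE)
      }
      opts_of[[q]] <- opts
    }
    configs <- list()
    rec <- function(q, used, cost, outs, links) {
      if (q > n) {
        configs[[length(configs) + 1L]] <<- list(cost = cost, tmask = used,
                                                 outs = outs, links = links)
        return()
      }
      for (o in opts_of[[q]]) {
        if (bitwAnd(used, o$tmask) != 0L) next
        rec(q + 1L, bitwOr(used, o$tmask), cost + o$cost,
            c(outs, o$out), c(links, o$links))
      }
    }
    rec(1L, 0L, 0, logical(0), integer(0))
    configs
  }

  frames <- t_first:t_last
  frame_rows <- lapply(frames, function(tt) which(pos$t == tt))
  dp <- 0                      # cost per in-mask of the current frame
  bp <- vector("list", length(frames))
  all_configs <- vector("list", length(frames))
  for (fi in seq_along(frames)) {
    tt <- frames[fi]
    rows <- frame_rows[[fi]]
    P <- pos[rows, , drop = FALSE]
    rows1 <- if (fi < length(frames)) frame_rows[[fi + 1L]] else integer()
    P1 <- pos[rows1, , drop = FALSE]
    configs <- stage_configs(tt, P, P1)
    all_configs[[fi]] <- configs
    n <- nrow(P)
    # per-config cost assuming every frame-tt position has an in-link, plus
    # the per-position surcharge when it does not
    base <- vapply(configs, function(cf) {
      cf$cost + sum(vapply(seq_len(n), function(q)
        settle(rows[q], TRUE, cf$outs[q]), numeric(1)))
    }, numeric(1))
    delta <- matrix(0, length(configs), max(n, 1L))
    if (n) {
      for (c_id in seq_along(configs)) {
        cf <- configs[[c_id]]
        delta[c_id, seq_len(n)] <- vapply(seq_len(n), function(q)
          settle(rows[q], FALSE, cf$outs[q]) - settle(rows[q], TRUE, cf$outs[q]),
          numeric(1))
      }
    }
    tmask <- vapply(configs, function(cf) cf$tmask, integer(1))
    n1 <- nrow(P1)
    dp_next <- rep(Inf, 2^n1)
    bp_stage <- vector("list", 2^n1)
    for (s in seq_along(dp)) {
      if (!is.finite(dp[s])) next
      miss <- if (n) as.numeric(bitwAnd(s - 1L, bitwShiftL(1L, seq_len(n) - 1L)) == 0L)
              else numeric(1)
      tot <- dp[s] + base + as.numeric(delta %*% miss[seq_len(ncol(delta))])
      ord <- order(tot)
      first <- ord[!duplicated(tmask[ord])]
      for (c_id in first) {
        m <- tmask[c_id] + 1L
        if (tot[c_id] < dp_next[m] - 1e-12) {
          dp_next[m] <- tot[c_id]
          bp_stage[[m]] <- c(s, c_id)
        }
      }
    }
    dp <- dp_next
    bp[[fi]] <- bp_stage
  }
  best_state <- which.min(dp)
  # walk the backpointers to recover the chosen candidate rows
  sel <- integer()
  st <- best_state
  for (fi in rev(seq_along(frames))) {
    step <- bp[[fi]][[st]]
    sel <- c(sel, all_configs[[fi]][[step[2]]]$links)
    st <- step[1]
  }
  sel <- sort(sel)
  out <- links_tbl(cand$t[sel], cand$from[sel], cand$to[sel])
  attr(out, "objective") <- solution_objective(problem, out)
  attr(out, "status") <- "optimal"
  out
}
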
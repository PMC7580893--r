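test_that("nearest-neighbour linking follows proximity, divisions for free", {
  res <- paper_res
  # two stationary nuclei -> two correct links per frame step
  pos <- positions_tbl(t = c(0, 0, 1, 1, 2, 2),
                       x = c(10, 40, 10, 40, 10, 40),
                       y = c(10, 40, 10, 40, 10, 40), z = 3)
  lk <- nearest_neighbor_link(pos, res)
  expect_equal(nrow(lk), 4L)
  expect_true(all(lk$from == lk$to))

  # three positions at t+1 nearest to one parent: out-degree 3 is permitted
  pos3 <- positions_tbl(t = c(0, 0, 1, 1, 1),
                        x = c(10, 100, 9, 11, 10),
                        y = c(10, 100, 10, 10, 12), z = 3)
  lk3 <- nearest_neighbor_link(pos3, res)
  expect_equal(sum(lk3$from == 1), 3L)

  # noiseless slow drift: every ground-truth link recovered
  gt <- simulate_ground_truth(simulation_config(n_nuclei = 15, n_frames = 15,
                                                motion_sigma = 0.3,
                                                division_rate = 0, seed = 22))
  lk_nn <- nearest_neighbor_link(gt$experiment$positions, res)
  expect_equal(dplyr::arrange(lk_nn, t, from),
               dplyr::arrange(gt$experiment$links, t, from))
})

test_that("candidates honour the twice-the-nearest-neighbour cutoff", {
  res <- paper_res
  # source A with neighbours at 2, 3.5 and 5 um; a second source near the far
  # target keeps the backward direction from rescuing the 5 um link
  um <- function(v) v / res$pixel_size_xy
  pos <- positions_tbl(t = c(0, 0, 1, 1, 1),
                       x = um(c(0, 5.5, 2, 3.5, 5)),
                       y = 0, z = 0)
  cand <- generate_candidates(pos, res, factor = 2)
  a_cand <- dplyr::filter(cand, .data$from == 1)
  expect_equal(sort(round(a_cand$dx_um, 2)), c(2, 3.5))
  # single position in each frame -> exactly one candidate
  single <- positions_tbl(c(0, 1), c(0, 30), c(0, 0), c(0, 0))
  expect_equal(nrow(generate_candidates(single, res)), 1L)
  # factor 1 keeps only mutual/directional nearest neighbours
  c1 <- generate_candidates(pos, res, factor = 1)
  expect_true(all(round(c1$dx_um[c1$from == 1], 2) == 2))
})

test_that("link costs follow the movement-plus-volume rule and halve at divisions", {
  w <- link_weights()
  expect_equal(link_cost(3, 6, w), 100)           # (3 + 6/3) * 20
  expect_equal(link_cost(3, 6, w, TRUE), 50)      # halved
  expect_equal(link_cost(0, 0, w), 0)
  expect_equal(w$w_link, 20); expect_equal(w$w_end, 100)
  expect_equal(w$w_start, 150); expect_equal(w$w_ignore, 150)
  expect_equal(w$w_division, 30)
})

test_that("division scores gate on combined volume and intensity ratios", {
  # both ratios exactly 1 -> boundary score 1
  expect_equal(division_score(1, 1, 1, 1, 1, 1), 1)
  # mother twice the daughters in both volume and intensity -> 2
  expect_equal(division_score(2, 1, 1, 2, 1, 1), 2)
  # dim small mother -> below 1, division disallowed
  expect_lt(division_score(0.5, 1, 1, 0.5, 1, 1), 1)
  # zero denominators cap at a large finite score
  expect_true(is.finite(division_score(1, 0, 0, 1, 0, 0)))
  # missing volumes fall back to intensity only
  expect_equal(division_score(NA, NA, NA, 2, 1, 1), 2)
})

test_that("the worked one-link instance resolves as expected", {
  pos <- positions_tbl(c(0, 1), c(0, 1 / 0.32), c(0, 0), c(0, 0))
  pr <- link_problem(pos, res = paper_res)
  sol <- solve_links(pr)
  expect_equal(nrow(sol), 1L)
  expect_equal(attr(sol, "objective"), 20, tolerance = 1e-9)
  # alternatives are costlier: ignore both = 300, two singletons = 250
  expect_equal(solution_objective(pr, links_tbl()), 250)  # cheaper of the two
  # empty problem yields an empty link graph
  e <- solve_links(link_problem(positions_tbl(), res = paper_res))
  expect_equal(nrow(e), 0L)
})

test_that("an isolated interior position is ignored rather than tracked", {
  pr <- link_problem(positions_tbl(1, 5, 5, 5), res = paper_res,
                     t_first = 0, t_last = 2)
  expect_equal(attr(brute_force_link(pr), "objective"), 150)  # 150 < 250
  expect_equal(attr(solve_links(pr), "objective"), 150)
  # all weights zero: any feasible solution costs 0
  pr0 <- link_problem(positions_tbl(1, 5, 5, 5),
                      weights = link_weights(0, 0, 0, 0, 0),
                      res = paper_res, t_first = 0, t_last = 2)
  expect_equal(attr(brute_force_link(pr0), "objective"), 0)
})

test_that("the exact solver agrees with brute force on random instances", {
  for (seed in 1:40) {
    pr <- random_link_problem(seed)
    o_milp <- attr(solve_links(pr), "objective")
    o_bf <- attr(brute_force_link(pr), "objective")
    expect_equal(o_milp, o_bf, tolerance = 1e-6,
                 info = sprintf("seed %d", seed))
  }
})

test_that("solver output always satisfies the link-graph invariants", {
  for (seed in 41:55) {
    pr <- random_link_problem(seed)
    sol <- solve_links(pr)
    if (!nrow(sol)) next
    # no merges
    expect_false(anyDuplicated(pos_key_vec(sol$t + 1L, sol$to)) > 0)
    outdeg <- dplyr::count(sol, .data$t, .data$from)
    expect_true(all(outdeg$n <= 2))
    # divisions only on gated pairs
    mothers <- outdeg[outdeg$n == 2L, ]
    for (k in seq_len(nrow(mothers))) {
      dl <- sol[sol$t == mothers$t[k] & sol$from == mothers$from[k], ]
      pk <- paste(pr$pairs$t, pr$pairs$from, pr$pairs$to1, pr$pairs$to2)
      expect_true(paste(mothers$t[k], mothers$from[k],
                        min(dl$to), max(dl$to)) %in% pk)
    }
    # objective no worse than nearest-neighbour linking under the same costs
    nn <- nearest_neighbor_link(pr$positions, pr$res)
    o_nn <- solution_objective(pr, nn)
    expect_lte(attr(sol, "objective"), o_nn + 1e-9)
  }
})

test_that("brute force refuses oversized instances", {
  pos <- positions_tbl(rep(0:1, each = 20), runif(40, 0, 50), runif(40, 0, 50), 0)
  pr <- link_problem(pos, res = paper_res)
  expect_error(brute_force_link(pr), "too large")
})

test_that("linking clean synthetic detections recovers the ground truth", {
  cfg <- simulation_config(n_nuclei = 12, n_frames = 12, division_rate = 0.02,
                           cell_cycle_min = 0, seed = 30)
  gt <- simulate_ground_truth(cfg)
  exp <- gt$experiment  # positions + true shapes, links are the truth
  truth <- exp$links
  relink <- link_experiment(
    tracking_experiment(cfg$resolution, exp$positions, shapes = exp$shapes,
                        n_frames = cfg$n_frames))
  m <- match_links(list(positions = exp$positions, links = truth),
                   list(positions = relink$positions, links = relink$links),
                   cfg$resolution)
  f1 <- precision_recall_f1(m, quiet = TRUE)$f1
  expect_gte(f1, 0.99)
})

test_that("raising start and end penalties cannot fragment more tracks", {
  gt <- simulate_ground_truth(simulation_config(n_nuclei = 8, n_frames = 6,
                                                division_rate = 0, seed = 33))
  pos <- degrade_ground_truth(gt, miss_rate = 0.1, fp_rate = 0.1, jitter_um = 0.3,
                              seed = 2)
  n_tracks <- vapply(c(30, 80, 150, 300), function(wse) {
    w <- link_weights(w_link = 20, w_end = wse, w_start = wse * 1.5,
                      w_ignore = 150, w_division = 30)
    pr <- link_problem(pos, weights = w, res = gt$config$resolution,
                       t_first = 0, t_last = 5)
    sol <- solve_links(pr)
    ex <- tracking_experiment(gt$config$resolution, pos, sol, n_frames = 6L)
    # tracks = maximal unbranched segments (singletons included); raising the
    # start/end penalties buys longer tracks, so this count cannot grow
    nrow(attr(track_segments(ex), "tracks"))
  }, numeric(1))
  expect_true(all(diff(n_tracks) <= 0))
})
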
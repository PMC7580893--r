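test_that("detection matching is greedy with a 5 um cap and a reject zone", {
  res <- paper_res
  um <- function(v) v / res$pixel_size_xy
  # identical sets match perfectly
  gt <- positions_tbl(c(0, 0), um(c(0, 10)), 0, 0)
  m <- match_detections(gt, gt, res)
  expect_equal(c(m$tp, m$fp, m$fn, m$rejected), c(2, 0, 0, 0))

  # gt at 0 and 10 um; pred at 1 and 4 um: greedy assigns 1<->0, leaving the
  # 4 um pred an unmatched detection near annotated cells (FP) and the 10 um
  # center unmatched (FN)
  pred <- positions_tbl(c(0, 0), um(c(1, 4)), 0, 0)
  m2 <- match_detections(gt, pred, res)
  expect_equal(c(m2$tp, m2$fp, m2$fn, m2$rejected), c(1, 1, 1, 0))

  # a detection 6 um from the only center is rejected, not an FP
  gt1 <- positions_tbl(0, 0, 0, 0)
  pred6 <- positions_tbl(0, um(6), 0, 0)
  m3 <- match_detections(gt1, pred6, res)
  expect_equal(c(m3$tp, m3$fp, m3$fn, m3$rejected), c(0, 0, 1, 1))

  # symmetry: swapping gt and pred swaps FP and FN when nothing is rejected
  gt_s <- positions_tbl(c(0, 0), um(c(0, 4)), 0, 0)
  pred_s <- positions_tbl(0, um(1), 0, 0)
  ms <- match_detections(gt_s, pred_s, res)
  ms_sw <- match_detections(pred_s, gt_s, res)
  expect_equal(ms$rejected + ms_sw$rejected, 0L)
  expect_equal(c(ms_sw$tp, ms_sw$fp, ms_sw$fn), c(ms$tp, ms$fn, ms$fp))
})

test_that("link matching tolerates 5 um endpoint offsets and rejects debris", {
  res <- paper_res
  gt <- fixture_experiment()
  # identical link sets are all true positives
  m <- match_links(gt, gt, res)
  expect_equal(c(m$tp, m$fp, m$fn), c(nrow(gt$links), 0, 0))

  # removing the frame-1 detection of the linear track loses both its links
  broken <- delete_position(gt, 1, 1)
  m2 <- match_links(gt, broken, res)
  expect_equal(m2$fn, 2L)
  expect_equal(m2$tp, nrow(gt$links) - 2L)

  # a spurious link far from all annotations is rejected, not an FP
  far <- gt
  far$positions <- dplyr::bind_rows(
    far$positions,
    tibble::tibble(t = c(0L, 1L), i = c(90L, 90L), x = 400, y = 400, z = 3))
  far$links <- dplyr::bind_rows(far$links,
                                tibble::tibble(t = 0L, from = 90L, to = 90L))
  m3 <- match_links(gt, far, res)
  expect_equal(m3$fp, 0L)
  expect_equal(m3$rejected, 1L)
})

test_that("precision, recall and F1 reproduce the worked values", {
  # the detection network's headline numbers
  expect_equal(round(precision_recall_f1(96, 2, 4)$precision, 2), 0.98)
  f1 <- function(p, r) 2 * p * r / (p + r)
  expect_equal(round(f1(0.98, 0.96), 2), 0.97)
  expect_equal(round(f1(0.969, 0.66), 2), 0.79)
  expect_equal(round(f1(0.79, 0.55), 2), 0.65)
  # p = r makes the harmonic mean collapse to p
  expect_equal(precision_recall_f1(50, 50, 50)$f1, 0.5)
  # degenerate zero counts give zeros, not NaN
  z <- precision_recall_f1(0, 0, 0, quiet = TRUE)
  expect_equal(c(z$precision, z$recall, z$f1), c(0, 0, 0))
  m <- precision_recall_f1(0, 5, 5, quiet = TRUE)
  expect_equal(m$f1, 0)
})

test_that("F1 stays within its theoretical envelope on random counts", {
  set.seed(3)
  for (k in 1:20) {
    tp <- rpois(1, 20); fp <- rpois(1, 5); fn <- rpois(1, 5)
    m <- precision_recall_f1(tp, fp, fn, quiet = TRUE)
    expect_gte(m$f1, 0); expect_lte(m$f1, 1)
    expect_lte(m$f1, max(m$precision, m$recall) + 1e-12)
    if (tp == 0) expect_equal(m$f1, 0)
  }
})

test_that("pseudo-masks are 5 um spheres split by nearest position", {
  res <- paper_res
  # one sphere mid-volume: ~31 px in-plane diameter, 5 slices in z
  pos <- positions_tbl(0, 50, 50, 8)
  lab <- make_pseudo_masks(pos, res, c(16, 100, 100), radius_um = 5)
  expect_equal(sort(unique(as.vector(lab))), c(0L, 1L))
  prof_x <- which(lab[51, , 9] == 1L)
  expect_equal(length(prof_x), 31)  # 2 * floor(5 / 0.32) + 1
  prof_z <- which(lab[51, 51, ] == 1L)
  expect_equal(length(prof_z), 5)   # 2 * floor(5 / 2) + 1
  # two positions 4 um apart split along the perpendicular bisector
  two <- positions_tbl(c(0, 0), c(50, 50 + 4 / 0.32), 50, 8)
  lab2 <- make_pseudo_masks(two, res, c(16, 100, 100), radius_um = 5)
  xs1 <- which(lab2[51, , 9] == 1L); xs2 <- which(lab2[51, , 9] == 2L)
  expect_lt(max(xs1), min(xs2))
  mid <- 51 + 2 / 0.32
  expect_true(all(xs1 < mid + 1) && all(xs2 > mid - 1))
  # empty frame -> all zero
  expect_equal(max(make_pseudo_masks(positions_tbl(), res, c(4, 10, 10))), 0L)
})

test_that("CTC export/import round-trips lineage topology", {
  dir <- withr::local_tempdir()
  exp <- fixture_experiment()
  export_ctc(exp, dir, shape = c(16, 64, 64))
  expect_true(file.exists(file.path(dir, "res_track.txt")))
  expect_length(list.files(dir, pattern = "^mask[0-9]+\\.tif$"), 3L)
  tr <- utils::read.table(file.path(dir, "res_track.txt"),
                          col.names = c("track", "begin", "end", "parent"))
  # one track per unbranched segment: linear track + mother + 2 daughters
  expect_equal(nrow(tr), 4L)
  expect_equal(sum(tr$parent == 0), 2L)
  # the two daughters share the mother track as parent, begin after its end
  daughters <- tr[tr$parent > 0, ]
  expect_equal(nrow(daughters), 2L)
  expect_equal(length(unique(daughters$parent)), 1L)
  mother <- tr[tr$track == daughters$parent[1], ]
  expect_equal(daughters$begin, rep(mother$end + 1L, 2))

  back <- import_ctc(dir, exp$resolution)
  expect_equal(nrow(back$positions), nrow(exp$positions))
  # identical lineage trees (same division structure)
  fr1 <- build_lineage_trees(exp)
  fr2 <- build_lineage_trees(back)
  expect_equal(sort(table(fr1$tree_id)), sort(table(fr2$tree_id)),
               ignore_attr = TRUE)
  expect_equal(sort(fr1$divisions), sort(fr2$divisions))
  # positions round-trip to voxel resolution
  m <- match_detections(exp$positions, back$positions, exp$resolution,
                        max_dist_um = 1.5)
  expect_equal(m$fn, 0L)

  # merges refuse to export
  bad <- exp
  bad$links <- dplyr::bind_rows(bad$links, tibble::tibble(t = 0L, from = 1L, to = 2L))
  expect_error(export_ctc(bad, dir, c(16, 64, 64)), "merge")
})

test_that("a single 3-frame track exports as one label with parent 0", {
  dir <- withr::local_tempdir()
  pos <- positions_tbl(0:2, 20, 20, 4)
  exp <- tracking_experiment(paper_res, pos, links_tbl(0:1, 1, 1), n_frames = 3L)
  export_ctc(exp, dir, shape = c(8, 40, 40))
  tr <- utils::read.table(file.path(dir, "res_track.txt"),
                          col.names = c("track", "begin", "end", "parent"))
  expect_equal(nrow(tr), 1L)
  expect_equal(c(tr$begin, tr$end, tr$parent), c(0, 2, 0))
  for (tt in 0:2) {
    lab <- nuctrackr:::read_label_tiff(file.path(dir, sprintf("mask%03d.tif", tt)))
    expect_equal(sort(unique(as.vector(lab))), c(0L, tr$track))
  }
})

test_that("degraded detections measure back the configured rates", {
  gt <- simulate_ground_truth(simulation_config(n_nuclei = 25, n_frames = 8,
                                                division_rate = 0,
                                                debris_count = 0, seed = 50))
  res <- gt$config$resolution
  miss <- 0.04; fp_rate <- 0.02
  tps <- fps <- fns <- 0
  for (s in 1:12) {
    pred <- degrade_ground_truth(gt, miss, fp_rate, 0, seed = s)
    m <- match_detections(gt$experiment$positions, pred, res)
    tps <- tps + m$tp; fps <- fps + m$fp; fns <- fns + m$fn
  }
  recall <- tps / (tps + fns)
  n <- nrow(gt$experiment$positions) * 12
  expect_lt(abs(recall - (1 - miss)), 3 * sqrt(miss * (1 - miss) / n))
  # false positives can also be rejected (far from any annotation), so the
  # measured precision is at least the binomial expectation
  precision <- tps / (tps + fps)
  expect_gte(precision, (1 - miss) / (1 - miss + fp_rate) - 0.02)
})
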
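test_that("mask IoU counts pixels correctly", {
  a <- mask_from(3:4, 3:4)
  expect_equal(mask_iou(a, a), 1)
  expect_equal(mask_iou(a, mask_from(8:9, 8:9)), 0)
  # 2x2 square against the same square shifted right by one column
  expect_equal(mask_iou(a, mask_from(3:4, 4:5)), 2 / 6)
  expect_equal(mask_iou(mask_from(integer(0), integer(0)),
                        mask_from(integer(0), integer(0))), 0)
  expect_error(mask_iou(a, matrix(FALSE, 5, 5)), "shape")
})

test_that("greedy matching follows score order and the IoU threshold", {
  gts <- instance_set(list(mask_from(1:4, 1:4), mask_from(8:11, 8:11)))
  perfect <- instance_set(gts$masks, score = c(0.9, 0.8))
  for (t in c(0.5, 0.75, 0.9)) {
    m <- match_detections(perfect, gts, t, "mask")
    expect_equal(sum(m$detections$tp), 2)
    expect_equal(m$fn, 0)
  }

  # one detection overlapping two ground truths is matched to the higher
  # IoU one; the other ground truth becomes a false negative
  gt2 <- instance_set(list(mask_from(1:4, 1:5), mask_from(1:4, 6:9)))
  det <- instance_set(list(mask_from(1:4, 1:6)), score = 0.9)
  m <- match_detections(det, gt2, 0.5, "mask")
  expect_true(m$detections$tp[1])
  expect_equal(m$detections$matched_gt[1], 1L)
  expect_equal(m$fn, 1)

  # TP + FN equals the number of ground-truth instances at any threshold
  set.seed(42)
  for (i in 1:5) {
    n <- sample(1:6, 1)
    gts_r <- instance_set(lapply(seq_len(n), function(k)
      mask_from(sample(1:10, 3), sample(1:10, 3))))
    dets_r <- instance_set(lapply(1:4, function(k)
      mask_from(sample(1:10, 3), sample(1:10, 3))), score = runif(4))
    m <- match_detections(dets_r, gts_r, 0.5, "mask")
    expect_equal(sum(m$detections$tp) + m$fn, n)
  }
})

test_that("only the 100 top-scoring detections are considered", {
  gt <- instance_set(list(mask_from(1:3, 1:3)))
  masks <- c(list(mask_from(1:3, 1:3)),
             replicate(149, mask_from(9:10, 9:10), simplify = FALSE))
  # the only correct mask carries the lowest score, so it is truncated away
  dets <- instance_set(masks, score = c(0.001, seq(0.999, 0.01,
                                                   length.out = 149)))
  m <- match_detections(dets, gt, 0.5, "mask")
  expect_equal(nrow(m$detections), 100)
  expect_equal(sum(m$detections$tp), 0)
})

test_that("interpolated AP matches hand-computed examples", {
  # all detections correct and covering all ground truth
  case_perfect <- list(scores = c(0.9, 0.8), is_tp = c(TRUE, TRUE), n_gt = 2)
  expect_equal(interpolated_ap(as_match_result(case_perfect)), 1)

  # 2 GT; one TP at 0.9, one FP at 0.8: precision/recall curve gives
  # p_interp = 1 for r <= 0.5 and 0 beyond -> 51/101
  case_half <- list(scores = c(0.9, 0.8), is_tp = c(TRUE, FALSE), n_gt = 2)
  expect_equal(interpolated_ap(as_match_result(case_half)), 51 / 101)

  case_none <- list(scores = numeric(0), is_tp = logical(0), n_gt = 3)
  expect_equal(interpolated_ap(as_match_result(case_none)), 0)

  expect_true(is.na(interpolated_ap(as_match_result(
    list(scores = 0.5, is_tp = FALSE, n_gt = 0)))))
})

test_that("AP is invariant to how detections are split across images", {
  set.seed(7)
  case <- random_match_case()
  while (case$n_gt == 0 || length(case$scores) < 4) case <- random_match_case()
  pooled <- interpolated_ap(as_match_result(case))
  half <- floor(length(case$scores) / 2)
  a <- list(scores = case$scores[seq_len(half)],
            is_tp = case$is_tp[seq_len(half)], n_gt = case$n_gt)
  b <- list(scores = case$scores[-seq_len(half)],
            is_tp = case$is_tp[-seq_len(half)], n_gt = 0)
  split_ap <- interpolated_ap(list(as_match_result(a), as_match_result(b)))
  expect_equal(split_ap, pooled)
})

test_that("AP is non-increasing in the IoU threshold", {
  set.seed(11)
  scenes <- generate_dataset(2, scene_config(
    image_height = 96, image_width = 96, n_cells = 3, cluster_fraction = 0,
    multinucleate_rate = 0, nucleus_radius_range = c(3, 5),
    cell_radius_range = c(8, 12)), seed = 11)
  gts <- lapply(scenes, function(s) s$cell_truth)
  # noisy predictions: true masks eroded/kept with jittered scores
  preds <- lapply(gts, function(g) {
    masks <- lapply(g$masks, function(m) {
      if (runif(1) < 0.5) m & mask_from(1:60, 1:90, 96, 96) else m
    })
    instance_set(masks, score = runif(length(masks)))
  })
  aps <- vapply(seq(0.5, 0.9, 0.05), function(t) {
    interpolated_ap(purrr::map2(preds, gts, match_detections, t = t,
                                mode = "mask"))
  }, numeric(1))
  expect_true(all(diff(aps) <= 1e-12))
})

test_that("mean AP averages the nine thresholds and guards missing values", {
  expect_equal(mean_ap(rep(1, 9)), 1)
  ths <- seq(0.5, 0.9, 0.05)
  tbl <- tibble::tibble(threshold = ths, ap = seq(0.9, 0.1, length.out = 9))
  expect_equal(mean_ap(tbl), mean(tbl$ap))
  tbl$ap[3] <- NA
  expect_error(mean_ap(tbl), "missing")
  expect_equal(mean_ap(tbl, na_action = "omit"), mean(tbl$ap, na.rm = TRUE))
  expect_error(mean_ap(rep(1, 8)), "9")
})

test_that("relative improvement is exact arithmetic", {
  expect_equal(relative_improvement(0.5, 0.5), 0)
  expect_equal(relative_improvement(0.55, 0.5), 10)
  expect_error(relative_improvement(0.5, 0), "positive")
})

test_that("evaluate_detections produces a coherent report", {
  gts <- instance_set(list(mask_from(1:4, 1:4), mask_from(8:11, 8:11)))
  preds <- instance_set(gts$masks, score = c(0.9, 0.8))
  rep <- evaluate_detections(preds, gts, mode = "mask")
  expect_s3_class(tidy(rep), "tbl_df")
  expect_equal(nrow(tidy(rep)), 9)
  expect_equal(rep$mean_ap, 1)
  g <- glance(rep)
  expect_equal(g$tp, 2)
  expect_equal(g$fp + g$fn, 0)
  expect_equal(g$precision, 1)
  p <- autoplot(rep)
  expect_s3_class(p, "ggplot")
})
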
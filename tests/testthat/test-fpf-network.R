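zero_stages <- function(base = 16, C = c(32, 64, 128, 256)) {
  stats::setNames(lapply(1:4, function(s) {
    array(0, c(base / 2^(s - 1), base / 2^(s - 1), C[s]))
  }), paste0("C", 2:5))
}

test_that("feature pyramid has the contracted shapes and zero behaviour", {
  set.seed(1)
  # stage sizes of a 256x256 input: 64, 32, 16, 8 -> levels 64..4
  stages <- stats::setNames(lapply(1:4, function(s) {
    array(rnorm(64^2 / 4^(s - 1) * 8 * 2^(s - 1)),
          c(64 / 2^(s - 1), 64 / 2^(s - 1), 8 * 2^(s - 1)))
  }), paste0("C", 2:5))
  pyr <- build_pyramid(stages, pyramid_width = 32)
  expect_equal(names(pyr), paste0("P", 2:6))
  expect_equal(unname(vapply(pyr, function(p) dim(p$value)[1], 0)),
               c(64, 32, 16, 8, 4))
  expect_true(all(vapply(pyr, function(p) dim(p$value)[3], 0) == 32))
  expect_equal(unname(attr(pyr, "strides")),
               c(4, 8, 16, 32, 64))

  z <- build_pyramid(zero_stages(), pyramid_width = 16)
  expect_true(all(vapply(z, function(p) max(abs(p$value)), 0) == 0))
})

test_that("pyramid fusion obeys additive identity and channel contracts", {
  set.seed(2)
  mk <- function(val = NULL) {
    stats::setNames(lapply(c(16, 8, 4, 2, 1), function(hw) {
      v <- if (is.null(val)) array(rnorm(hw * hw * 8), c(hw, hw, 8))
      else array(val, c(hw, hw, 8))
      fpfuse:::nn_const(fpfuse:::as4d(v))
    }), paste0("P", 2:6))
  }
  cell <- mk()
  zero_nuc <- mk(0)
  fused <- fuse_pyramids(cell, zero_nuc, mode = "add")
  for (l in names(cell)) expect_equal(fused[[l]]$value, cell[[l]]$value)
  expect_equal(attr(fused, "merge_mode"), "add")

  cat_fused <- fuse_pyramids(cell, mk(), mode = "concat")
  expect_equal(dim(cat_fused$P2$value)[3], 16)

  proj <- build_fusion_projection(8)
  cat_proj <- fuse_pyramids(cell, mk(), mode = "concat", projection = proj)
  expect_equal(dim(cat_proj$P2$value)[3], 8)
})

test_that("pyramid level assignment follows the k0 + log2 rule", {
  expect_equal(assign_pyramid_level(c(0, 0, 224, 224)), 4L)
  expect_equal(assign_pyramid_level(c(0, 0, 112, 112)), 3L)
  expect_equal(assign_pyramid_level(c(0, 0, 1000, 1000)), 5L)
  expect_equal(assign_pyramid_level(c(0, 0, 8, 8)), 2L)
  expect_equal(assign_pyramid_level(c(5, 5, 5, 9)), 2L)  # degenerate
})

test_that("RoI-Align interpolates constants and planes exactly", {
  const_map <- array(3.7, c(16, 16, 2))
  out <- roi_align(const_map, matrix(c(2.3, 1.1, 9.8, 12.4), 1), 7)
  expect_equal(dim(out$value), c(7, 7, 2, 1))
  expect_true(all(abs(out$value - 3.7) < 1e-12))

  # linear ramp: bilinear interpolation reproduces the plane analytically
  H <- 20; W <- 20
  plane <- outer(seq_len(H) - 0.5, seq_len(W) - 0.5,
                 function(y, x) 2 * x - 0.5 * y + 1)
  pm <- array(plane, c(H, W, 1))
  box <- c(3, 4, 13, 16)
  out2 <- roi_align(pm, matrix(box, 1), 5, sampling = 2)
  bw <- (box[3] - box[1]) / 5; bh <- (box[4] - box[2]) / 5
  expected <- matrix(0, 5, 5)
  for (i in 1:5) for (j in 1:5) {
    sy <- box[2] + (i - 1) * bh + c(0.25, 0.75) * bh
    sx <- box[1] + (j - 1) * bw + c(0.25, 0.75) * bw
    expected[i, j] <- mean(outer(sy, sx, function(y, x) 2 * x - 0.5 * y + 1))
  }
  expect_equal(out2$value[, , 1, 1], expected, tolerance = 1e-12)

  expect_error(roi_align(pm, matrix(c(5, 5, 5, 9), 1), 7), "non-positive")
})

test_that("anchor box coding is an algebraic inverse", {
  set.seed(4)
  refs <- cbind(runif(20, 0, 50), runif(20, 0, 50), 0, 0)
  refs[, 3] <- refs[, 1] + runif(20, 5, 40)
  refs[, 4] <- refs[, 2] + runif(20, 5, 40)
  boxes <- refs + matrix(rnorm(80, 0, 3), 20, 4)
  boxes[, 3] <- pmax(boxes[, 3], boxes[, 1] + 1)
  boxes[, 4] <- pmax(boxes[, 4], boxes[, 2] + 1)
  rt <- decode_boxes(encode_boxes(boxes, refs), refs)
  expect_lt(max(abs(rt - boxes)), 1e-4)
})

test_that("anchor layout matches the score-map vectorization order", {
  anc <- level_anchors(3, 2, stride = 4, scale = 8, ratios = c(1))
  # rows go y-fastest, then x: first anchor centred at (2, 2), second at
  # (2, 6), fourth at (6, 2)
  expect_equal(anc[1, ], c(-2, -2, 6, 6))
  expect_equal(anc[2, ], c(-2, 2, 6, 10))
  expect_equal(anc[4, ], c(2, -2, 10, 6))
  # aspect ratios preserve area
  anc3 <- level_anchors(1, 1, 4, 32, ratios = c(0.5, 1, 2))
  areas <- (anc3[, 3] - anc3[, 1]) * (anc3[, 4] - anc3[, 2])
  expect_equal(areas, rep(32^2, 3))
})

test_that("greedy NMS suppresses by overlap in score order", {
  boxes <- rbind(c(0, 0, 10, 10), c(1, 1, 11, 11), c(20, 20, 30, 30))
  keep <- nms(boxes, c(0.9, 0.8, 0.7), 0.5)
  expect_equal(keep, c(1, 3))
  keep_all <- nms(boxes, c(0.9, 0.8, 0.7), 0.95)
  expect_equal(keep_all, 1:3)
})

test_that("proposals are deterministic and score-calibrated", {
  set.seed(5)
  model <- fpf_model("cell_only",
                     backbone = backbone_config(width_multiplier = 0.125),
                     config = micro_model_config(), seed = 11)
  s <- simulate_scene(micro_scene_config(seed = 5))
  p1 <- predict(model, s$image_pair)
  p2 <- predict(model, s$image_pair)
  expect_identical(p1$meta, p2$meta)
  expect_lte(n_instances(p1), 100)

  # strongly negative objectness -> no proposal passes a 0.5 objectness cut
  pyr <- fpfuse:::forward_pyramid(model, s$image_pair)
  flat <- lapply(pyr, function(p) {
    d <- dim(p$value)
    n_cells <- d[1] * d[2] * 3
    list(scores = rep(-10, n_cells),
         deltas = matrix(0, n_cells, 4))
  })
  anch <- fpfuse:::model_anchors(model, pyr)
  props <- fpfuse:::rpn_proposals(flat, anch, dim(s$image_pair$cell))
  expect_true(all(1 / (1 + exp(-props$scores)) < 0.5))
})

test_that("loss bundle composition carries the factor-2 weighting", {
  b <- loss_bundle(0.1, 0.2, 0.3, 0.4, 0.5)
  expect_equal(b$total, 0.1 + 2 * 0.2 + 0.3 + 2 * 0.4 + 2 * 0.5)
  expect_equal(tidy(b)$weight, c(1, 2, 1, 2, 2))
  expect_error(loss_bundle(-1, 0, 0, 0, 0), "non-negative")
})

test_that("compute_loss returns finite weighted terms and honours no-positive guards", {
  set.seed(6)
  model <- fpf_model("cell_only",
                     backbone = backbone_config(width_multiplier = 0.125),
                     config = micro_model_config(), seed = 12)
  s <- simulate_scene(micro_scene_config(seed = 6))
  b <- compute_loss(model, s$image_pair, s$cell_truth)
  expect_true(all(is.finite(tidy(b)$value)))
  expect_equal(b$total,
               sum(tidy(b)$value * tidy(b)$weight))

  # blank ground truth: box and mask terms are zero by the count guard
  blank <- fpfuse:::empty_instance_set(dim(s$image_pair$cell), "cell")
  b0 <- compute_loss(model, s$image_pair, blank)
  v <- tidy(b0)
  expect_equal(v$value[v$term == "l_box"], 0)
  expect_equal(v$value[v$term == "l_mask"], 0)
})

test_that("pasted masks preserve the area of the nearest-resized box mask", {
  set.seed(7)
  for (i in 1:5) {
    msz <- 28
    mask <- matrix(runif(msz^2) > 0.5, msz, msz)
    box <- sort(runif(2, 0, 40)); boy <- sort(runif(2, 0, 40))
    box <- c(box[1], boy[1], box[1] + max(box[2] - box[1], 3),
             boy[1] + max(boy[2] - boy[1], 3))
    pasted <- fpfuse:::paste_mask(mask, box, c(64, 64))
    # independent expectation: nearest-neighbour lookup per covered pixel
    rows <- (floor(box[2]) + 1):ceiling(box[4])
    cols <- (floor(box[1]) + 1):ceiling(box[3])
    cnt <- 0
    for (r in rows) for (cc in cols) {
      ry <- min(max(ceiling((r - 0.5 - box[2]) / (box[4] - box[2]) * msz), 1), msz)
      rx <- min(max(ceiling((cc - 0.5 - box[1]) / (box[3] - box[1]) * msz), 1), msz)
      if (mask[ry, rx]) cnt <- cnt + 1
    }
    expect_equal(sum(pasted), cnt)
  }
})
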
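# Toy-array fixtures for the three refinement rules.

test_that("cells sharing a nucleus are merged, transitively", {
  # two cells over one shared nucleus -> single union instance
  a <- mask_from(2:5, 2:5)
  b <- mask_from(2:5, 6:9)
  nuc <- instance_set(list(mask_from(3:4, 4:7)), class = "nucleus")
  cells <- instance_set(list(a, b), score = c(0.9, 0.7))
  merged <- merge_cells_sharing_nucleus(cells, nuc)
  expect_equal(n_instances(merged), 1)
  expect_identical(merged$masks[[1]], a | b)
  expect_equal(merged$meta$score, 0.9)

  # no nucleus overlapped by two cells -> identity
  nuc1 <- instance_set(list(mask_from(3:4, 3:4)), class = "nucleus")
  same <- merge_cells_sharing_nucleus(cells, nuc1)
  expect_equal(n_instances(same), 2)

  # chain A-n1-B, B-n2-C collapses into one instance
  cc <- mask_from(2:5, 10:12)
  n1 <- instance_set(list(mask_from(3:4, 5:6), mask_from(3:4, 9:10)),
                     class = "nucleus")
  chain <- merge_cells_sharing_nucleus(
    instance_set(list(a, b, cc), score = c(0.9, 0.8, 0.7)), n1)
  expect_equal(n_instances(chain), 1)
  expect_identical(chain$masks[[1]], a | b | cc)
})

test_that("uncovered foreground regions follow rules (a), (b), (c)", {
  H <- 24; W <- 24
  img <- matrix(0, H, W)
  cells_masks <- list(mask_from(3:8, 3:8, H, W), mask_from(3:8, 16:21, H, W))
  img[cells_masks[[1]] | cells_masks[[2]]] <- 1
  cfg <- postprocess_config(min_region_area = 4, foreground_threshold = 0.5)

  # (a) residual adjacent to exactly one cell is appended to it
  img_a <- img
  img_a[9:12, 3:8] <- 1   # block hanging off cell 1
  cells <- instance_set(cells_masks, score = c(0.9, 0.8))
  out_a <- recover_uncovered_regions(img_a, cells, cfg)
  expect_equal(n_instances(out_a), 2)
  expect_equal(sum(out_a$masks[[1]]), sum(cells_masks[[1]]) + 4 * 6)
  expect_identical(out_a$masks[[2]], cells_masks[[2]])

  # (b) residual bridging two cells is dropped
  img_b <- img
  img_b[5:6, 9:15] <- 1   # bridge between the two cells
  out_b <- recover_uncovered_regions(img_b, cells, cfg)
  expect_equal(n_instances(out_b), 2)
  expect_identical(out_b$masks[[1]], cells_masks[[1]])
  expect_identical(out_b$masks[[2]], cells_masks[[2]])

  # (c) isolated residual becomes a new instance
  img_c <- img
  img_c[16:20, 3:7] <- 1
  out_c <- recover_uncovered_regions(img_c, cells, cfg)
  expect_equal(n_instances(out_c), 3)

  # residual below min_region_area is discarded
  img_d <- img
  img_d[20, 20] <- 1
  out_d <- recover_uncovered_regions(img_d, cells,
                                     postprocess_config(min_region_area = 10,
                                                        foreground_threshold = 0.5))
  expect_equal(n_instances(out_d), 2)

  # predictions covering all foreground: identity
  out_e <- recover_uncovered_regions(img, cells, cfg)
  expect_identical(lapply(out_e$masks, identity), cells_masks)
})

test_that("cells expand to cover their nuclei; orphans become cells", {
  cell <- mask_from(2:7, 2:7)
  half_in <- mask_from(5:8, 4:5)       # nucleus sticking out of the cell
  orphan <- mask_from(9:11, 9:11)
  nuclei <- instance_set(list(half_in, orphan), class = "nucleus")
  cells <- instance_set(list(cell), score = 0.9)
  out <- expand_cells_to_nuclei(cells, nuclei)
  expect_equal(n_instances(out), 2)
  expect_true(all(out$masks[[1]][half_in]))
  expect_identical(out$masks[[2]], orphan)

  # fully covered nuclei: no-op
  nuc_in <- instance_set(list(mask_from(3:4, 3:4)), class = "nucleus")
  expect_identical(expand_cells_to_nuclei(cells, nuc_in)$masks[[1]], cell)
})

test_that("full postprocess is idempotent and covers every nucleus", {
  set.seed(5)
  for (seed in c(61, 62)) {
    s <- simulate_scene(micro_scene_config(seed = seed, noise_sd = 0))
    gt <- s$cell_truth
    # corrupt the prediction: split the first cell vertically, drop the last
    first <- gt$masks[[1]]
    cols <- which(colSums(first) > 0)
    mid <- cols[ceiling(length(cols) / 2)]
    left <- first; left[, mid:ncol(first)] <- FALSE
    right <- first; right[, 1:(mid - 1)] <- FALSE
    masks <- c(list(left, right), gt$masks[-c(1, n_instances(gt))])
    preds <- instance_set(Filter(any, masks),
                          score = runif(length(Filter(any, masks))))
    cfg <- postprocess_config(min_region_area = 20,
                              foreground_threshold = 0.3)
    once <- postprocess(preds, s$nucleus_truth, s$image_pair$cell, cfg)
    twice <- postprocess(once, s$nucleus_truth, s$image_pair$cell, cfg)
    expect_equal(n_instances(twice), n_instances(once))
    expect_identical(lapply(twice$masks, identity),
                     lapply(once$masks, identity))
    # every nucleus pixel covered by exactly one cell instance
    for (nm in s$nucleus_truth$masks) {
      cover <- Reduce(`+`, lapply(once$masks, function(cm) (cm & nm) * 1))
      expect_true(all(cover[nm] == 1))
    }
  }
})

test_that("a deliberately split cell is re-merged and empty predictions recover one cell per nucleus", {
  s <- simulate_scene(micro_scene_config(seed = 71, noise_sd = 0,
                                         multinucleate_rate = 0))
  gt <- s$cell_truth
  first <- gt$masks[[1]]
  rows <- which(rowSums(first) > 0)
  mid <- rows[ceiling(length(rows) / 2)]
  top <- first; top[mid:nrow(first), ] <- FALSE
  bot <- first; bot[1:(mid - 1), ] <- FALSE
  # nucleus of cell 1 must intersect both halves for the merge rule to fire
  nuc1 <- s$nucleus_truth$masks[[which(s$nucleus_to_cell ==
                                         gt$meta$label[1])[1]]]
  if (any(nuc1 & top) && any(nuc1 & bot)) {
    preds <- instance_set(c(list(top, bot), gt$masks[-1]),
                          score = runif(n_instances(gt) + 1))
    cfg <- postprocess_config(min_region_area = 20,
                              foreground_threshold = 0.3)
    out <- postprocess(preds, s$nucleus_truth, s$image_pair$cell, cfg)
    expect_equal(n_instances(out), n_instances(preds) - 1)
  }

  empty <- empty_instance_set(dim(s$image_pair$cell), "cell")
  out2 <- expand_cells_to_nuclei(empty, s$nucleus_truth)
  expect_equal(n_instances(out2), n_instances(s$nucleus_truth))
  for (i in seq_len(n_instances(out2))) {
    expect_identical(out2$masks[[i]], s$nucleus_truth$masks[[i]])
  }
})
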
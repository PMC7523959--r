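test_that("threshold segmentation handles blanks, counts and area filter", {
  cfg <- bootstrap_config(threshold_method = "fixed", fixed_threshold = 0.5,
                          morphology_radius = 0, min_instance_area = 1)
  expect_equal(n_instances(threshold_segment(matrix(0, 20, 20), cfg)), 0)

  # two 3-px components die under a 5-px minimum area
  img <- matrix(0, 20, 20)
  img[2, 2:4] <- 1
  img[10, 10:12] <- 1
  cfg5 <- bootstrap_config(threshold_method = "fixed", fixed_threshold = 0.5,
                           morphology_radius = 0, min_instance_area = 5)
  expect_equal(n_instances(threshold_segment(img, cfg5)), 0)
  expect_equal(n_instances(threshold_segment(img, cfg)), 2)

  expect_error(bootstrap_config(threshold_method = "fixed"), "required")
  expect_error(threshold_segment(matrix(c(1, NA), 2, 2), cfg), "finite")
})

test_that("threshold segmentation recovers the true component count", {
  cfg0 <- micro_scene_config(seed = 31, cluster_fraction = 0, noise_sd = 0,
                             contact_attenuation = 0)
  s <- simulate_scene(cfg0)
  iset <- threshold_segment(s$image_pair$cell,
                            bootstrap_config(threshold_method = "fixed",
                                             fixed_threshold = 0.3))
  truth_components <- max(EBImage::bwlabel(
    EBImage::Image((as_label_matrix(s$cell_truth) > 0) * 1)))
  expect_equal(n_instances(iset), truth_components)
})

test_that("nearest-nucleus split partitions exactly with the tie rule", {
  # single nucleus: identity
  cell <- mask_from(2:6, 2:6, 8, 8)
  nuc <- instance_set(list(mask_from(3:4, 3:4, 8, 8)), class = "nucleus")
  expect_identical(split_multinucleate(cell, nuc), list(cell))

  # 1x10 pixel row with point nuclei at columns 3 and 8 (1-based):
  # columns 1-5 go to the first nucleus, 6-10 to the second
  row <- matrix(TRUE, 1, 10)
  n1 <- matrix(FALSE, 1, 10); n1[1, 3] <- TRUE
  n2 <- matrix(FALSE, 1, 10); n2[1, 8] <- TRUE
  sp <- split_multinucleate(row, instance_set(list(n1, n2),
                                              class = "nucleus"))
  expect_equal(which(sp[[1]]), 1:5)
  expect_equal(which(sp[[2]]), 6:10)

  # symmetric 1x9 row, nuclei at columns 2 and 8: the equidistant middle
  # column joins the lower label
  row9 <- matrix(TRUE, 1, 9)
  m1 <- matrix(FALSE, 1, 9); m1[1, 2] <- TRUE
  m2 <- matrix(FALSE, 1, 9); m2[1, 8] <- TRUE
  sp9 <- split_multinucleate(row9, instance_set(list(m1, m2),
                                                class = "nucleus"))
  expect_true(sp9[[1]][1, 5])
  expect_false(sp9[[2]][1, 5])

  # exact partition property on irregular shapes
  set.seed(13)
  cellr <- mask_from(2:11, 2:11) | mask_from(5:8, 10:12)
  nucs <- instance_set(list(mask_from(3:4, 3:4), mask_from(8:9, 8:9),
                            mask_from(6:7, 11:12)), class = "nucleus")
  parts <- split_multinucleate(cellr, nucs)
  expect_equal(Reduce(`+`, lapply(parts, sum)), sum(cellr))
  expect_identical(Reduce(`|`, parts), cellr)
  for (i in seq_along(parts)) {
    for (j in seq_len(i - 1)) expect_false(any(parts[[i]] & parts[[j]]))
  }

  # no intersecting nucleus: unchanged with a warning
  far <- instance_set(list(mask_from(1, 1, 20, 20)), class = "nucleus")
  expect_warning(out <- split_multinucleate(mask_from(10:12, 10:12, 20, 20),
                                            far), "no intersecting")
  expect_true(attr(out, "orphan"))
})

test_that("bootstrap pipeline is a self-consistency oracle on clean scenes", {
  cfg0 <- micro_scene_config(seed = 41, cluster_fraction = 0, noise_sd = 0,
                             contact_attenuation = 0)
  s <- simulate_scene(cfg0)
  bt <- bootstrap_ground_truth(
    s$image_pair, bootstrap_config(threshold_method = "fixed",
                                   fixed_threshold = 0.3))
  expect_equal(n_instances(bt$cells), n_instances(s$cell_truth))
  expect_equal(n_instances(bt$nuclei), n_instances(s$nucleus_truth))
  for (i in seq_len(n_instances(bt$cells))) {
    best <- max(vapply(s$cell_truth$masks, mask_iou,
                       numeric(1), b = bt$cells$masks[[i]]))
    expect_gte(best, 0.95)
  }
})

test_that("a two-nucleus cell is split into two instances", {
  cfg <- micro_scene_config(seed = 52, n_cells = 3, cluster_fraction = 0,
                            noise_sd = 0, contact_attenuation = 0,
                            multinucleate_rate = 1)
  s <- simulate_scene(cfg)
  two_nuc <- sum(table(s$nucleus_to_cell) == 2)
  expect_gt(two_nuc, 0)
  bt <- bootstrap_ground_truth(
    s$image_pair, bootstrap_config(threshold_method = "fixed",
                                   fixed_threshold = 0.3))
  expect_equal(n_instances(bt$cells),
               n_instances(s$cell_truth) + two_nuc)
})

test_that("an empty image bootstraps to two empty sets", {
  blank <- list(nucleus = matrix(0, 64, 64), cell = matrix(0, 64, 64))
  bt <- bootstrap_ground_truth(blank,
                               bootstrap_config(threshold_method = "fixed",
                                                fixed_threshold = 0.5))
  expect_equal(n_instances(bt$cells), 0)
  expect_equal(n_instances(bt$nuclei), 0)
})
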
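test_that("empty scene request yields blank truth", {
  s <- sample_geometry(micro_scene_config(seed = 1, n_cells = 0))
  expect_equal(n_instances(s$cell_truth), 0)
  expect_equal(n_instances(s$nucleus_truth), 0)
  expect_length(s$nucleus_to_cell, 0)
})

test_that("instance counts and nucleus-cell mapping are exact", {
  s <- sample_geometry(micro_scene_config(seed = 2, multinucleate_rate = 0))
  expect_equal(n_instances(s$cell_truth), 5)
  expect_equal(n_instances(s$nucleus_truth), 5)
  # bijective nucleus -> cell mapping when no cell is multinucleate
  expect_equal(sort(unname(s$nucleus_to_cell)),
               sort(s$cell_truth$meta$label))
})

test_that("every nucleus lies inside its cell, for many seeds", {
  for (seed in c(3, 17, 91)) {
    s <- sample_geometry(micro_scene_config(seed = seed,
                                            multinucleate_rate = 0.4))
    lab <- as_label_matrix(s$cell_truth)
    for (i in seq_len(n_instances(s$nucleus_truth))) {
      cl <- s$nucleus_to_cell[[as.character(i)]]
      expect_true(all(lab[s$nucleus_truth$masks[[i]]] == cl))
    }
    expect_equal(n_instances(s$cell_truth), s$config$n_cells)
  }
})

test_that("full clustering makes every cell touch another cell", {
  s <- sample_geometry(micro_scene_config(seed = 5, n_cells = 4,
                                          cluster_fraction = 1))
  lab <- as_label_matrix(s$cell_truth)
  adj <- fpfuse:::label_adjacency(lab)
  touched <- sort(unique(as.vector(adj)))
  expect_equal(touched, sort(s$cell_truth$meta$label))
})

test_that("rendering is deterministic and respects the noiseless limit", {
  cfg <- micro_scene_config(seed = 8)
  s1 <- simulate_scene(cfg)
  s2 <- simulate_scene(cfg)
  expect_identical(s1$image_pair, s2$image_pair)

  cfg0 <- micro_scene_config(seed = 9, n_cells = 1, cluster_fraction = 0,
                             multinucleate_rate = 0, noise_sd = 0,
                             contact_attenuation = 0)
  s0 <- simulate_scene(cfg0)
  lab <- as_label_matrix(s0$cell_truth)
  vals <- sort(unique(as.vector(s0$image_pair$cell)))
  expect_equal(vals, c(cfg0$background_level, cfg0$cell_intensity))
  expect_true(all(s0$image_pair$cell[lab > 0] == cfg0$cell_intensity))
  expect_true(all(s0$image_pair$cell[lab == 0] == cfg0$background_level))
})

test_that("contact bands are attenuated by the configured factor", {
  cfg <- micro_scene_config(seed = 12, n_cells = 2, cluster_fraction = 1,
                            noise_sd = 0, contact_attenuation = 0.5)
  s <- simulate_scene(cfg)
  lab <- as_label_matrix(s$cell_truth)
  band <- fpfuse:::contact_band(lab)
  expect_gt(sum(band), 0)
  expect_equal(mean(s$image_pair$cell[band]),
               0.5 * cfg$cell_intensity, tolerance = 1e-12)
  interior <- lab > 0 & !band
  expect_equal(mean(s$image_pair$cell[interior]), cfg$cell_intensity)
})

test_that("two-nucleus frequency converges to the configured rate", {
  r <- 0.25
  counts2 <- 0; total <- 0
  for (seed in 1:40) {
    s <- sample_geometry(scene_config(
      image_height = 256, image_width = 256, n_cells = 25,
      cluster_fraction = 0, multinucleate_rate = r,
      nucleus_radius_range = c(3, 4), cell_radius_range = c(10, 14),
      seed = 1000 + seed))
    per_cell <- table(factor(s$nucleus_to_cell,
                             levels = s$cell_truth$meta$label))
    counts2 <- counts2 + sum(per_cell == 2)
    total <- total + length(per_cell)
  }
  expect_equal(total, 1000)
  # binomial 3.5-sigma band around r at n = 1000
  expect_lt(abs(counts2 / total - r), 3.5 * sqrt(r * (1 - r) / total))
})

test_that("infeasible packing raises an explicit error", {
  expect_error(sample_geometry(scene_config(
    image_height = 64, image_width = 64, n_cells = 40,
    nucleus_radius_range = c(4, 6), cell_radius_range = c(14, 20),
    seed = 1)), "pack")
})

test_that("datasets round-trip through disk losslessly", {
  dir <- withr::local_tempdir()
  samples <- generate_dataset(3, micro_scene_config(), seed = 21)
  manifest <- write_dataset(samples, dir, n_train = 2)
  expect_equal(nrow(manifest), 3)
  expect_equal(sum(manifest$split == "train"), 2)
  expect_equal(sum(manifest$split == "test"), 1)
  m2 <- read_manifest(dir)
  expect_equal(m2$sample, manifest$sample)
  for (i in 1:3) {
    lab <- read_label_mask(manifest$cell_mask[i])
    expect_identical(lab, as_label_matrix(samples[[i]]$cell_truth))
    nlab <- read_label_mask(manifest$nucleus_mask[i])
    expect_identical(nlab, as_label_matrix(samples[[i]]$nucleus_truth))
    pair <- read_image_pair(manifest$nucleus[i], manifest$cell[i])
    # intensities are stored at 16-bit depth
    expect_lt(max(abs(pair$cell - samples[[i]]$image_pair$cell)), 1 / 65535)
    # a second write/read of the quantized raster is bit-exact
    p2 <- file.path(dir, "rt.tif")
    write_intensity_tiff(pair$cell, p2)
    expect_identical(tiff::readTIFF(p2), tiff::readTIFF(manifest$cell[i]))
  }
})
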
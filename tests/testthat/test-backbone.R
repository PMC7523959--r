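test_that("stage outputs reproduce the published layer table at 224 input", {
  set.seed(1)
  bb <- build_backbone(backbone_config())
  feats <- bb$fwd(fpfuse:::nn_const(array(0, c(224, 224, 1, 1))))
  sizes <- vapply(feats, function(f) dim(f$value)[1], 0)
  chans <- vapply(feats, function(f) dim(f$value)[3], 0)
  expect_equal(unname(sizes), c(56, 28, 14, 7))
  expect_equal(unname(chans), c(128, 256, 512, 1024))
})

test_that("stage outputs scale equivariantly with input size", {
  set.seed(1)
  bb <- build_backbone(backbone_config(width_multiplier = 0.125))
  feats <- bb$fwd(fpfuse:::nn_const(array(0, c(512, 512, 1, 1))))
  expect_equal(unname(vapply(feats, function(f) dim(f$value)[1], 0)),
               c(128, 64, 32, 16))
  expect_error(bb$fwd(fpfuse:::nn_const(array(0, c(16, 64, 1, 1)))),
               "32 px")
})

test_that("parameter counts match an independent layer-by-layer tally", {
  set.seed(1)
  reduced <- build_backbone(backbone_config())
  expect_equal(count_parameters(reduced),
               tally_backbone_params(1, 64, c(32, 64, 128, 256),
                                     c(2, 2, 3, 2)))
  original <- build_backbone(backbone_config(width_multiplier = 1,
                                             blocks = c(3, 4, 6, 3)))
  expect_equal(count_parameters(original),
               tally_backbone_params(1, 64, c(64, 128, 256, 512),
                                     c(3, 4, 6, 3)))
  # conv1 alone: 7x7 single-channel kernel, 64 filters, no bias
  expect_equal(length(reduced$params[["conv1.w"]]$value), 7 * 7 * 1 * 64)
  # determinism
  set.seed(1)
  again <- build_backbone(backbone_config())
  expect_identical(count_parameters(again), count_parameters(reduced))
})

test_that("convolution parameters scale quadratically with width", {
  conv_weights <- function(bb) {
    nms <- grep("\\.w$", ls(bb$params), value = TRUE)
    nms <- setdiff(nms, "conv1.w")  # the stem does not scale with width
    sum(vapply(nms, function(nm) length(bb$params[[nm]]$value), 0))
  }
  set.seed(1)
  narrow <- build_backbone(backbone_config(width_multiplier = 0.25))
  set.seed(1)
  wide <- build_backbone(backbone_config(width_multiplier = 0.5))
  ratio <- conv_weights(wide) / conv_weights(narrow)
  expect_gt(ratio, 3.5)
  expect_lt(ratio, 4.3)
})

test_that("first-layer adaptation duplicates and halves the kernel", {
  set.seed(2)
  w1 <- array(rnorm(7 * 7 * 1 * 8), c(7, 7, 1, 8))
  w2 <- adapt_first_layer_two_channels(w1)
  expect_equal(dim(w2), c(7, 7, 2, 8))
  # channel sum reproduces the original kernel
  expect_equal(w2[, , 1, ] + w2[, , 2, ], w1[, , 1, ])

  # feeding the same image into both channels gives the original response
  img <- array(rnorm(20 * 20), c(20, 20, 1, 1))
  img2 <- array(c(img, img), c(20, 20, 2, 1))
  y1 <- fpfuse:::.conv2d_fwd(img, w1, numeric(0), 2L, 3L)
  y2 <- fpfuse:::.conv2d_fwd(img2, w2, numeric(0), 2L, 3L)
  expect_equal(y2, y1, tolerance = 1e-12)

  # a zeroed second channel halves the response
  imgz <- array(c(img, 0 * img), c(20, 20, 2, 1))
  yz <- fpfuse:::.conv2d_fwd(imgz, w2, numeric(0), 2L, 3L)
  expect_equal(yz, y1 / 2, tolerance = 1e-12)

  expect_error(adapt_first_layer_two_channels(array(0, c(7, 7, 3, 8))),
               "kernel")
})

test_that("checkpoints round-trip parameter values exactly", {
  set.seed(3)
  bb <- build_backbone(backbone_config(width_multiplier = 0.125))
  path <- withr::local_tempfile(fileext = ".rds")
  save_checkpoint(bb, path)
  bb$params[["conv1.w"]]$value[] <- 0
  load_checkpoint(bb, path)
  expect_gt(max(abs(bb$params[["conv1.w"]]$value)), 0)
  snap <- readRDS(path)
  expect_identical(snap[["conv1.w"]], bb$params[["conv1.w"]]$value)
})
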
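test_that("the three-phase schedule reproduces the published budgets", {
  sched <- make_schedule(train_config())
  expect_equal(sched$iters, c(100000L, 250000L, 500000L))
  expect_equal(sched$lr, c(0.001, 0.001, 0.0001))
  micro <- make_schedule(train_config(scale = 1 / 1000))
  expect_equal(micro$iters, c(100L, 250L, 500L))
  expect_error(train_config(phase_iters = c(0, 1, 1)), "positive")
  expect_error(train_config(crop_size = 100), "64")
})

test_that("phase trainable sets freeze the right backbone stages", {
  set.seed(1)
  model <- fpf_model("cell_only",
                     backbone = backbone_config(width_multiplier = 0.125),
                     config = micro_model_config(), seed = 2)
  t1 <- fpfuse:::trainable_set(model, "heads")
  t2 <- fpfuse:::trainable_set(model, "conv4_up")
  t3 <- fpfuse:::trainable_set(model, "all")
  bb <- grep("^backbone\\.", names(t1), value = TRUE)
  expect_false(any(unlist(t1[bb])))
  expect_true(all(unlist(t1[grep("^rpn\\.|^fpn\\.|^box_head\\.|^mask_head\\.",
                                 names(t1))])))
  deep <- grep("^backbone\\.conv[45]\\.", names(t2), value = TRUE)
  shallow <- grep("^backbone\\.(conv1|bn1|conv[23])\\.", names(t2),
                  value = TRUE)
  expect_true(all(unlist(t2[deep])))
  expect_false(any(unlist(t2[shallow])))
  expect_true(all(unlist(t3)))
})

test_that("augmentation preserves masks and is involutive where expected", {
  s <- simulate_scene(micro_scene_config(seed = 13))
  areas <- vapply(s$cell_truth$masks, sum, 0)

  none <- augment(s, c(crop = FALSE, flip = FALSE, rot90 = FALSE))
  expect_identical(none$image_pair, s$image_pair)

  hflip <- function(m) m[, rev(seq_len(ncol(m))), drop = FALSE]
  once <- fpfuse:::transform_sample(s, hflip)
  twice <- fpfuse:::transform_sample(once, hflip)
  expect_identical(twice$image_pair$cell, s$image_pair$cell)
  expect_identical(twice$cell_truth$masks, s$cell_truth$masks)
  expect_equal(vapply(once$cell_truth$masks, sum, 0), areas)

  set.seed(3)
  aug <- augment(s, c(crop = FALSE, flip = TRUE, rot90 = TRUE))
  expect_equal(sort(vapply(aug$cell_truth$masks, sum, 0)), sort(areas))

  # a crop larger than the frame pads by reflection first
  small <- simulate_scene(micro_scene_config(seed = 14, image_height = 96,
                                             image_width = 96, n_cells = 3))
  set.seed(4)
  cropped <- augment(small, c(crop = TRUE, flip = FALSE, rot90 = FALSE),
                     crop_size = 128)
  expect_equal(dim(cropped$image_pair$cell), c(128, 128))
})

test_that("training is deterministic and updates only the scheduled sets", {
  run_once <- function() {
    model <- fpf_model("cell_only",
                       backbone = backbone_config(width_multiplier = 0.125),
                       config = micro_model_config(), seed = 5)
    s <- simulate_scene(micro_scene_config(seed = 15))
    cfg <- train_config(scale = 6 / 850000, crop_size = 128,
                        augment_flags = c(crop = FALSE, flip = FALSE,
                                          rot90 = FALSE), seed = 9)
    train_model(model, list(s), cfg, log_every = 1)
  }
  m1 <- run_once()
  m2 <- run_once()
  expect_identical(fpfuse:::params_snapshot(m1), fpfuse:::params_snapshot(m2))
  h <- tidy(m1)
  expect_true(all(c("total", "l_mask", "iteration", "phase") %in% names(h)))
  expect_equal(h$total,
               h$l_rpn_cls + 2 * h$l_rpn_box + h$l_cls + 2 * h$l_box +
                 2 * h$l_mask)
})

test_that("heads-phase training leaves the backbone untouched", {
  set.seed(6)
  model <- fpf_model("cell_only",
                     backbone = backbone_config(width_multiplier = 0.125),
                     config = micro_model_config(), seed = 7)
  before <- fpfuse:::params_snapshot(model)
  s <- simulate_scene(micro_scene_config(seed = 16))
  cfg <- train_config(scale = 2 / 850000, crop_size = 128,
                      augment_flags = c(crop = FALSE, flip = FALSE,
                                        rot90 = FALSE), seed = 10)
  # only phase 1 runs within two iterations (budgets 1, 1, ...) -- actually
  # the scaled schedule is (1, 1, 1); check stage-wise changes per phase via
  # a single phase-1 step instead
  sched <- make_schedule(cfg)
  expect_equal(sched$iters, c(1L, 1L, 1L))
  trainable <- fpfuse:::trainable_set(model, "heads")
  state <- new.env(parent = emptyenv())
  b <- compute_loss(model, s$image_pair, s$cell_truth)
  fpfuse:::zero_grads(model$params)
  fpfuse:::nn_backward(attr(b, "total_node"))
  fpfuse:::sgd_step(model$params, lr = 0.001, state = state,
                    trainable = trainable,
                    decay_mask = fpfuse:::decay_mask_for(model))
  after <- fpfuse:::params_snapshot(model)
  bb <- grep("^backbone\\.", names(before), value = TRUE)
  expect_identical(before[bb], after[bb])
  changed <- vapply(grep("^rpn\\.", names(before), value = TRUE),
                    function(nm) !identical(before[[nm]], after[[nm]]), TRUE)
  expect_true(any(changed))
})
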
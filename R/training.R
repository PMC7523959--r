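#' Training configuration
#'
#' Three-phase schedule with momentum SGD: heads (plus RPN and pyramid) for
#' 100,000 iterations at learning rate 0.001, then backbone layers conv4 and
#' deeper for 250,000 iterations, then the whole network for 500,000
#' iterations at 0.0001. Both regression losses and the mask loss are
#' weighted by a factor of 2. All phase budgets scale jointly through
#' `scale` for desk-size runs.
#'
#' @param learning_rate Base learning rate (phases 1-2).
#' @param momentum SGD momentum.
#' @param weight_decay L2 penalty on convolution/fc weights.
#' @param phase_iters Iteration budgets of the three phases.
#' @param final_lr Learning rate of phase 3.
#' @param scale Single factor applied to all phase budgets (e.g. `1/1000`
#'   for a micro run).
#' @param crop_size Square training crop in pixels (multiple of 64).
#' @param augment_flags Logical flags: `crop`, `flip`, `rot90`.
#' @param seed Training seed (sampling, augmentation).
#' @return A `train_config` list.
#' @export
train_config <- function(learning_rate = 0.001, momentum = 0.9,
                         weight_decay = 0.0001,
                         phase_iters = c(heads = 100000, conv4_up = 250000,
                                         all = 500000),
                         final_lr = 0.0001, scale = 1,
                         crop_size = 512,
                         augment_flags = c(crop = TRUE, flip = TRUE,
                                           rot90 = TRUE),
                         seed = 1L) {
  if (any(phase_iters <= 0)) stop("phase budgets must be positive")
  if (learning_rate <= 0 || final_lr <= 0) stop("learning rates must be positive")
  if (crop_size %% 64 != 0) stop("crop_size must be divisible by 64")
  structure(as.list(environment()), class = "train_config")
}

#' Build the three-phase schedule from a training configuration
#'
#' @param config A [train_config()].
#' @return Tibble with one row per phase: `phase`, `iters`, `lr`,
#'   `trainable` (descriptor: `heads`, `conv4_up`, `all`).
#' @export
make_schedule <- function(config = train_config()) {
  iters <- pmax(1, round(config$phase_iters * config$scale))
  if (any(iters <= 0)) stop("zero-length phase after scaling")
  tibble::tibble(
    phase = 1:3,
    iters = as.integer(iters),
    lr = c(config$learning_rate, config$learning_rate, config$final_lr),
    trainable = c("heads", "conv4_up", "all")
  )
}

# which parameters train in a given phase; the frozen nucleus branch is
# excluded everywhere (its nodes have requires = FALSE anyway)
trainable_set <- function(model, descriptor) {
  nms <- names(model$params)
  is_nucleus <- grepl("^nucleus_", nms)
  in_backbone <- grepl("^backbone\\.", nms)
  stage <- ifelse(in_backbone,
                  sub("^backbone\\.(conv1|bn1|conv[2-5])\\..*$", "\\1", nms),
                  "")
  deep <- stage %in% c("conv4", "conv5")
  sel <- switch(descriptor,
    heads = !in_backbone,
    conv4_up = !in_backbone | deep,
    all = rep(TRUE, length(nms)),
    stop("unknown trainable-set descriptor: ", descriptor))
  stats::setNames(as.list(sel & !is_nucleus), nms)
}

decay_mask_for <- function(model) {
  nms <- names(model$params)
  stats::setNames(as.list(grepl("\\.w$", nms)), nms)
}

#' Augment a training sample
#'
#' Random crop to `crop_size` (reflect-padding images smaller than the
#' crop), horizontal/vertical flips, and 90-degree rotations; masks and
#' boxes are transformed consistently with the channels.
#'
#' @param sample A `synthetic_sample`-like list (`image_pair` plus truth
#'   `instance_set`s).
#' @param flags Named logical flags `crop`, `flip`, `rot90`.
#' @param crop_size Target crop side.
#' @return The transformed sample.
#' @export
augment <- function(sample, flags = c(crop = TRUE, flip = TRUE,
                                      rot90 = TRUE),
                    crop_size = 512) {
  s <- sample
  if (isTRUE(flags[["crop"]])) {
    s <- reflect_pad_sample(s, crop_size)
    H <- nrow(s$image_pair$cell); W <- ncol(s$image_pair$cell)
    y0 <- if (H > crop_size) sample.int(H - crop_size, 1) else 1L
    x0 <- if (W > crop_size) sample.int(W - crop_size, 1) else 1L
    s <- crop_sample(s, y0, y0 + crop_size - 1L, x0, x0 + crop_size - 1L)
  }
  if (isTRUE(flags[["flip"]])) {
    if (stats::runif(1) < 0.5) s <- transform_sample(s, function(m) m[, rev(seq_len(ncol(m))), drop = FALSE])
    if (stats::runif(1) < 0.5) s <- transform_sample(s, function(m) m[rev(seq_len(nrow(m))), , drop = FALSE])
  }
  if (isTRUE(flags[["rot90"]])) {
    k <- sample.int(4, 1) - 1L
    for (i in seq_len(k)) {
      s <- transform_sample(s, function(m) t(m[rev(seq_len(nrow(m))), , drop = FALSE]))
    }
  }
  s
}

transform_sample <- function(s, f) {
  tf_set <- function(iset) {
    if (n_instances(iset) == 0) {
      m0 <- f(matrix(FALSE, iset$shape[1], iset$shape[2]))
      return(empty_instance_set(dim(m0), iset$meta$class[1] %||% "cell"))
    }
    instance_set(lapply(iset$masks, f), score = iset$meta$score,
                 class = iset$meta$class, label = iset$meta$label)
  }
  s$image_pair <- lapply(s$image_pair, f)
  s$cell_truth <- tf_set(s$cell_truth)
  s$nucleus_truth <- tf_set(s$nucleus_truth)
  if (!is.null(s$config)) {
    s$config$image_height <- nrow(s$image_pair$cell)
    s$config$image_width <- ncol(s$image_pair$cell)
  }
  s
}

reflect_pad_sample <- function(s, min_size) {
  H <- nrow(s$image_pair$cell); W <- ncol(s$image_pair$cell)
  if (H >= min_size && W >= min_size) return(s)
  py <- max(0L, min_size - H); px <- max(0L, min_size - W)
  idx_y <- c(seq_len(H), rev(seq_len(H)))[seq_len(H + py)]
  idx_x <- c(seq_len(W), rev(seq_len(W)))[seq_len(W + px)]
  transform_sample(s, function(m) m[idx_y, idx_x, drop = FALSE])
}

gt_for_class <- function(sample, class_name) {
  if (class_name == "nucleus") sample$nucleus_truth else sample$cell_truth
}

#' Train a model on a dataset of samples
#'
#' Runs the three-phase schedule with momentum SGD (single image per step,
#' single worker, deterministic given `config$seed`). For the fpf variant a
#' stage-1 nucleus model must already be merged into the model (its
#' parameters stay bit-identical throughout — the freezing contract).
#'
#' @param model An [fpf_model()].
#' @param dataset List of rendered `synthetic_sample`s (or compatible).
#' @param config A [train_config()].
#' @param log_every Record the loss bundle every this many iterations.
#' @param on_iteration Optional callback `function(iter, bundle)`.
#' @return The trained model (updated in place and returned) with a
#'   `history` tibble attribute: iteration, phase, loss terms, total.
#' @export
train_model <- function(model, dataset, config = train_config(),
                        log_every = 10, on_iteration = NULL) {
  if (model$variant == "fpf" && is.null(model$nucleus_branch)) {
    stop("fpf training requires a nucleus branch")
  }
  if (model$variant == "fpf" &&
      any(vapply(prefix_params("x", model$nucleus_branch$backbone$params),
                 function(p) p$requires, TRUE))) {
    stop("nucleus branch must be frozen during fpf training")
  }
  sched <- make_schedule(config)
  set.seed(config$seed)
  state <- new.env(parent = emptyenv())
  decay_mask <- decay_mask_for(model)
  history <- list()
  iter_global <- 0L
  crop_flags <- config$augment_flags
  for (ph in seq_len(nrow(sched))) {
    trainable <- trainable_set(model, sched$trainable[ph])
    for (it in seq_len(sched$iters[ph])) {
      iter_global <- iter_global + 1L
      s <- dataset[[sample.int(length(dataset), 1)]]
      if (any(unlist(crop_flags))) {
        s <- augment(s, crop_flags,
                     crop_size = min(config$crop_size,
                                     nrow(s$image_pair$cell)))
      }
      gt <- gt_for_class(s, model$class_name)
      bundle <- compute_loss(model, s$image_pair, gt)
      total <- attr(bundle, "total_node")
      zero_grads(model$params)
      nn_backward(total)
      sgd_step(model$params, lr = sched$lr[ph],
               momentum = config$momentum,
               weight_decay = config$weight_decay,
               state = state, trainable = trainable,
               decay_mask = decay_mask)
      if (iter_global %% log_every == 0 || it == sched$iters[ph]) {
        history[[length(history) + 1]] <- dplyr::mutate(
          glance(bundle), iteration = iter_global, phase = ph)
      }
      if (!is.null(on_iteration)) on_iteration(iter_global, bundle)
    }
  }
  attr(model, "history") <- dplyr::bind_rows(history)
  model
}

#' @rdname train_model
#' @param x A trained `fpf_model`.
#' @param ... Unused.
#' @exportS3Method generics::tidy
tidy.fpf_model <- function(x, ...) {
  h <- attr(x, "history")
  if (is.null(h)) tibble::tibble() else h
}
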
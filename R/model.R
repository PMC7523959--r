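#' Detection model configuration
#'
#' Hyper-parameters of the two-stage detector built on the reduced backbone
#' and feature pyramid: anchor layout, proposal budgets, RoI sampling, head
#' widths, and inference-time filtering.
#'
#' @param pyramid_width Channels per pyramid level (default 256).
#' @param fc_dim Width of the two fully connected layers in the box head.
#' @param mask_channels,mask_convs Width and depth of the mask head.
#' @param anchor_scales Anchor side length per level P2..P6.
#' @param anchor_ratios Anchor aspect ratios.
#' @param rpn_pre_nms,rpn_post_nms_train,rpn_post_nms_test Proposal budgets
#'   before/after non-maximum suppression.
#' @param rpn_nms RPN NMS IoU threshold (default 0.7).
#' @param rpn_batch,rpn_pos_fraction Anchor sample size and positive
#'   fraction for the RPN loss.
#' @param roi_batch,roi_pos_fraction RoI sample size per image and positive
#'   fraction (default 512 at 1:3).
#' @param score_floor Minimum detection score kept before truncation.
#' @param det_nms Detection NMS IoU threshold (default 0.5).
#' @param max_detections Per-image detection budget (default 100).
#' @param mask_threshold Probability threshold for binarizing masks.
#' @param concat_projection For concat-mode fusion, apply a trainable 1x1
#'   projection back to `pyramid_width` so head shapes are merge-mode
#'   invariant.
#' @return A `model_config` list.
#' @export
model_config <- function(pyramid_width = 256, fc_dim = 1024,
                         mask_channels = 256, mask_convs = 4,
                         anchor_scales = c(32, 64, 128, 256, 512),
                         anchor_ratios = c(0.5, 1, 2),
                         rpn_pre_nms = 1000, rpn_post_nms_train = 200,
                         rpn_post_nms_test = 100, rpn_nms = 0.7,
                         rpn_batch = 128, rpn_pos_fraction = 0.5,
                         roi_batch = 512, roi_pos_fraction = 0.25,
                         score_floor = 0.05, det_nms = 0.5,
                         max_detections = 100, mask_threshold = 0.5,
                         concat_projection = TRUE) {
  structure(as.list(environment()), class = "model_config")
}

#' @rdname model_config
#' @details `micro_model_config()` is a narrow preset (pyramid width 128,
#'   small heads, reduced proposal budgets) sized for CPU-scale experiments
#'   on 128x128 synthetic scenes.
#' @export
micro_model_config <- function() {
  model_config(pyramid_width = 128, fc_dim = 256, mask_channels = 64,
               mask_convs = 2, rpn_pre_nms = 300, rpn_post_nms_train = 80,
               rpn_post_nms_test = 60, rpn_batch = 64, roi_batch = 32)
}

prefix_params <- function(prefix, env_or_list) {
  nms <- if (is.environment(env_or_list)) ls(env_or_list) else
    names(env_or_list)
  out <- stats::setNames(
    lapply(nms, function(nm) env_or_list[[nm]]),
    paste0(prefix, ".", nms))
  out
}

freeze_params <- function(params) {
  for (p in params) p$requires <- FALSE
  invisible(NULL)
}

#' Build a cell detection/segmentation model
#'
#' Assembles one of the three architecture variants:
#' \describe{
#'   \item{`cell_only`}{single-channel Mask R-CNN-style detector without any
#'     nucleus information (also used, on the nucleus channel, as the
#'     stage-1 nucleus model).}
#'   \item{`early_fusion`}{the same detector with a 2-channel input (cell
#'     stain + nucleus stain stacked).}
#'   \item{`fpf`}{feature pyramid fusion: a frozen nucleus branch (backbone
#'     + pyramid, initialized from a stage-1 nucleus model) merged
#'     level-by-level into the cell pyramid by addition or concatenation.}
#' }
#'
#' @param variant `"cell_only"`, `"early_fusion"` or `"fpf"`.
#' @param merge_mode `"add"` or `"concat"` (fpf only).
#' @param weighted_loss Use the Gaussian border [contour_weight_map()] in
#'   the mask loss.
#' @param backbone Cell-branch [backbone_config()]; `input_channels` is
#'   forced to 2 for `early_fusion`.
#' @param config A [model_config()].
#' @param nucleus_model Stage-1 nucleus model whose backbone and pyramid
#'   parameters seed the frozen nucleus branch (fpf only; required by
#'   [train_model()], optional here for architecture experiments).
#' @param class_name Foreground class of this model (`"cell"` or
#'   `"nucleus"`).
#' @param seed Seed for weight initialization.
#' @return An `fpf_model` object.
#' @export
fpf_model <- function(variant = c("cell_only", "early_fusion", "fpf"),
                      merge_mode = c("add", "concat"),
                      weighted_loss = FALSE,
                      backbone = backbone_config(),
                      config = model_config(),
                      nucleus_model = NULL,
                      class_name = "cell",
                      seed = 1L) {
  variant <- match.arg(variant)
  merge_mode <- match.arg(merge_mode)
  set.seed(seed)
  if (variant == "early_fusion") backbone$input_channels <- 2L
  if (variant != "early_fusion" && backbone$input_channels != 1) {
    stop("cell_only and fpf variants take single-channel backbones")
  }
  bb <- build_backbone(backbone)
  widths <- 4L * stage_widths(backbone)
  fpn <- build_fpn(in_channels = widths, pyramid_width = config$pyramid_width)
  params <- c(prefix_params("backbone", bb$params),
              prefix_params("fpn", fpn$params))

  nucleus_branch <- NULL
  fusion_proj <- NULL
  if (variant == "fpf") {
    nbb <- build_backbone(backbone_config(
      input_channels = 1, width_multiplier = backbone$width_multiplier,
      blocks = backbone$blocks, conv1_filters = backbone$conv1_filters))
    nfpn <- build_fpn(in_channels = widths,
                      pyramid_width = config$pyramid_width)
    if (!is.null(nucleus_model)) {
      params_restore(nbb, params_snapshot_prefixed(nucleus_model, "backbone"))
      params_restore(nfpn, params_snapshot_prefixed(nucleus_model, "fpn"))
    }
    freeze_params(prefix_params("x", nbb$params))
    freeze_params(prefix_params("x", nfpn$params))
    nucleus_branch <- list(backbone = nbb, fpn = nfpn)
    params <- c(params,
                prefix_params("nucleus_backbone", nbb$params),
                prefix_params("nucleus_fpn", nfpn$params))
    if (merge_mode == "concat" && config$concat_projection) {
      fusion_proj <- build_fusion_projection(config$pyramid_width)
      params <- c(params, prefix_params("fusion", attr(fusion_proj, "params")))
    }
  }

  rpn <- build_rpn_head(config$pyramid_width,
                        n_anchors = length(config$anchor_ratios))
  box_head <- build_box_head(config$pyramid_width, fc_dim = config$fc_dim)
  mask_head <- build_mask_head(config$pyramid_width,
                               channels = config$mask_channels,
                               n_conv = config$mask_convs)
  params <- c(params,
              prefix_params("rpn", rpn$params),
              prefix_params("box_head", box_head$params),
              prefix_params("mask_head", mask_head$params))

  structure(list(
    variant = variant, merge_mode = merge_mode,
    weighted_loss = weighted_loss,
    backbone = bb, fpn = fpn, nucleus_branch = nucleus_branch,
    fusion_proj = fusion_proj, rpn = rpn,
    box_head = box_head, mask_head = mask_head,
    params = params, config = config, backbone_config = backbone,
    class_name = class_name, seed = seed
  ), class = "fpf_model")
}

params_snapshot_prefixed <- function(model, prefix) {
  snap <- params_snapshot(model)
  sel <- grep(paste0("^", prefix, "\\."), names(snap), value = TRUE)
  stats::setNames(snap[sel], sub(paste0("^", prefix, "\\."), "", sel))
}

#' @export
print.fpf_model <- function(x, ...) {
  cat(sprintf("<fpf_model: %s%s%s, %s class, %s parameters>\n",
              x$variant,
              if (x$variant == "fpf") paste0(" (", x$merge_mode, ")") else "",
              if (x$weighted_loss) " + weighted loss" else "",
              x$class_name,
              format(count_parameters(x$params), big.mark = ",")))
  invisible(x)
}

model_input <- function(model, image_pair) {
  if (model$variant == "early_fusion") {
    if (!identical(dim(image_pair$nucleus), dim(image_pair$cell))) {
      stop("channel shapes differ")
    }
    x <- array(0, c(dim(image_pair$cell), 2, 1))
    x[, , 1, 1] <- image_pair$cell
    x[, , 2, 1] <- image_pair$nucleus
    x
  } else {
    ch <- if (model$class_name == "nucleus") image_pair$nucleus else
      image_pair$cell
    array(ch, c(dim(ch), 1, 1))
  }
}

# forward pass to the (possibly fused) feature pyramid
forward_pyramid <- function(model, image_pair) {
  x <- nn_const(model_input(model, image_pair))
  pyr <- model$fpn$fwd(model$backbone$fwd(x))
  if (model$variant == "fpf") {
    if (!identical(dim(image_pair$nucleus), dim(image_pair$cell))) {
      stop("channel shapes differ")
    }
    nx <- nn_const(array(image_pair$nucleus,
                         c(dim(image_pair$nucleus), 1, 1)))
    npyr <- model$nucleus_branch$fpn$fwd(model$nucleus_branch$backbone$fwd(nx))
    pyr <- fuse_pyramids(pyr, npyr, mode = model$merge_mode,
                         projection = model$fusion_proj)
  }
  pyr
}

model_anchors <- function(model, pyr) {
  strides <- model$fpn$strides
  lapply(seq_along(pyr), function(l) {
    d <- dim(pyr[[l]]$value)
    level_anchors(d[1], d[2], strides[l], model$config$anchor_scales[l],
                  model$config$anchor_ratios)
  })
}

# ---- training loss ----------------------------------------------------

sample_balanced <- function(pos_idx, neg_idx, total, pos_fraction) {
  n_pos <- min(length(pos_idx), round(total * pos_fraction))
  n_neg <- min(length(neg_idx), total - n_pos)
  pos <- if (length(pos_idx) > n_pos)
    sample(pos_idx, n_pos) else pos_idx
  neg <- if (length(neg_idx) > n_neg)
    sample(neg_idx, n_neg) else neg_idx
  list(pos = pos, neg = neg)
}

# RPN anchor targets: positives are anchors with IoU >= 0.7 to some box or
# the best anchor of each box; negatives have max IoU < 0.3.
rpn_targets <- function(anchors, gt_boxes) {
  n <- nrow(anchors)
  if (nrow(gt_boxes) == 0) {
    return(list(pos = integer(0), neg = seq_len(n),
                match = integer(0)))
  }
  ious <- box_iou_matrix(anchors, gt_boxes)
  best <- apply(ious, 1, max)
  match <- max.col(ious, ties.method = "first")
  pos <- which(best >= 0.7)
  for (g in seq_len(ncol(ious))) {
    m <- max(ious[, g])
    if (m > 0) pos <- union(pos, which(ious[, g] == m))
  }
  neg <- which(best < 0.3)
  list(pos = pos, neg = setdiff(neg, pos), match = match)
}

# differentiable gather of RPN outputs for the sampled anchors
gather_rpn <- function(rpn_nodes, level_sizes, n_anchors, sel) {
  offsets <- cumsum(c(0, head(level_sizes, -1)))
  score_nodes <- list(); delta_nodes <- list()
  order_kept <- integer(0)
  for (l in seq_along(rpn_nodes)) {
    local <- sel[sel > offsets[l] & sel <= offsets[l] + level_sizes[l]] -
      offsets[l]
    if (length(local) == 0) next
    order_kept <- c(order_kept,
                    which(sel > offsets[l] & sel <= offsets[l] + level_sizes[l]))
    d <- dim(rpn_nodes[[l]]$obj$value)
    hw <- d[1] * d[2]
    score_nodes[[length(score_nodes) + 1]] <-
      nd_gather_vec(rpn_nodes[[l]]$obj, local)
    a <- ceiling(local / hw)
    cell <- local - (a - 1L) * hw
    idx4 <- as.vector(vapply(seq_along(local), function(i) {
      cell[i] + hw * ((a[i] - 1L) * 4L + 0:3)
    }, numeric(4)))
    delta_nodes[[length(delta_nodes) + 1]] <-
      nd_gather_vec(rpn_nodes[[l]]$reg, idx4)
  }
  list(scores = score_nodes, deltas = delta_nodes, order = order_kept)
}

nd_cat_vec <- function(nodes) {
  lens <- vapply(nodes, function(n) length(n$value), 0L)
  v <- unlist(lapply(nodes, function(n) as.numeric(n$value)))
  out <- new_node(v, nodes)
  out$backfn <- function(g) {
    off <- 0L
    for (k in seq_along(nodes)) {
      accum_grad(nodes[[k]], g[off + seq_len(lens[k])])
      off <- off + lens[k]
    }
  }
  out
}

#' Compute the multi-task training loss for one sample
#'
#' Runs the full training-time forward pass (pyramid, RPN, RoI heads) and
#' assembles the loss bundle
#' \eqn{L = L_{rpn,cls} + 2 L_{rpn,box} + L_{cls} + 2 L_{box} + 2 L_{mask}}:
#' cross-entropy for classifications, smooth-L1 for both box regressions,
#' per-pixel binary cross-entropy on the 28x28 mask crops — optionally
#' multiplied by the border weight-map crop when the model was built with
#' `weighted_loss = TRUE` (both regression losses and the mask loss carry
#' the factor-2 weighting).
#'
#' @param model An [fpf_model()].
#' @param image_pair List of `nucleus` and `cell` channel matrices.
#' @param gt Ground-truth `instance_set` for the model's class.
#' @param weight_map Optional precomputed [contour_weight_map()]; computed
#'   on the fly from `gt` when the model uses the weighted loss.
#' @return A `loss_bundle` (see [loss_bundle()]); attribute `total_node`
#'   carries the differentiable graph for the optimizer.
#' @export
compute_loss <- function(model, image_pair, gt, weight_map = NULL) {
  cfg <- model$config
  pyr <- forward_pyramid(model, image_pair)
  image_hw <- dim(image_pair$cell)
  rpn_nodes <- lapply(pyr, model$rpn$fwd)
  anchors_by_level <- model_anchors(model, pyr)
  anchors <- do.call(rbind, anchors_by_level)
  level_sizes <- vapply(anchors_by_level, nrow, 0L)
  gt_boxes <- as.matrix(gt$meta[, c("x0", "y0", "x1", "y1")])

  tg <- rpn_targets(anchors, gt_boxes)
  samp <- sample_balanced(tg$pos, tg$neg, cfg$rpn_batch,
                          cfg$rpn_pos_fraction)
  sel <- c(samp$pos, samp$neg)
  labels <- c(rep(1, length(samp$pos)), rep(0, length(samp$neg)))
  gathered <- gather_rpn(rpn_nodes, level_sizes,
                         length(cfg$anchor_ratios), sel)
  scores_node <- nd_cat_vec(gathered$scores)
  l_rpn_cls <- nd_bce_logits(scores_node, labels[gathered$order])

  if (length(samp$pos) > 0) {
    gp <- gather_rpn(rpn_nodes, level_sizes, length(cfg$anchor_ratios),
                     samp$pos)
    deltas_node <- nd_reshape(nd_cat_vec(gp$deltas),
                              c(4L, length(samp$pos)))
    pos_in_order <- samp$pos[gp$order]
    target_d <- t(encode_boxes(
      gt_boxes[tg$match[pos_in_order], , drop = FALSE],
      anchors[pos_in_order, , drop = FALSE]))
    l_rpn_box <- nd_smooth_l1(deltas_node, target_d)
  } else {
    l_rpn_box <- nn_const(0)
  }

  # proposals (non-differentiable path), plus ground-truth boxes so the
  # heads always see positives while the RPN is still warming up
  flat <- lapply(seq_along(rpn_nodes), function(l) {
    flatten_rpn_level(rpn_nodes[[l]]$obj, rpn_nodes[[l]]$reg,
                      length(cfg$anchor_ratios))
  })
  props <- rpn_proposals(flat, anchors_by_level, image_hw,
                         pre_nms_top_n = cfg$rpn_pre_nms,
                         post_nms_top_n = cfg$rpn_post_nms_train,
                         nms_threshold = cfg$rpn_nms)
  proposals <- rbind(props$boxes, gt_boxes)
  if (nrow(proposals) == 0) {
    bundle <- loss_bundle(l_rpn_cls$value, l_rpn_box$value, 0, 0, 0)
    attr(bundle, "total_node") <- nd_sum_scalars(
      list(l_rpn_cls, nd_scale(l_rpn_box, 2)))
    return(bundle)
  }

  ious <- box_iou_matrix(proposals, gt_boxes)
  best <- if (ncol(ious)) apply(ious, 1, max) else rep(0, nrow(proposals))
  match <- if (ncol(ious)) max.col(ious, ties.method = "first") else
    rep(NA_integer_, nrow(proposals))
  samp2 <- sample_balanced(which(best >= 0.5), which(best < 0.5),
                           cfg$roi_batch, cfg$roi_pos_fraction)
  keep <- c(samp2$pos, samp2$neg)
  roi_boxes <- proposals[keep, , drop = FALSE]
  roi_labels <- c(rep(2L, length(samp2$pos)), rep(1L, length(samp2$neg)))
  heads_in <- multilevel_roi_align(pyr, model$fpn$strides, roi_boxes,
                                   model$box_head$roi_size)
  heads_out <- model$box_head$fwd(heads_in)
  l_cls <- nd_softmax_ce(heads_out$cls, roi_labels)

  n_pos <- length(samp2$pos)
  if (n_pos > 0) {
    pos_cols <- seq_len(n_pos)
    idx4 <- as.vector(vapply(pos_cols, function(i) (i - 1L) * 4L + 1:4,
                             numeric(4)))
    reg_node <- nd_reshape(nd_gather_vec(heads_out$reg, idx4),
                           c(4L, n_pos))
    pos_boxes <- roi_boxes[pos_cols, , drop = FALSE]
    pos_match <- match[keep[pos_cols]]
    target_d <- t(encode_boxes(gt_boxes[pos_match, , drop = FALSE],
                               pos_boxes))
    l_box <- nd_smooth_l1(reg_node, target_d)

    mask_in <- multilevel_roi_align(pyr, model$fpn$strides, pos_boxes,
                                    model$mask_head$roi_size)
    mask_logits <- model$mask_head$fwd(mask_in)
    msz <- model$mask_head$out_size
    targets <- array(0, c(msz, msz, 1, n_pos))
    weights <- NULL
    if (model$weighted_loss) {
      if (is.null(weight_map)) {
        weight_map <- contour_weight_map(as_label_matrix(gt))
      }
      weights <- array(1, c(msz, msz, 1, n_pos))
    }
    for (i in seq_len(n_pos)) {
      gm <- gt$masks[[pos_match[i]]]
      targets[, , 1, i] <-
        crop_resize_bilinear(gm * 1, pos_boxes[i, ], msz, msz) >= 0.5
      if (!is.null(weights)) {
        weights[, , 1, i] <-
          crop_resize_bilinear(weight_map, pos_boxes[i, ], msz, msz)
      }
    }
    l_mask <- nd_bce_logits(mask_logits, targets, weights)
  } else {
    l_box <- nn_const(0)
    l_mask <- nn_const(0)
  }

  total <- nd_sum_scalars(list(
    l_rpn_cls, nd_scale(l_rpn_box, 2), l_cls,
    nd_scale(l_box, 2), nd_scale(l_mask, 2)))
  bundle <- loss_bundle(l_rpn_cls$value, l_rpn_box$value, l_cls$value,
                        l_box$value, l_mask$value)
  attr(bundle, "total_node") <- total
  attr(bundle, "n_pos") <- n_pos
  bundle
}

# ---- inference --------------------------------------------------------

#' Predict instances on an image pair
#'
#' Full inference path: feature pyramid (with nucleus fusion for the fpf
#' variant), RPN proposals, box head refinement, score filtering,
#' non-maximum suppression, truncation to the 100 top-scoring detections,
#' and mask prediction; masks are thresholded at 0.5 and pasted back to
#' image coordinates by nearest-neighbour resizing.
#'
#' @param object An [fpf_model()].
#' @param image_pair List of `nucleus` and `cell` channel matrices.
#' @param ... Unused.
#' @return An `instance_set` of at most `max_detections` scored detections.
#' @export
predict.fpf_model <- function(object, image_pair, ...) {
  model <- object
  cfg <- model$config
  if (!identical(dim(image_pair$nucleus), dim(image_pair$cell))) {
    stop("channel shapes differ")
  }
  image_hw <- dim(image_pair$cell)
  pyr <- forward_pyramid(model, image_pair)
  rpn_nodes <- lapply(pyr, model$rpn$fwd)
  anchors_by_level <- model_anchors(model, pyr)
  flat <- lapply(seq_along(rpn_nodes), function(l) {
    flatten_rpn_level(rpn_nodes[[l]]$obj, rpn_nodes[[l]]$reg,
                      length(cfg$anchor_ratios))
  })
  props <- rpn_proposals(flat, anchors_by_level, image_hw,
                         pre_nms_top_n = cfg$rpn_pre_nms,
                         post_nms_top_n = cfg$rpn_post_nms_test,
                         nms_threshold = cfg$rpn_nms)
  if (nrow(props$boxes) == 0) {
    return(empty_instance_set(image_hw, model$class_name))
  }
  heads_in <- multilevel_roi_align(pyr, model$fpn$strides, props$boxes,
                                   model$box_head$roi_size)
  heads_out <- model$box_head$fwd(heads_in)
  logits <- heads_out$cls$value           # (2, n): bg, fg
  zs <- sweep(logits, 2, apply(logits, 2, max))
  pr <- exp(zs)
  pr <- sweep(pr, 2, colSums(pr), "/")
  scores <- pr[2, ]
  deltas <- matrix(heads_out$reg$value, 4)   # (4, n)
  boxes <- decode_boxes(t(deltas), props$boxes)
  boxes <- clip_boxes(boxes, image_hw[1], image_hw[2])
  ok <- scores >= cfg$score_floor &
    (boxes[, 3] - boxes[, 1]) >= 1 & (boxes[, 4] - boxes[, 2]) >= 1
  if (!any(ok)) return(empty_instance_set(image_hw, model$class_name))
  boxes <- boxes[ok, , drop = FALSE]
  scores <- scores[ok]
  keep <- nms(boxes, scores, cfg$det_nms)
  keep <- keep[seq_len(min(length(keep), cfg$max_detections))]
  boxes <- boxes[keep, , drop = FALSE]
  scores <- scores[keep]

  mask_in <- multilevel_roi_align(pyr, model$fpn$strides, boxes,
                                  model$mask_head$roi_size)
  mask_logits <- model$mask_head$fwd(mask_in)$value
  msz <- model$mask_head$out_size
  masks <- lapply(seq_along(scores), function(i) {
    prob <- 1 / (1 + exp(-mask_logits[, , 1, i]))
    paste_mask(prob >= cfg$mask_threshold, boxes[i, ], image_hw)
  })
  nonempty <- vapply(masks, any, TRUE)
  if (!any(nonempty)) return(empty_instance_set(image_hw, model$class_name))
  instance_set(masks[nonempty], score = scores[nonempty],
               class = model$class_name)
}

# nearest-neighbour paste of a box-space binary mask into the image frame
paste_mask <- function(mask, box, image_hw) {
  H <- image_hw[1]; W <- image_hw[2]
  x0 <- max(0L, floor(box[1])); x1 <- min(W, ceiling(box[3]))
  y0 <- max(0L, floor(box[2])); y1 <- min(H, ceiling(box[4]))
  out <- matrix(FALSE, H, W)
  if (x1 <= x0 || y1 <= y0) return(out)
  ms <- nrow(mask)
  rows <- (y0 + 1):y1
  cols <- (x0 + 1):x1
  # map pixel centers back into mask bins
  ry <- pmin(pmax(ceiling((rows - 0.5 - box[2]) / (box[4] - box[2]) * ms),
                  1), ms)
  rx <- pmin(pmax(ceiling((cols - 0.5 - box[1]) / (box[3] - box[1]) * ms),
                  1), ms)
  out[rows, cols] <- mask[ry, rx]
  out
}

#' @rdname fpf_model
#' @param x An `fpf_model`.
#' @param ... Unused.
#' @exportS3Method generics::glance
glance.fpf_model <- function(x, ...) {
  tibble::tibble(variant = x$variant,
                 merge_mode = if (x$variant == "fpf") x$merge_mode else NA,
                 weighted_loss = x$weighted_loss,
                 class = x$class_name,
                 n_parameters = count_parameters(x$params),
                 pyramid_width = x$config$pyramid_width)
}

#' Read and write configurations as YAML
#'
#' Model, training and scene configurations round-trip through YAML so
#' experiments are reproducible from a config file plus a seed.
#'
#' @param path YAML file path.
#' @param type Which constructor to apply: `"model"`, `"train"` or
#'   `"scene"`.
#' @return The corresponding config object.
#' @export
read_config_yaml <- function(path, type = c("model", "train", "scene")) {
  type <- match.arg(type)
  vals <- yaml::read_yaml(path)
  # YAML maps scalars-in-lists; restore flat (possibly named) vectors
  vals <- lapply(vals, function(v) {
    if (is.list(v) && length(v) > 0 &&
        all(vapply(v, function(e) is.atomic(e) && length(e) == 1, TRUE))) {
      unlist(v)
    } else v
  })
  ctor <- switch(type, model = model_config, train = train_config,
                 scene = scene_config)
  keep <- intersect(names(vals), names(formals(ctor)))
  do.call(ctor, vals[keep])
}

#' @rdname read_config_yaml
#' @param config A `model_config`, `train_config` or `scene_config`.
#' @export
write_config_yaml <- function(config, path) {
  yaml::write_yaml(lapply(unclass(config), function(v) {
    if (is.null(names(v))) v else as.list(v)
  }), path)
  invisible(path)
}
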
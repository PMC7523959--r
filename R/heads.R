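# Detection heads: multi-level RoI-Align, box/class head, mask head.

#' RoI-Align over a single feature map
#'
#' Extracts fixed-size feature crops by averaging bilinear samples on a
#' regular grid inside each box bin — no coordinate quantization. Boxes are
#' given in image pixels and scaled by `1/stride` into feature coordinates.
#'
#' @param feature Feature array `(H, W, C)` or node.
#' @param boxes Matrix `(n, 4)` of image-space boxes.
#' @param output_size Side length of the output crop.
#' @param stride Feature stride relative to the image.
#' @param sampling Bilinear samples per bin axis (default 2).
#' @return Node of shape `(output_size, output_size, C, n)`.
#' @export
roi_align <- function(feature, boxes, output_size, stride = 1,
                      sampling = 2) {
  feature <- as_node(feature)
  if (any(boxes[, 3] <= boxes[, 1]) || any(boxes[, 4] <= boxes[, 2])) {
    stop("non-positive box supplied to roi_align")
  }
  nd_roi_align(feature, boxes / stride, output_size, sampling)
}

# RoI-Align with FPN level routing: boxes are assigned to levels by
# assign_pyramid_level, aligned per level in one batched kernel call, and
# reassembled in input order by a single fused node (one allocation each
# way instead of per-RoI slicing).
multilevel_roi_align <- function(pyramid, strides, boxes, output_size,
                                 sampling = 2) {
  n <- nrow(boxes)
  levels <- vapply(seq_len(n), function(i)
    assign_pyramid_level(boxes[i, ]), 0L)
  used <- sort(unique(levels))
  sel_by_level <- lapply(used, function(l) which(levels == l))
  parent_nodes <- lapply(used, function(l) pyramid[[paste0("P", l)]])
  C <- dim(parent_nodes[[1]]$value)[3]
  v <- array(0, c(output_size, output_size, C, n))
  crops <- vector("list", length(used))
  for (k in seq_along(used)) {
    lev <- paste0("P", used[k])
    f3 <- parent_nodes[[k]]$value
    dim(f3) <- dim(f3)[1:3]
    crops[[k]] <- .roi_align_fwd(
      f3, boxes[sel_by_level[[k]], , drop = FALSE] / strides[[lev]],
      as.integer(output_size), as.integer(sampling))
    v[, , , sel_by_level[[k]]] <- crops[[k]]
  }
  out <- new_node(v, parent_nodes)
  out$backfn <- function(g) {
    dim(g) <- dim(v)
    for (k in seq_along(used)) {
      pn <- parent_nodes[[k]]
      if (!pn$requires) next
      lev <- paste0("P", used[k])
      d <- dim(pn$value)
      df <- .roi_align_bwd(
        g[, , , sel_by_level[[k]], drop = FALSE],
        boxes[sel_by_level[[k]], , drop = FALSE] / strides[[lev]],
        as.integer(d[1:3]), as.integer(output_size), as.integer(sampling))
      dim(df) <- d
      accum_grad(pn, df)
    }
  }
  out
}

# Box/class head: 7x7 RoI features -> two fc layers -> class logits (bg/fg)
# and box deltas for the foreground class.
build_box_head <- function(pyramid_width, fc_dim = 1024, roi_size = 7) {
  params <- new.env(parent = emptyenv())
  d_in <- roi_size * roi_size * pyramid_width
  init_fc <- function(name, din, dout, sd = sqrt(2 / din)) {
    params[[paste0(name, ".w")]] <- nn_param(
      matrix(stats::rnorm(din * dout, 0, sd), din, dout))
    params[[paste0(name, ".b")]] <- nn_param(numeric(dout))
  }
  init_fc("fc1", d_in, fc_dim)
  init_fc("fc2", fc_dim, fc_dim)
  init_fc("cls", fc_dim, 2, sd = 0.01)
  init_fc("reg", fc_dim, 4, sd = 0.001)
  fwd <- function(rois) {
    x <- nd_flatten(rois)
    x <- nd_relu(nd_fc(x, params[["fc1.w"]], params[["fc1.b"]]))
    x <- nd_relu(nd_fc(x, params[["fc2.w"]], params[["fc2.b"]]))
    list(cls = nd_fc(x, params[["cls.w"]], params[["cls.b"]]),
         reg = nd_fc(x, params[["reg.w"]], params[["reg.b"]]))
  }
  structure(list(fwd = fwd, params = params, roi_size = roi_size),
            class = "box_head")
}

# Mask head: 14x14 RoI features -> n_conv 3x3 convs -> 2x nearest upsample +
# 3x3 conv -> 1x1 conv -> 28x28 single-channel logits.
build_mask_head <- function(pyramid_width, channels = 256, n_conv = 4,
                            roi_size = 14) {
  params <- new.env(parent = emptyenv())
  convs <- list()
  cin <- pyramid_width
  for (i in seq_len(n_conv)) {
    convs[[i]] <- make_conv(params, sprintf("conv%d", i), 3, 3, cin,
                            channels, bias = TRUE)
    cin <- channels
  }
  up_conv <- make_conv(params, "up_conv", 3, 3, channels, channels,
                       bias = TRUE)
  logit_conv <- make_conv(params, "logits", 1, 1, channels, 1, pad = 0,
                          bias = TRUE, init_sd = 0.01)
  fwd <- function(rois) {
    x <- rois
    for (cv in convs) x <- nd_relu(cv(x))
    x <- nd_relu(up_conv(nd_upsample2(x)))
    logit_conv(x)  # (2*roi_size, 2*roi_size, 1, n)
  }
  structure(list(fwd = fwd, params = params, roi_size = roi_size,
                 out_size = 2L * roi_size),
            class = "mask_head")
}
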
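# Region proposal network: per-level anchors, box coding, NMS, proposals.

#' Generate anchors for one pyramid level
#'
#' One anchor scale per level (32, 64, 128, 256, 512 px for P2..P6) with
#' aspect ratios 0.5, 1, 2. Anchors are centred on feature-map cells
#' (continuous image coordinates); the row order matches the vectorization
#' of an `(H, W, A)` score map (rows fastest, then columns, then anchors).
#'
#' @param feat_h,feat_w Feature-map size of the level.
#' @param stride Level stride in pixels.
#' @param scale Anchor side length at aspect 1.
#' @param ratios Aspect ratios h/w.
#' @return Matrix `(n, 4)` of `(x0, y0, x1, y1)` anchors.
#' @export
level_anchors <- function(feat_h, feat_w, stride, scale,
                          ratios = c(0.5, 1, 2)) {
  cy <- (seq_len(feat_h) - 0.5) * stride
  cx <- (seq_len(feat_w) - 0.5) * stride
  out <- matrix(0, feat_h * feat_w * length(ratios), 4)
  row <- 1L
  for (r in ratios) {
    h <- scale * sqrt(r)
    w <- scale / sqrt(r)
    for (x in cx) {
      for (y in cy) {
        out[row, ] <- c(x - w / 2, y - h / 2, x + w / 2, y + h / 2)
        row <- row + 1L
      }
    }
  }
  out
}

#' Box delta coding
#'
#' Standard parameterization: offsets of centre and log-scales of size,
#' relative to the reference (anchor or proposal) box. `decode_boxes` is the
#' algebraic inverse of `encode_boxes`.
#'
#' @param boxes Matrix `(n, 4)` of target boxes.
#' @param refs Matrix `(n, 4)` of reference boxes.
#' @return `encode_boxes`: matrix `(n, 4)` of `(dx, dy, dw, dh)`;
#'   `decode_boxes`: matrix `(n, 4)` of boxes.
#' @export
encode_boxes <- function(boxes, refs) {
  rw <- refs[, 3] - refs[, 1]; rh <- refs[, 4] - refs[, 2]
  rcx <- refs[, 1] + rw / 2; rcy <- refs[, 2] + rh / 2
  bw <- boxes[, 3] - boxes[, 1]; bh <- boxes[, 4] - boxes[, 2]
  bcx <- boxes[, 1] + bw / 2; bcy <- boxes[, 2] + bh / 2
  cbind((bcx - rcx) / rw, (bcy - rcy) / rh, log(bw / rw), log(bh / rh))
}

#' @rdname encode_boxes
#' @param deltas Matrix `(n, 4)` of `(dx, dy, dw, dh)`.
#' @export
decode_boxes <- function(deltas, refs) {
  rw <- refs[, 3] - refs[, 1]; rh <- refs[, 4] - refs[, 2]
  rcx <- refs[, 1] + rw / 2; rcy <- refs[, 2] + rh / 2
  # cap the log-scale like reference implementations to avoid overflow
  dw <- pmin(deltas[, 3], log(1000 / 16))
  dh <- pmin(deltas[, 4], log(1000 / 16))
  cx <- rcx + deltas[, 1] * rw
  cy <- rcy + deltas[, 2] * rh
  w <- rw * exp(dw); h <- rh * exp(dh)
  cbind(cx - w / 2, cy - h / 2, cx + w / 2, cy + h / 2)
}

clip_boxes <- function(boxes, height, width) {
  boxes[, 1] <- pmin(pmax(boxes[, 1], 0), width)
  boxes[, 3] <- pmin(pmax(boxes[, 3], 0), width)
  boxes[, 2] <- pmin(pmax(boxes[, 2], 0), height)
  boxes[, 4] <- pmin(pmax(boxes[, 4], 0), height)
  boxes
}

box_iou_matrix <- function(a, b) {
  na <- nrow(a); nb <- nrow(b)
  if (na == 0 || nb == 0) return(matrix(0, na, nb))
  iw <- pmax(outer(a[, 3], b[, 3], pmin) - outer(a[, 1], b[, 1], pmax), 0)
  ih <- pmax(outer(a[, 4], b[, 4], pmin) - outer(a[, 2], b[, 2], pmax), 0)
  inter <- iw * ih
  area_a <- (a[, 3] - a[, 1]) * (a[, 4] - a[, 2])
  area_b <- (b[, 3] - b[, 1]) * (b[, 4] - b[, 2])
  uni <- outer(area_a, area_b, `+`) - inter
  out <- inter / pmax(uni, 1e-12)
  out[uni <= 0 | !is.finite(out)] <- 0
  out
}

#' Greedy non-maximum suppression
#'
#' @param boxes Matrix `(n, 4)`.
#' @param scores Numeric vector.
#' @param iou_threshold Overlap above which a lower-scoring box is
#'   suppressed.
#' @return Integer indices of kept boxes, in decreasing score order.
#' @export
nms <- function(boxes, scores, iou_threshold = 0.5) {
  ord <- order(scores, decreasing = TRUE)
  areas <- (boxes[, 3] - boxes[, 1]) * (boxes[, 4] - boxes[, 2])
  keep <- integer(0)
  while (length(ord) > 0) {
    i <- ord[1]
    keep <- c(keep, i)
    if (length(ord) == 1) break
    rest <- ord[-1]
    iw <- pmax(pmin(boxes[i, 3], boxes[rest, 3]) -
                 pmax(boxes[i, 1], boxes[rest, 1]), 0)
    ih <- pmax(pmin(boxes[i, 4], boxes[rest, 4]) -
                 pmax(boxes[i, 2], boxes[rest, 2]), 0)
    inter <- iw * ih
    ious <- inter / pmax(areas[i] + areas[rest] - inter, 1e-12)
    ord <- rest[ious <= iou_threshold]
  }
  keep
}

# RPN head module shared across levels: 3x3 conv + ReLU, then 1x1 heads for
# objectness (A) and box deltas (4A)
build_rpn_head <- function(pyramid_width, n_anchors = 3) {
  params <- new.env(parent = emptyenv())
  conv <- make_conv(params, "conv", 3, 3, pyramid_width, pyramid_width,
                    bias = TRUE)
  obj <- make_conv(params, "obj", 1, 1, pyramid_width, n_anchors, pad = 0,
                   bias = TRUE, init_sd = 0.01)
  reg <- make_conv(params, "reg", 1, 1, pyramid_width, 4 * n_anchors,
                   pad = 0, bias = TRUE, init_sd = 0.001)
  fwd <- function(level) {
    h <- nd_relu(conv(level))
    list(obj = obj(h), reg = reg(h))
  }
  structure(list(fwd = fwd, params = params, n_anchors = n_anchors),
            class = "rpn_head")
}

# flatten RPN outputs of one level into per-anchor vectors matching
# level_anchors() order: obj (H,W,A,1) -> n; reg (H,W,4A,1) -> (n, 4).
# The reg layout groups the 4 coordinates per anchor contiguously.
flatten_rpn_level <- function(obj_node, reg_node, n_anchors) {
  d <- dim(obj_node$value)
  scores <- as.vector(obj_node$value)
  rv <- reg_node$value
  hw <- d[1] * d[2]
  dim(rv) <- c(hw, 4L * n_anchors)
  deltas <- matrix(0, hw * n_anchors, 4)
  for (a in seq_len(n_anchors)) {
    deltas[(a - 1L) * hw + seq_len(hw), ] <-
      rv[, (a - 1L) * 4L + 1:4, drop = FALSE]
  }
  list(scores = scores, deltas = deltas)
}

# Decode proposals from RPN outputs across levels.
rpn_proposals <- function(rpn_out, anchors_by_level, image_hw,
                          pre_nms_top_n = 1000, post_nms_top_n = 200,
                          nms_threshold = 0.7, min_size = 1) {
  all_boxes <- list(); all_scores <- list()
  for (l in seq_along(rpn_out)) {
    fl <- rpn_out[[l]]
    anc <- anchors_by_level[[l]]
    sc <- fl$scores
    top <- order(sc, decreasing = TRUE)
    top <- top[seq_len(min(length(top), pre_nms_top_n))]
    boxes <- decode_boxes(fl$deltas[top, , drop = FALSE],
                          anc[top, , drop = FALSE])
    boxes <- clip_boxes(boxes, image_hw[1], image_hw[2])
    ok <- apply(is.finite(boxes), 1, all) &
      (boxes[, 3] - boxes[, 1]) >= min_size &
      (boxes[, 4] - boxes[, 2]) >= min_size
    all_boxes[[l]] <- boxes[ok, , drop = FALSE]
    all_scores[[l]] <- sc[top][ok]
  }
  boxes <- do.call(rbind, all_boxes)
  scores <- do.call(c, all_scores)
  if (length(scores) == 0) {
    return(list(boxes = matrix(0, 0, 4), scores = numeric(0)))
  }
  keep <- nms(boxes, scores, nms_threshold)
  keep <- keep[seq_len(min(length(keep), post_nms_top_n))]
  list(boxes = boxes[keep, , drop = FALSE], scores = scores[keep])
}
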
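#' Build a feature pyramid network module
#'
#' Standard top-down pyramid over backbone stages C2..C5: 1x1 lateral
#' projections to a common `pyramid_width`, nearest-neighbour 2x upsampling
#' with addition along the top-down path, a 3x3 smoothing convolution per
#' output level, and P6 as a stride-2 subsample of P5. Level strides are
#' 4, 8, 16, 32, 64.
#'
#' @param in_channels Channel counts of C2..C5 (default the reduced
#'   backbone's 128, 256, 512, 1024).
#' @param pyramid_width Channels per pyramid level (default 256).
#' @return An `fpn` module: list with `fwd(stages)` mapping a named list of
#'   C2..C5 nodes to a named list of P2..P6 nodes, `params`, `strides`, and
#'   `pyramid_width`.
#' @export
build_fpn <- function(in_channels = c(128, 256, 512, 1024),
                      pyramid_width = 256) {
  stopifnot(length(in_channels) == 4)
  params <- new.env(parent = emptyenv())
  lats <- lapply(1:4, function(s) {
    make_conv(params, sprintf("lateral%d", s + 1), 1, 1, in_channels[s],
              pyramid_width, pad = 0, bias = TRUE)
  })
  smooths <- lapply(1:4, function(s) {
    make_conv(params, sprintf("smooth%d", s + 1), 3, 3, pyramid_width,
              pyramid_width, bias = TRUE)
  })
  # biases start at zero so an all-zero input yields an all-zero pyramid
  for (nm in grep("\\.b$", ls(params), value = TRUE)) {
    params[[nm]]$value[] <- 0
  }
  fwd <- function(stages) {
    stages <- lapply(stages, as_node)
    for (s in 1:4) {
      if (dim(stages[[s]]$value)[3] != in_channels[s]) {
        stop(sprintf("stage C%d has %d channels, expected %d", s + 1,
                     dim(stages[[s]]$value)[3], in_channels[s]))
      }
    }
    m <- vector("list", 4)
    m[[4]] <- lats[[4]](stages[[4]])
    for (s in 3:1) {
      up <- nd_upsample2(m[[s + 1]])
      lat <- lats[[s]](stages[[s]])
      if (!all(dim(up$value)[1:2] == dim(lat$value)[1:2])) {
        stop("stage spatial sizes are not dyadic; pad the input to a multiple of 64")
      }
      m[[s]] <- nd_add(lat, up)
    }
    p <- lapply(1:4, function(s) smooths[[s]](m[[s]]))
    p[[5]] <- nd_subsample2(p[[4]])
    stats::setNames(p, paste0("P", 2:6))
  }
  structure(list(fwd = fwd, params = params,
                 strides = c(P2 = 4, P3 = 8, P4 = 16, P5 = 32, P6 = 64),
                 pyramid_width = pyramid_width),
            class = "fpn")
}

as_node <- function(x) {
  if (inherits(x, "nn_node")) return(x)
  new_node(as4d(x), requires = FALSE)
}

#' Build a feature pyramid from stage features
#'
#' Functional convenience over [build_fpn()]: constructs a fresh pyramid
#' module (He-initialized from the current RNG state) and applies it to the
#' given stage features.
#'
#' @param stages Named list `C2..C5` of feature arrays `(H, W, C)` or nodes.
#' @param pyramid_width Channels per level.
#' @return Named list of P2..P6 nodes with a `strides` attribute.
#' @export
build_pyramid <- function(stages, pyramid_width = 256) {
  stages <- lapply(stages, as_node)
  chans <- vapply(stages, function(s) dim(s$value)[3], 0)
  fpn <- build_fpn(in_channels = chans, pyramid_width = pyramid_width)
  out <- fpn$fwd(stages)
  attr(out, "strides") <- fpn$strides
  out
}

#' Fuse a nucleus feature pyramid into a cell feature pyramid
#'
#' Level-by-level merge of the (frozen) nucleus pyramid into the cell
#' pyramid, by element-wise addition (channel count unchanged) or channel
#' concatenation (doubled, optionally projected back to the cell width by a
#' trainable 1x1 convolution so downstream heads are merge-mode invariant).
#' The nucleus branch carries no gradients: its parameters are excluded from
#' updates and the backward sweep prunes the whole branch.
#'
#' @param cell_pyr,nucleus_pyr Named lists of P2..P6 nodes (or arrays) with
#'   matching spatial sizes.
#' @param mode `"add"` or `"concat"`.
#' @param projection For `mode = "concat"`, a list of per-level projection
#'   closures built by [build_fusion_projection()], or `NULL` for raw
#'   concatenation.
#' @return Named list of fused P2..P6 nodes; attribute `merge_mode` records
#'   the mode.
#' @export
fuse_pyramids <- function(cell_pyr, nucleus_pyr, mode = c("add", "concat"),
                          projection = NULL) {
  mode <- match.arg(mode)
  stopifnot(length(cell_pyr) == length(nucleus_pyr))
  out <- lapply(seq_along(cell_pyr), function(i) {
    a <- as_node(cell_pyr[[i]])
    b <- as_node(nucleus_pyr[[i]])
    if (!all(dim(a$value)[1:2] == dim(b$value)[1:2])) {
      stop("pyramid level spatial sizes differ between branches")
    }
    if (mode == "add") {
      if (dim(a$value)[3] != dim(b$value)[3]) {
        stop("add-mode fusion requires equal channel counts")
      }
      nd_add(a, b)
    } else {
      y <- nd_concat_c(a, b)
      if (!is.null(projection)) projection[[i]](y) else y
    }
  })
  names(out) <- names(cell_pyr)
  attr(out, "merge_mode") <- mode
  out
}

#' @rdname fuse_pyramids
#' @param pyramid_width Cell-branch channel count per level.
#' @param n_levels Number of pyramid levels (default 5).
#' @export
build_fusion_projection <- function(pyramid_width, n_levels = 5) {
  params <- new.env(parent = emptyenv())
  projs <- lapply(seq_len(n_levels), function(i) {
    make_conv(params, sprintf("proj%d", i), 1, 1, 2 * pyramid_width,
              pyramid_width, pad = 0, bias = TRUE)
  })
  attr(projs, "params") <- params
  projs
}

#' Assign a box to a pyramid level
#'
#' The standard FPN heuristic
#' \eqn{k = \lfloor k_0 + \log_2(\sqrt{wh} / 224) \rfloor} with
#' \eqn{k_0 = 4}, clamped to levels 2..5: larger boxes are routed to coarser
#' pyramid levels. Degenerate (zero-area) boxes go to level 2.
#'
#' @param box Numeric `(x0, y0, x1, y1)`, half-open pixel units.
#' @param image_size Unused; kept for signature compatibility.
#' @return Integer level in 2..5.
#' @export
assign_pyramid_level <- function(box, image_size = NULL) {
  w <- box[3] - box[1]
  h <- box[4] - box[2]
  if (w <= 0 || h <= 0) return(2L)
  k <- floor(4 + log2(sqrt(w * h) / 224))
  as.integer(min(max(k, 2), 5))
}
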
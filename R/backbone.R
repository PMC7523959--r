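#' Reduced ResNet-50 backbone configuration
#'
#' The backbone is a bottleneck residual network with halved filter counts
#' and halved block counts relative to the standard ResNet-50: conv1 is a
#' 7x7, 64-filter, stride-2 convolution followed by 3x3 max pooling (stride
#' 2); the four stages use bottleneck widths (32, 64, 128, 256) with output
#' widths four times larger and block counts (2, 2, 3, 2). Stage outputs
#' C2..C5 have strides 4, 8, 16, 32 and channel counts 128, 256, 512, 1024.
#'
#' @param input_channels 1 (single stain) or 2 (early fusion of both stains).
#' @param width_multiplier Stage-width scale relative to the standard
#'   ResNet-50 (0.5 reproduces the reduced architecture; 1 the original).
#' @param blocks Integer vector of per-stage block counts; default
#'   `c(2, 2, 3, 2)` (the original uses `c(3, 4, 6, 3)`).
#' @param conv1_filters Filters in the stem convolution (64 in both the
#'   original and the reduced architecture).
#' @return A `backbone_config` list.
#' @export
backbone_config <- function(input_channels = 1, width_multiplier = 0.5,
                            blocks = c(2, 2, 3, 2), conv1_filters = 64) {
  if (!input_channels %in% 1:2) stop("input_channels must be 1 or 2")
  if (width_multiplier <= 0) stop("width_multiplier must be positive")
  if (length(blocks) != 4 || any(blocks < 1)) {
    stop("blocks must give one positive count per stage")
  }
  structure(list(input_channels = as.integer(input_channels),
                 width_multiplier = width_multiplier,
                 blocks = as.integer(blocks),
                 conv1_filters = as.integer(conv1_filters)),
            class = "backbone_config")
}

stage_widths <- function(config) {
  as.integer(round(64 * 2^(0:3) * config$width_multiplier / 0.5 * 0.5))
}

he_init <- function(kh, kw, cin, cout) {
  sd <- sqrt(2 / (kh * kw * cin))
  array(stats::rnorm(kh * kw * cin * cout, 0, sd), c(kh, kw, cin, cout))
}

make_conv <- function(params, name, kh, kw, cin, cout, stride = 1,
                      pad = NULL, bias = FALSE, init_sd = NULL) {
  force(stride); force(bias); force(name)
  if (is.null(pad)) pad <- (kh - 1) / 2
  init <- if (is.null(init_sd)) he_init(kh, kw, cin, cout) else
    array(stats::rnorm(kh * kw * cin * cout, 0, init_sd),
          c(kh, kw, cin, cout))
  params[[paste0(name, ".w")]] <- nn_param(init)
  if (bias) params[[paste0(name, ".b")]] <- nn_param(numeric(cout))
  function(x) nd_conv2d(x, params[[paste0(name, ".w")]],
                        if (bias) params[[paste0(name, ".b")]] else NULL,
                        stride = stride, pad = pad)
}

make_bn <- function(params, name, c) {
  params[[paste0(name, ".gamma")]] <- nn_param(rep(1, c))
  params[[paste0(name, ".beta")]] <- nn_param(numeric(c))
  function(x) nd_bn(x, params[[paste0(name, ".gamma")]],
                    params[[paste0(name, ".beta")]])
}

# bottleneck residual block: 1x1 reduce, 3x3 (carries the stride), 1x1
# expand; projection shortcut when shape changes
make_bottleneck <- function(params, name, cin, w, stride) {
  force(cin); force(w); force(stride)
  cout <- 4L * w
  c1 <- make_conv(params, paste0(name, ".conv1"), 1, 1, cin, w)
  b1 <- make_bn(params, paste0(name, ".bn1"), w)
  c2 <- make_conv(params, paste0(name, ".conv2"), 3, 3, w, w,
                  stride = stride)
  b2 <- make_bn(params, paste0(name, ".bn2"), w)
  c3 <- make_conv(params, paste0(name, ".conv3"), 1, 1, w, cout)
  b3 <- make_bn(params, paste0(name, ".bn3"), cout)
  # zero-init the last BN scale so each block starts as identity and the
  # activation variance stays bounded without normalizing statistics
  params[[paste0(name, ".bn3.gamma")]]$value[] <- 0
  proj <- NULL
  if (cin != cout || stride != 1) {
    pc <- make_conv(params, paste0(name, ".proj"), 1, 1, cin, cout,
                    stride = stride, pad = 0)
    pb <- make_bn(params, paste0(name, ".proj_bn"), cout)
    proj <- function(x) pb(pc(x))
  }
  function(x) {
    y <- nd_relu(b1(c1(x)))
    y <- nd_relu(b2(c2(y)))
    y <- b3(c3(y))
    sc <- if (is.null(proj)) x else proj(x)
    nd_relu(nd_add(y, sc))
  }
}

#' Build the backbone feature extractor
#'
#' Returns a module whose forward pass maps an input tensor of shape
#' `(H, W, input_channels, 1)` (H, W at least 32) to the stage features
#' C2..C5 at strides 4, 8, 16, 32. Weights are He-initialized from the
#' current RNG state; batch normalization runs with frozen statistics
#' (trainable scale and shift), the standard choice for small-batch
#' detection fine-tuning.
#'
#' @param config A [backbone_config()].
#' @return A `backbone` module: list with `fwd(x_node)` returning
#'   `list(C2, C3, C4, C5)` node list, `params` (environment of named
#'   parameter nodes), `stage_of` (named character vector mapping parameter
#'   names to stem/conv2/.../conv5), and `config`.
#' @export
build_backbone <- function(config = backbone_config()) {
  params <- new.env(parent = emptyenv())
  conv1 <- make_conv(params, "conv1", 7, 7, config$input_channels,
                     config$conv1_filters, stride = 2, pad = 3)
  bn1 <- make_bn(params, "bn1", config$conv1_filters)
  widths <- stage_widths(config)
  stages <- list()
  cin <- config$conv1_filters
  for (s in 1:4) {
    blocks <- list()
    for (b in seq_len(config$blocks[s])) {
      stride <- if (b == 1 && s > 1) 2 else 1
      blocks[[b]] <- make_bottleneck(
        params, sprintf("conv%d.b%d", s + 1, b), cin, widths[s], stride)
      cin <- 4L * widths[s]
    }
    stages[[s]] <- blocks
  }
  fwd <- function(x) {
    d <- dim(x$value)
    if (min(d[1], d[2]) < 32) {
      stop("input must be at least 32 px per side (stride budget is 32)")
    }
    if (d[3] != config$input_channels) {
      stop(sprintf("expected %d input channel(s), got %d",
                   config$input_channels, d[3]))
    }
    y <- nd_maxpool(nd_relu(bn1(conv1(x))), k = 3, stride = 2, pad = 1)
    feats <- vector("list", 4)
    for (s in 1:4) {
      for (blk in stages[[s]]) y <- blk(y)
      feats[[s]] <- y
    }
    names(feats) <- paste0("C", 2:5)
    feats
  }
  pnames <- ls(params)
  stage_of <- vapply(pnames, function(nm) {
    if (grepl("^conv1\\.|^bn1\\.", nm)) "stem" else
      sub("^(conv[2-5])\\..*$", "\\1", nm)
  }, "")
  structure(list(fwd = fwd, params = params, stage_of = stage_of,
                 config = config),
            class = "backbone")
}

#' Count trainable parameters
#'
#' Exact count of trainable scalars (convolution weights, biases where
#' present, and batch-normalization scale/shift) in a module or model.
#'
#' @param x A `backbone`, `fpf_model`, parameter environment, or named list
#'   of parameter nodes.
#' @return Integer scalar count.
#' @export
count_parameters <- function(x) {
  params <- if (is.environment(x)) x
  else if (!is.null(x$params)) x$params
  else x
  nms <- if (is.environment(params)) ls(params) else names(params)
  sum(vapply(nms, function(nm) length(params[[nm]]$value), numeric(1)))
}

#' Adapt 1-channel first-layer weights to 2-channel input
#'
#' For early fusion, the single-channel 7x7 stem kernel is duplicated onto
#' both input channels and halved, so an image fed identically into both
#' channels produces exactly the original activations and downstream layers
#' see undisturbed statistics.
#'
#' @param weights_1ch Array of shape `(kh, kw, 1, cout)`.
#' @return Array of shape `(kh, kw, 2, cout)` with each channel slice equal
#'   to half the original kernel.
#' @export
adapt_first_layer_two_channels <- function(weights_1ch) {
  d <- dim(weights_1ch)
  if (length(d) != 4 || d[3] != 1) {
    stop("expected a (kh, kw, 1, cout) kernel")
  }
  out <- array(0, c(d[1], d[2], 2, d[4]))
  out[, , 1, ] <- weights_1ch[, , 1, ] / 2
  out[, , 2, ] <- weights_1ch[, , 1, ] / 2
  out
}

# snapshot / restore parameter values (native checkpoint format: a named
# list of numeric arrays, serializable with saveRDS)
params_snapshot <- function(module) {
  params <- module$params
  nms <- sort(ls(params))
  stats::setNames(lapply(nms, function(nm) params[[nm]]$value), nms)
}

params_restore <- function(module, snapshot) {
  params <- module$params
  for (nm in names(snapshot)) {
    if (is.null(params[[nm]])) stop("unknown parameter in checkpoint: ", nm)
    if (length(params[[nm]]$value) != length(snapshot[[nm]])) {
      stop("shape mismatch for parameter ", nm)
    }
    params[[nm]]$value <- snapshot[[nm]]
  }
  invisible(module)
}

#' Save / load model checkpoints
#'
#' Checkpoints are named lists of numeric arrays keyed by hierarchical
#' parameter names (e.g. `cell_backbone.conv2.b1.conv1.w`), serialized with
#' [saveRDS()].
#'
#' @param model A model or module with a `params` environment.
#' @param path File path.
#' @export
save_checkpoint <- function(model, path) {
  saveRDS(params_snapshot(model), path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(model, path) {
  params_restore(model, readRDS(path))
}
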
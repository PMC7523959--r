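# Minimal reverse-mode automatic differentiation over numeric arrays.
#
# Nodes are environments carrying a value, an accumulated gradient, links to
# parent nodes and a backward closure. Trainable parameters are leaf nodes
# with requires = TRUE; gradient flow is pruned at subtrees without any
# trainable leaf (this is what makes the frozen nucleus branch free of both
# gradients and backward compute).

.tape <- new.env(parent = emptyenv())
.tape$counter <- 0L

new_node <- function(value, parents = list(), backfn = NULL,
                     requires = NULL) {
  n <- new.env(parent = emptyenv())
  n$value <- value
  n$grad <- NULL
  n$parents <- parents
  n$backfn <- backfn
  n$requires <- if (!is.null(requires)) requires else
    any(vapply(parents, function(p) p$requires, TRUE))
  .tape$counter <- .tape$counter + 1L
  n$idx <- .tape$counter
  class(n) <- "nn_node"
  n
}

#' @export
print.nn_node <- function(x, ...) {
  cat(sprintf("<nn_node dim=%s requires=%s>\n",
              paste(dim(x$value) %||% length(x$value), collapse = "x"),
              x$requires))
  invisible(x)
}

nn_param <- function(value, frozen = FALSE) {
  new_node(value, requires = !frozen)
}

nn_const <- function(value) new_node(value, requires = FALSE)

accum_grad <- function(node, g) {
  if (!node$requires) return(invisible(NULL))
  if (is.null(node$grad)) node$grad <- g else node$grad <- node$grad + g
  invisible(NULL)
}

# reverse-mode sweep from a scalar loss node
nn_backward <- function(loss) {
  stopifnot(length(loss$value) == 1)
  # collect the subgraph that requires gradients
  seen <- new.env(parent = emptyenv())
  stack <- list(loss)
  nodes <- list()
  while (length(stack) > 0) {
    nd <- stack[[length(stack)]]
    stack[[length(stack)]] <- NULL
    key <- as.character(nd$idx)
    if (!is.null(seen[[key]]) || !nd$requires) next
    seen[[key]] <- TRUE
    nodes[[length(nodes) + 1]] <- nd
    for (p in nd$parents) stack[[length(stack) + 1]] <- p
  }
  ord <- order(vapply(nodes, function(n) n$idx, 0L), decreasing = TRUE)
  loss$grad <- 1
  for (i in ord) {
    nd <- nodes[[i]]
    if (!is.null(nd$backfn) && !is.null(nd$grad)) nd$backfn(nd$grad)
  }
  invisible(NULL)
}

# ---- differentiable ops -----------------------------------------------

as4d <- function(x) {
  d <- dim(x)
  if (is.null(d)) stop("expected an array")
  if (length(d) == 2) dim(x) <- c(d, 1L, 1L)
  if (length(dim(x)) == 3) dim(x) <- c(dim(x), 1L)
  x
}

nd_conv2d <- function(x, w, b = NULL, stride = 1L, pad = 0L) {
  bvec <- if (is.null(b)) numeric(0) else b$value
  parents <- c(list(x, w), if (!is.null(b)) list(b))
  if (dim(x$value)[4] == 1L) {
    # single-sample path: retain the im2col workspace so the backward pass
    # skips the recomputation (batched RoI convs recompute; cheaper than
    # allocating their large workspaces)
    r <- .conv2d_fwd_ws(x$value, w$value, bvec, as.integer(stride),
                        as.integer(pad))
    out <- new_node(r$y, parents)
    xdim <- dim(x$value)
    out$backfn <- function(g) {
      gr <- .conv2d_bwd_ws(r$cols, w$value, g, as.integer(xdim),
                           as.integer(stride), as.integer(pad), x$requires)
      if (x$requires) accum_grad(x, gr$dx)
      accum_grad(w, gr$dw)
      if (!is.null(b)) accum_grad(b, gr$db)
    }
    return(out)
  }
  y <- .conv2d_fwd(x$value, w$value, bvec, as.integer(stride),
                   as.integer(pad))
  out <- new_node(y, parents)
  out$backfn <- function(g) {
    gr <- .conv2d_bwd(x$value, w$value, g, as.integer(stride),
                      as.integer(pad), x$requires)
    if (x$requires) accum_grad(x, gr$dx)
    accum_grad(w, gr$dw)
    if (!is.null(b)) accum_grad(b, gr$db)
  }
  out
}

# frozen-statistics batch norm = per-channel affine (gamma, beta trainable)
nd_bn <- function(x, gamma, beta) {
  d <- dim(x$value)
  C <- d[3]
  gm <- rep(gamma$value, each = d[1] * d[2])
  bt <- rep(beta$value, each = d[1] * d[2])
  y <- x$value * gm + bt
  out <- new_node(y, list(x, gamma, beta))
  out$backfn <- function(g) {
    if (x$requires) accum_grad(x, g * gm)
    gmat <- matrix(g, d[1] * d[2], C * d[4])
    xmat <- matrix(x$value, d[1] * d[2], C * d[4])
    per <- colSums(gmat)
    perx <- colSums(gmat * xmat)
    if (d[4] > 1) {
      per <- rowSums(matrix(per, C, d[4]))
      perx <- rowSums(matrix(perx, C, d[4]))
    }
    accum_grad(gamma, perx)
    accum_grad(beta, per)
  }
  out
}

nd_relu <- function(x) {
  mask <- x$value > 0
  out <- new_node(x$value * mask, list(x))
  out$backfn <- function(g) accum_grad(x, g * mask)
  out
}

nd_add <- function(x, y) {
  out <- new_node(x$value + y$value, list(x, y))
  out$backfn <- function(g) {
    accum_grad(x, g)
    accum_grad(y, g)
  }
  out
}

nd_concat_c <- function(x, y) {
  dx <- dim(x$value); dy <- dim(y$value)
  stopifnot(dx[1] == dy[1], dx[2] == dy[2], dx[4] == dy[4])
  v <- array(0, c(dx[1], dx[2], dx[3] + dy[3], dx[4]))
  v[, , seq_len(dx[3]), ] <- x$value
  v[, , dx[3] + seq_len(dy[3]), ] <- y$value
  out <- new_node(v, list(x, y))
  out$backfn <- function(g) {
    dim(g) <- dim(v)
    accum_grad(x, g[, , seq_len(dx[3]), , drop = FALSE])
    accum_grad(y, g[, , dx[3] + seq_len(dy[3]), , drop = FALSE])
  }
  out
}

nd_maxpool <- function(x, k = 2L, stride = 2L, pad = 0L) {
  r <- .maxpool_fwd(x$value, as.integer(k), as.integer(stride),
                    as.integer(pad))
  out <- new_node(r$y, list(x))
  xdim <- dim(x$value)
  out$backfn <- function(g) {
    accum_grad(x, .maxpool_bwd(g, r$arg, as.integer(xdim)))
  }
  out
}

nd_upsample2 <- function(x) {
  d <- dim(x$value)
  iy <- rep(seq_len(d[1]), each = 2)
  ix <- rep(seq_len(d[2]), each = 2)
  y <- x$value[iy, ix, , , drop = FALSE]
  out <- new_node(y, list(x))
  out$backfn <- function(g) {
    dim(g) <- dim(y)
    # sum the 2x2 duplicates back onto each source pixel
    gg <- g[seq(1, 2 * d[1], 2), seq(1, 2 * d[2], 2), , , drop = FALSE] +
      g[seq(2, 2 * d[1], 2), seq(1, 2 * d[2], 2), , , drop = FALSE] +
      g[seq(1, 2 * d[1], 2), seq(2, 2 * d[2], 2), , , drop = FALSE] +
      g[seq(2, 2 * d[1], 2), seq(2, 2 * d[2], 2), , , drop = FALSE]
    accum_grad(x, gg)
  }
  out
}

# crop-resize P5 -> P6 uses stride-2 max pooling (1x1 kernel, stride 2)
nd_subsample2 <- function(x) {
  d <- dim(x$value)
  ys <- seq(1, d[1], by = 2)
  xs <- seq(1, d[2], by = 2)
  y <- x$value[ys, xs, , , drop = FALSE]
  out <- new_node(y, list(x))
  out$backfn <- function(g) {
    dim(g) <- dim(y)
    gg <- array(0, d)
    gg[ys, xs, , ] <- g
    accum_grad(x, gg)
  }
  out
}

# RoI-Align: boxes are a plain matrix in feature-map coordinates (no grad)
nd_roi_align <- function(feat, boxes, out_size, sampling = 2L) {
  fv <- feat$value
  d <- dim(fv)
  f3 <- fv
  dim(f3) <- d[1:3]
  y <- .roi_align_fwd(f3, boxes, as.integer(out_size), as.integer(sampling))
  out <- new_node(y, list(feat))
  out$backfn <- function(g) {
    dim(g) <- dim(y)
    df <- .roi_align_bwd(g, boxes, as.integer(d[1:3]),
                         as.integer(out_size), as.integer(sampling))
    dim(df) <- d
    accum_grad(feat, df)
  }
  out
}

# flatten (h,w,c,n) -> (h*w*c, n)
nd_flatten <- function(x) {
  d <- dim(x$value)
  v <- x$value
  dim(v) <- c(prod(d[1:3]), d[4])
  out <- new_node(v, list(x))
  out$backfn <- function(g) {
    dim(g) <- d
    accum_grad(x, g)
  }
  out
}

# fully connected: x (d, n), w (d, k), b (k)  ->  (k, n)
nd_fc <- function(x, w, b = NULL) {
  y <- crossprod(w$value, x$value)
  if (!is.null(b)) y <- y + b$value
  parents <- c(list(x, w), if (!is.null(b)) list(b))
  out <- new_node(y, parents)
  out$backfn <- function(g) {
    dim(g) <- dim(y)
    if (x$requires) accum_grad(x, w$value %*% g)
    accum_grad(w, x$value %*% t(g))
    if (!is.null(b)) accum_grad(b, rowSums(g))
  }
  out
}

# gather elements of the flattened value; backward scatter-adds
nd_gather_vec <- function(x, idx) {
  v <- x$value[idx]
  out <- new_node(v, list(x))
  out$backfn <- function(g) {
    gg <- array(0, dim(x$value) %||% length(x$value))
    # idx may repeat; accumulate
    add <- rowsum(as.numeric(g), idx)
    gg[as.integer(rownames(add))] <- add
    accum_grad(x, gg)
  }
  out
}

nd_reshape <- function(x, new_dim) {
  v <- x$value
  old <- dim(v) %||% length(v)
  dim(v) <- new_dim
  out <- new_node(v, list(x))
  out$backfn <- function(g) {
    dim(g) <- old
    accum_grad(x, g)
  }
  out
}

# ---- scalar losses ----------------------------------------------------

# numerically stable binary cross-entropy with logits; optional per-element
# weights; mean reduction over all elements
nd_bce_logits <- function(logits, targets, weights = NULL) {
  z <- logits$value
  t <- targets
  w <- if (is.null(weights)) 1 else weights
  # log(1 + exp(-|z|)) + max(z, 0) - z*t
  ll <- pmax(z, 0) - z * t + log1p(exp(-abs(z)))
  denom <- length(z)
  val <- sum(w * ll) / denom
  out <- new_node(val, list(logits))
  out$backfn <- function(g) {
    p <- 1 / (1 + exp(-z))
    accum_grad(logits, g * w * (p - t) / denom)
  }
  out
}

# softmax cross-entropy: logits (k, n), labels integer vector in 1..k
nd_softmax_ce <- function(logits, labels) {
  z <- logits$value
  n <- ncol(z)
  zmax <- apply(z, 2, max)
  ez <- exp(sweep(z, 2, zmax))
  p <- sweep(ez, 2, colSums(ez), "/")
  picked <- p[cbind(labels, seq_len(n))]
  val <- -mean(log(pmax(picked, 1e-12)))
  out <- new_node(val, list(logits))
  out$backfn <- function(g) {
    dp <- p
    dp[cbind(labels, seq_len(n))] <- dp[cbind(labels, seq_len(n))] - 1
    accum_grad(logits, g * dp / n)
  }
  out
}

# smooth L1 (Huber, beta = 1): pred and target (4, n); mean over elements
nd_smooth_l1 <- function(pred, target) {
  d <- pred$value - target
  a <- abs(d)
  ll <- ifelse(a < 1, 0.5 * d^2, a - 0.5)
  denom <- length(d)
  val <- sum(ll) / denom
  out <- new_node(val, list(pred))
  out$backfn <- function(g) {
    accum_grad(pred, g * ifelse(a < 1, d, sign(d)) / denom)
  }
  out
}

nd_scale <- function(x, s) {
  out <- new_node(x$value * s, list(x))
  out$backfn <- function(g) accum_grad(x, g * s)
  out
}

nd_sum_scalars <- function(nodes) {
  val <- sum(vapply(nodes, function(n) n$value, numeric(1)))
  out <- new_node(val, nodes)
  out$backfn <- function(g) for (nd in nodes) accum_grad(nd, g)
  out
}

# ---- parameters and optimizer -----------------------------------------

zero_grads <- function(params) {
  for (p in params) p$grad <- NULL
  invisible(NULL)
}

# SGD with momentum and (optional) weight decay. `decay_mask` marks the
# parameters that receive weight decay (conv/fc weights, not biases or BN).
sgd_step <- function(params, lr, momentum = 0.9, weight_decay = 1e-4,
                     state, trainable = NULL, decay_mask = NULL) {
  for (nm in names(params)) {
    if (!is.null(trainable) && !trainable[[nm]]) next
    p <- params[[nm]]
    if (!p$requires || is.null(p$grad)) next
    g <- p$grad
    if (!is.null(decay_mask) && isTRUE(decay_mask[[nm]]) &&
        weight_decay > 0) {
      g <- g + weight_decay * p$value
    }
    v <- state[[nm]]
    if (is.null(v)) v <- 0
    v <- momentum * v - lr * g
    state[[nm]] <- v
    p$value <- p$value + v
  }
  invisible(state)
}
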
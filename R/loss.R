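#' Multi-task loss bundle
#'
#' Container for the components of the detection loss
#' \eqn{L = L_{cls} + L_{box} + L_{mask}} (plus the RPN terms), with the
#' factor-2 weighting of both regression losses and the mask loss. The
#' reported `total` is always the weighted sum of the components.
#'
#' @param l_rpn_cls,l_rpn_box,l_cls,l_box,l_mask Non-negative scalar loss
#'   terms.
#' @param weights Named multipliers; defaults weight the two regression
#'   terms and the mask term by 2.
#' @return A `loss_bundle`: tibble of terms plus a `total` attribute-free
#'   column-sum convenience via [glance()].
#' @export
loss_bundle <- function(l_rpn_cls, l_rpn_box, l_cls, l_box, l_mask,
                        weights = c(l_rpn_cls = 1, l_rpn_box = 2,
                                    l_cls = 1, l_box = 2, l_mask = 2)) {
  terms <- c(l_rpn_cls = l_rpn_cls, l_rpn_box = l_rpn_box,
             l_cls = l_cls, l_box = l_box, l_mask = l_mask)
  if (any(terms < 0)) stop("loss terms must be non-negative")
  structure(list(
    terms = tibble::tibble(term = names(terms), value = unname(terms),
                           weight = unname(weights[names(terms)])),
    total = sum(terms * weights[names(terms)])
  ), class = "loss_bundle")
}

#' @export
print.loss_bundle <- function(x, ...) {
  cat("<loss_bundle>\n")
  print(x$terms)
  cat(sprintf("  total = %.6f\n", x$total))
  invisible(x)
}

#' @rdname loss_bundle
#' @param x A `loss_bundle`.
#' @param ... Unused.
#' @exportS3Method generics::tidy
tidy.loss_bundle <- function(x, ...) x$terms

#' @rdname loss_bundle
#' @exportS3Method generics::glance
glance.loss_bundle <- function(x, ...) {
  tibble::tibble(total = x$total,
                 !!!stats::setNames(as.list(x$terms$value), x$terms$term))
}

#' Per-pixel binary cross-entropy mask loss (closed form)
#'
#' The mask loss applied to a 28x28 logit crop against a binary target
#' crop: mean over pixels of the per-pixel sigmoid binary cross-entropy,
#' optionally multiplied by a border weight crop (see [crop_weights()]).
#' A uniform weight crop of 1 reproduces the unweighted loss exactly.
#'
#' @param logits Numeric array of mask logits.
#' @param target Binary array of the same shape.
#' @param weights Optional per-pixel multipliers of the same shape.
#' @return Scalar loss.
#' @export
mask_bce <- function(logits, target, weights = NULL) {
  if (!all(dim(logits) == dim(target) %||% length(target))) {
    stop("logit and target shapes differ")
  }
  w <- if (is.null(weights)) 1 else weights
  ll <- pmax(logits, 0) - logits * target + log1p(exp(-abs(logits)))
  sum(w * ll) / length(logits)
}
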
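#' Instance sets
#'
#' An `instance_set` is the package's container for a per-image collection of
#' object instances (cells or nuclei): one binary mask per instance plus a
#' tibble of per-instance metadata (label, detection score, class, bounding
#' box). Ground-truth sets have disjoint masks and `NA` scores; predicted sets
#' carry scores in \[0, 1\] and may overlap.
#'
#' Boxes use 0-based, half-open pixel coordinates `[x0, x1) x [y0, y1)` with
#' `x` along columns and `y` along rows, so a full `H x W` frame is the box
#' `(0, 0, W, H)`.
#'
#' @param masks Either a list of logical matrices (all the same dimension) or
#'   a single integer label matrix (0 = background) which is split into one
#'   mask per positive label.
#' @param score Optional numeric vector of detection scores (recycled `NA`
#'   for ground truth).
#' @param class Instance class label, e.g. `"cell"` or `"nucleus"`.
#' @param label Optional integer instance labels; defaults to the labels of
#'   the label matrix or `seq_along(masks)`.
#' @param shape Image dimension `c(H, W)`; required only when `masks` is an
#'   empty list.
#' @return An object of class `instance_set` with fields `masks` (list of
#'   logical matrices), `meta` (tibble with columns `label`, `score`, `class`,
#'   `x0`, `y0`, `x1`, `y1`) and `shape`.
#' @export
instance_set <- function(masks, score = NULL, class = "cell", label = NULL,
                         shape = NULL) {
  if (is.matrix(masks) && !is.list(masks)) {
    lab_mat <- masks
    shape <- dim(lab_mat)
    labs <- sort(unique(as.vector(lab_mat)))
    labs <- labs[labs > 0]
    masks <- lapply(labs, function(l) lab_mat == l)
    if (is.null(label)) label <- as.integer(labs)
  }
  stopifnot(is.list(masks))
  n <- length(masks)
  if (n > 0) {
    dims <- vapply(masks, function(m) paste(dim(m), collapse = "x"), "")
    if (length(unique(dims)) > 1) stop("all masks must share one raster shape")
    shape <- dim(masks[[1]])
    masks <- lapply(masks, function(m) {
      storage.mode(m) <- "logical"
      m
    })
  } else if (is.null(shape)) {
    stop("`shape` is required for an empty instance_set")
  }
  if (is.null(label)) label <- seq_len(n)
  if (is.null(score)) score <- rep(NA_real_, n)
  score <- rep_len(as.numeric(score), n)
  boxes <- mask_boxes(masks, shape)
  meta <- tibble::tibble(
    label = as.integer(label),
    score = score,
    class = rep_len(class, n),
    x0 = boxes[, 1], y0 = boxes[, 2], x1 = boxes[, 3], y1 = boxes[, 4]
  )
  structure(list(masks = masks, meta = meta, shape = as.integer(shape)),
            class = "instance_set")
}

mask_boxes <- function(masks, shape) {
  if (length(masks) == 0) {
    return(matrix(numeric(0), ncol = 4))
  }
  t(vapply(masks, function(m) {
    idx <- which(m, arr.ind = TRUE)
    if (nrow(idx) == 0) return(c(0, 0, 0, 0))
    # rows are y, cols are x; 1-based closed -> 0-based half-open
    c(min(idx[, 2]) - 1, min(idx[, 1]) - 1, max(idx[, 2]), max(idx[, 1]))
  }, numeric(4)))
}

#' @export
print.instance_set <- function(x, ...) {
  cat(sprintf("<instance_set: %d %s instance(s), %dx%d frame>\n",
              n_instances(x), paste(unique(x$meta$class), collapse = "/"),
              x$shape[1], x$shape[2]))
  if (n_instances(x) > 0) print(x$meta, n = 10)
  invisible(x)
}

#' Number of instances in an instance set
#' @param x An `instance_set`.
#' @export
n_instances <- function(x) length(x$masks)

#' Convert an instance set to an integer label matrix
#'
#' Later instances overwrite earlier ones where predicted masks overlap;
#' ground-truth sets are disjoint so the conversion is lossless for them.
#'
#' @param x An `instance_set`.
#' @return Integer matrix, 0 = background, instance labels elsewhere.
#' @export
as_label_matrix <- function(x) {
  lab <- matrix(0L, x$shape[1], x$shape[2])
  for (i in seq_along(x$masks)) lab[x$masks[[i]]] <- x$meta$label[i]
  lab
}

#' Subset an instance set
#' @param x An `instance_set`.
#' @param i Index vector into the instances.
#' @param ... Unused.
#' @export
`[.instance_set` <- function(x, i, ...) {
  structure(list(masks = x$masks[i], meta = x$meta[i, , drop = FALSE],
                 shape = x$shape),
            class = "instance_set")
}

#' @rdname instance_set
#' @param x Object to tidy.
#' @param ... Unused.
#' @exportS3Method generics::tidy
tidy.instance_set <- function(x, ...) {
  dplyr::mutate(x$meta, area = vapply(x$masks, sum, numeric(1)))
}

empty_instance_set <- function(shape, class = "cell") {
  instance_set(list(), class = class, shape = shape)
}

#' Plot an instance set over an intensity image
#'
#' @param object An `instance_set`.
#' @param image Optional background intensity matrix.
#' @param ... Unused.
#' @return A ggplot object showing instance outlines coloured by label.
#' @exportS3Method ggplot2::autoplot
autoplot.instance_set <- function(object, image = NULL, ...) {
  df <- purrr::imap_dfr(object$masks, function(m, i) {
    idx <- which(m & !erode_mask(m), arr.ind = TRUE)
    if (nrow(idx) == 0) return(tibble::tibble())
    tibble::tibble(x = idx[, 2], y = idx[, 1],
                   label = factor(object$meta$label[i]))
  })
  p <- ggplot2::ggplot()
  if (!is.null(image)) {
    img_df <- tibble::tibble(
      x = rep(seq_len(ncol(image)), each = nrow(image)),
      y = rep(seq_len(nrow(image)), ncol(image)),
      v = as.vector(image)
    )
    p <- p + ggplot2::geom_raster(data = img_df,
                                  ggplot2::aes(x = .data$x, y = .data$y,
                                               fill = .data$v)) +
      ggplot2::scale_fill_gradient(low = "black", high = "white",
                                   guide = "none")
  }
  p + ggplot2::geom_point(data = df,
                          ggplot2::aes(x = .data$x, y = .data$y,
                                       colour = .data$label), size = 0.3) +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_fixed() +
    ggplot2::labs(x = NULL, y = NULL, colour = "instance")
}

erode_mask <- function(m) {
  # 4-neighbourhood erosion with FALSE padding
  H <- nrow(m); W <- ncol(m)
  up <- rbind(m[-1, , drop = FALSE], FALSE)
  dn <- rbind(FALSE, m[-H, , drop = FALSE])
  lf <- cbind(m[, -1, drop = FALSE], FALSE)
  rt <- cbind(FALSE, m[, -W, drop = FALSE])
  m & up & dn & lf & rt
}
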
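#' Configuration for ground-truth bootstrapping
#'
#' Ground truth is bootstrapped in two steps: a threshold-based initial
#' instance segmentation with light contour processing (morphological closing
#' plus a minimum-area filter), followed by a nearest-nucleus split of cells
#' that contain more than one nucleus.
#'
#' @param threshold_method `"otsu"` (default) or `"fixed"`.
#' @param fixed_threshold Intensity threshold; required iff
#'   `threshold_method = "fixed"`.
#' @param min_instance_area Components smaller than this (pixels) are
#'   removed.
#' @param morphology_radius Radius of the disc used for morphological
#'   closing of the thresholded foreground (0 disables closing).
#' @return A `bootstrap_config` list.
#' @export
bootstrap_config <- function(threshold_method = c("otsu", "fixed"),
                             fixed_threshold = NULL,
                             min_instance_area = 20,
                             morphology_radius = 2) {
  threshold_method <- match.arg(threshold_method)
  if (threshold_method == "fixed" && is.null(fixed_threshold)) {
    stop("fixed_threshold is required when threshold_method = \"fixed\"")
  }
  if (threshold_method == "otsu" && !is.null(fixed_threshold)) {
    stop("fixed_threshold is only meaningful with threshold_method = \"fixed\"")
  }
  if (min_instance_area < 1) stop("min_instance_area must be >= 1")
  structure(list(threshold_method = threshold_method,
                 fixed_threshold = fixed_threshold,
                 min_instance_area = min_instance_area,
                 morphology_radius = morphology_radius),
            class = "bootstrap_config")
}

#' Threshold-based initial instance segmentation
#'
#' Thresholds an intensity channel (Otsu or fixed), closes the foreground
#' morphologically, labels connected components, and removes components
#' smaller than `min_instance_area`. An all-background image yields an empty
#' instance set.
#'
#' @param channel Numeric intensity matrix with finite values.
#' @param config A [bootstrap_config()].
#' @param class Instance class to record (`"cell"` or `"nucleus"`).
#' @return An `instance_set`, one instance per surviving component.
#' @export
threshold_segment <- function(channel, config = bootstrap_config(),
                              class = "cell") {
  if (length(dim(channel)) != 2) stop("channel must be a 2-D raster")
  if (!all(is.finite(channel))) stop("channel contains non-finite values")
  th <- if (config$threshold_method == "fixed") {
    config$fixed_threshold
  } else {
    rng <- range(channel)
    if (diff(rng) == 0) Inf else EBImage::otsu(EBImage::Image(channel),
                                               range = rng)
  }
  fg <- channel > th
  if (!any(fg)) return(empty_instance_set(dim(channel), class))
  if (config$morphology_radius > 0) {
    brush_size <- 2 * config$morphology_radius + 1
    fg <- EBImage::closing(EBImage::Image(fg * 1),
                           EBImage::makeBrush(brush_size, shape = "disc"))
    fg <- matrix(as.numeric(fg) > 0.5, nrow(channel), ncol(channel))
  }
  lab <- matrix(as.integer(EBImage::bwlabel(EBImage::Image(fg * 1))),
                nrow(channel), ncol(channel))
  areas <- tabulate(lab[lab > 0])
  keep <- which(areas >= config$min_instance_area)
  if (length(keep) == 0) return(empty_instance_set(dim(channel), class))
  relab <- integer(max(lab))
  relab[keep] <- seq_along(keep)
  lab[lab > 0] <- relab[lab[lab > 0]]
  instance_set(lab, class = class)
}

#' Split a multinucleate cell by nearest nucleus
#'
#' Every pixel of the cell mask is assigned to the nucleus whose mask is
#' nearest in Euclidean distance (distance transform to the nucleus mask, not
#' its centroid), mirroring a Voronoi segmentation seeded at the nuclei. Only
#' nuclei that intersect the cell mask participate; ties go to the lower
#' nucleus label. The outputs partition the input mask exactly.
#'
#' @param cell_mask Logical matrix of one cell instance.
#' @param nuclei An `instance_set` of nuclei on the same raster.
#' @return A list of logical masks, one per intersecting nucleus (ordered by
#'   nucleus label). If no nucleus intersects, the input mask is returned
#'   unchanged with attribute `orphan = TRUE` and a warning.
#' @export
split_multinucleate <- function(cell_mask, nuclei) {
  hits <- which(vapply(nuclei$masks, function(nm) any(nm & cell_mask), TRUE))
  if (length(hits) == 0) {
    warning("cell has no intersecting nucleus; returned unchanged")
    out <- list(cell_mask)
    attr(out, "orphan") <- TRUE
    return(out)
  }
  # order by nucleus label so which.min ties resolve to the lower label
  hits <- hits[order(nuclei$meta$label[hits])]
  if (length(hits) == 1) return(list(cell_mask))
  dists <- vapply(hits, function(i) {
    nm <- nuclei$masks[[i]]
    d <- EBImage::distmap(EBImage::Image((!nm) * 1), metric = "euclidean")
    as.numeric(d)
  }, numeric(length(cell_mask)))
  assign_idx <- max.col(-dists, ties.method = "first")
  lapply(seq_along(hits), function(k) {
    m <- matrix(assign_idx == k, nrow(cell_mask), ncol(cell_mask))
    m & cell_mask
  })
}

#' Bootstrap instance ground truth from a raw image pair
#'
#' Segments nuclei from the nucleus channel and cells from the cell channel
#' with [threshold_segment()], then splits every cell containing more than
#' one nucleus with [split_multinucleate()].
#'
#' @param image_pair List with registered matrices `nucleus` and `cell`.
#' @param config A [bootstrap_config()] (applied to both channels).
#' @param nucleus_config Optional separate config for the nucleus channel.
#' @return List with `cells` and `nuclei` `instance_set`s.
#' @export
bootstrap_ground_truth <- function(image_pair, config = bootstrap_config(),
                                   nucleus_config = config) {
  if (!identical(dim(image_pair$nucleus), dim(image_pair$cell))) {
    stop("channels are not registered (different shapes)")
  }
  nuclei <- threshold_segment(image_pair$nucleus, nucleus_config,
                              class = "nucleus")
  cells0 <- threshold_segment(image_pair$cell, config, class = "cell")
  out_masks <- list()
  for (i in seq_len(n_instances(cells0))) {
    pieces <- suppressWarnings(
      split_multinucleate(cells0$masks[[i]], nuclei))
    out_masks <- c(out_masks, pieces)
  }
  cells <- if (length(out_masks) == 0) {
    empty_instance_set(dim(image_pair$cell), "cell")
  } else {
    instance_set(out_masks, class = "cell")
  }
  list(cells = cells, nuclei = nuclei)
}
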
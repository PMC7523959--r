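#' Configuration for rule-based post-processing
#'
#' @param min_region_area Residual foreground regions smaller than this
#'   (pixels) are discarded in the recovery step.
#' @param foreground_threshold Intensity threshold for the cell channel, or
#'   `"otsu"`.
#' @param connectivity 4 or 8 for labelling residual regions.
#' @return A `postprocess_config` list.
#' @export
postprocess_config <- function(min_region_area = 40,
                               foreground_threshold = "otsu",
                               connectivity = 8) {
  if (min_region_area < 1) stop("min_region_area must be >= 1")
  if (!connectivity %in% c(4, 8)) stop("connectivity must be 4 or 8")
  structure(list(min_region_area = min_region_area,
                 foreground_threshold = foreground_threshold,
                 connectivity = connectivity),
            class = "postprocess_config")
}

union_mask <- function(iset) {
  Reduce(`|`, iset$masks, matrix(FALSE, iset$shape[1], iset$shape[2]))
}

#' Merge predicted cells that share a nucleus
#'
#' Every nucleus overlapped by two or more cell masks indicates an
#' over-segmented cell: the overlapping cell masks are unioned into a single
#' instance. Merging is applied to transitive closure (chains of cells linked
#' through shared nuclei collapse into one instance). The merged instance
#' keeps the highest score and the lowest label of its members.
#'
#' @param cells Predicted cell `instance_set`.
#' @param nuclei Nucleus `instance_set` on the same raster.
#' @return A cell `instance_set`.
#' @export
merge_cells_sharing_nucleus <- function(cells, nuclei) {
  nc <- n_instances(cells)
  if (nc <= 1 || n_instances(nuclei) == 0) return(cells)
  edges <- matrix(integer(0), 0, 2)
  for (nm in nuclei$masks) {
    over <- which(vapply(cells$masks, function(cm) any(cm & nm), TRUE))
    if (length(over) >= 2) {
      edges <- rbind(edges, t(utils::combn(over, 2)))
    }
  }
  if (nrow(edges) == 0) return(cells)
  comp <- components_from_edges(edges, nc)
  groups <- split(seq_len(nc), comp)
  masks <- list(); scores <- numeric(0); labels <- integer(0)
  for (g in groups) {
    masks <- c(masks, list(Reduce(`|`, cells$masks[g])))
    scores <- c(scores, suppressWarnings(max(cells$meta$score[g])))
    labels <- c(labels, min(cells$meta$label[g]))
  }
  instance_set(masks, score = scores, class = cells$meta$class[1] %||% "cell",
               label = labels)
}

#' Recover foreground regions missed by the predictions
#'
#' Subtracts the union of predicted masks from a threshold-based foreground
#' segmentation of the cell channel, closes the residual morphologically,
#' discards components below `min_region_area`, and then handles each
#' remaining region: (a) appended to the unique adjacent cell instance,
#' (b) discarded when adjacent to several cells, (c) promoted to a new cell
#' instance when adjacent to none. Adjacency is 8-connectivity between the
#' region and a cell mask.
#'
#' @param cell_channel Intensity matrix of the cytoplasm stain.
#' @param cells Predicted cell `instance_set`.
#' @param config A [postprocess_config()].
#' @return A cell `instance_set`.
#' @export
recover_uncovered_regions <- function(cell_channel, cells,
                                      config = postprocess_config()) {
  th <- if (identical(config$foreground_threshold, "otsu")) {
    rng <- range(cell_channel)
    if (diff(rng) == 0) Inf else EBImage::otsu(EBImage::Image(cell_channel),
                                               range = rng)
  } else {
    config$foreground_threshold
  }
  fg <- cell_channel > th
  residual <- fg & !union_mask(cells)
  if (!any(residual)) return(cells)
  residual <- EBImage::closing(EBImage::Image(residual * 1),
                               EBImage::makeBrush(3, shape = "disc"))
  residual <- matrix(as.numeric(residual) > 0.5,
                     nrow(cell_channel), ncol(cell_channel))
  residual <- residual & !union_mask(cells)  # closing must not eat into cells
  lab <- matrix(as.integer(EBImage::bwlabel(EBImage::Image(residual * 1))),
                nrow(cell_channel), ncol(cell_channel))
  if (max(lab) == 0) return(cells)
  masks <- cells$masks
  scores <- cells$meta$score
  labels <- cells$meta$label
  next_label <- if (length(labels)) max(labels) + 1L else 1L
  dilated <- lapply(cells$masks, dilate8)
  for (r in seq_len(max(lab))) {
    region <- lab == r
    if (sum(region) < config$min_region_area) next
    touching <- which(vapply(dilated, function(d) any(d & region), TRUE))
    if (length(touching) == 1) {
      masks[[touching]] <- masks[[touching]] | region     # rule (a)
    } else if (length(touching) == 0) {                   # rule (c)
      masks <- c(masks, list(region))
      scores <- c(scores, if (length(scores) && any(is.finite(scores)))
        min(scores, na.rm = TRUE) else 0.5)
      labels <- c(labels, next_label)
      next_label <- next_label + 1L
    }                                                     # rule (b): drop
  }
  if (length(masks) == 0) return(cells)
  instance_set(masks, score = scores, class = cells$meta$class[1] %||% "cell",
               label = labels)
}

dilate8 <- function(m) {
  out <- m
  for (s in list(c(1, 0), c(-1, 0), c(0, 1), c(0, -1),
                 c(1, 1), c(1, -1), c(-1, 1), c(-1, -1))) {
    out <- out | shift_mat(m, s[1], s[2], fill = FALSE)
  }
  out
}

#' Expand cells to cover their nuclei
#'
#' Nucleus pixels not covered by any cell are added to the unique overlapping
#' cell when one exists (the largest-overlap cell if several overlap); an
#' entirely uncovered nucleus becomes a new cell instance with the nucleus
#' shape.
#'
#' @param cells Cell `instance_set`.
#' @param nuclei Nucleus `instance_set`.
#' @return A cell `instance_set` in which every nucleus pixel is covered.
#' @export
expand_cells_to_nuclei <- function(cells, nuclei) {
  masks <- cells$masks
  scores <- cells$meta$score
  labels <- cells$meta$label
  next_label <- if (length(labels)) max(labels) + 1L else 1L
  covered <- if (length(masks)) Reduce(`|`, masks) else
    matrix(FALSE, nuclei$shape[1], nuclei$shape[2])
  for (nm in nuclei$masks) {
    uncovered <- nm & !covered
    if (!any(uncovered)) next
    over <- which(vapply(masks, function(cm) any(cm & nm), TRUE))
    if (length(over) >= 1) {
      if (length(over) > 1) {
        sizes <- vapply(over, function(i) sum(masks[[i]] & nm), numeric(1))
        over <- over[which.max(sizes)]
      }
      masks[[over]] <- masks[[over]] | uncovered
    } else {
      masks <- c(masks, list(nm))
      scores <- c(scores, if (length(scores) && any(is.finite(scores)))
        min(scores, na.rm = TRUE) else 0.5)
      labels <- c(labels, next_label)
      next_label <- next_label + 1L
    }
    covered <- covered | nm
  }
  if (length(masks) == 0) {
    return(empty_instance_set(nuclei$shape, "cell"))
  }
  instance_set(masks, score = scores, class = "cell", label = labels)
}

#' Rule-based post-processing of predicted cell instances
#'
#' Applies the three refinement steps in order: merge cells sharing a
#' nucleus, recover uncovered foreground regions from the cell channel, and
#' expand cells to cover their nuclei. After completion every nucleus pixel
#' is covered by exactly one cell instance, and the operation is idempotent.
#'
#' @param cells Predicted cell `instance_set`.
#' @param nuclei Predicted (or ground-truth) nucleus `instance_set`.
#' @param cell_channel Intensity matrix of the cytoplasm stain.
#' @param config A [postprocess_config()].
#' @return A refined cell `instance_set`.
#' @export
postprocess <- function(cells, nuclei, cell_channel,
                        config = postprocess_config()) {
  out <- merge_cells_sharing_nucleus(cells, nuclei)
  out <- recover_uncovered_regions(cell_channel, out, config)
  expand_cells_to_nuclei(out, nuclei)
}
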
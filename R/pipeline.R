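#' Read a registered two-channel image pair
#'
#' Accepts either one 2-channel TIFF stack (nucleus first) or two
#' single-channel TIFF paths. Intensities are returned as numeric matrices on
#' the stored scale (16-bit files map to \[0, 1\] as written by
#' [write_intensity_tiff()]).
#'
#' @param nucleus Path to the nucleus-channel TIFF, or to a 2-channel stack.
#' @param cell Path to the cell-channel TIFF (omit for a stack).
#' @return List with matrices `nucleus` and `cell` of identical dimension.
#' @export
read_image_pair <- function(nucleus, cell = NULL) {
  if (is.null(cell)) {
    img <- read_tiff_checked(nucleus)
    if (length(dim(img)) != 3 || dim(img)[3] < 2) {
      stop("expected a 2-channel stack in ", nucleus)
    }
    pair <- list(nucleus = img[, , 1], cell = img[, , 2])
  } else {
    pair <- list(nucleus = as_channel(read_tiff_checked(nucleus)),
                 cell = as_channel(read_tiff_checked(cell)))
  }
  if (!identical(dim(pair$nucleus), dim(pair$cell))) {
    stop("nucleus and cell channels have different shapes")
  }
  pair
}

as_channel <- function(img) {
  if (length(dim(img)) == 3) img[, , 1] else img
}

read_tiff_checked <- function(path) {
  if (!file.exists(path)) stop("cannot read TIFF: ", path)
  tiff::readTIFF(path)
}

#' Write an intensity raster as a 16-bit TIFF
#'
#' Values are clipped to \[0, 1\] and stored at 16-bit depth, so a
#' write/read round trip is exact on the 1/65535 grid.
#'
#' @param mat Numeric matrix in \[0, 1\].
#' @param path Output path.
#' @export
write_intensity_tiff <- function(mat, path) {
  q <- round(pmin(pmax(mat, 0), 1) * 65535) / 65535
  ok <- try(tiff::writeTIFF(q, path, bits.per.sample = 16), silent = TRUE)
  if (inherits(ok, "try-error")) stop("cannot write TIFF: ", path)
  invisible(path)
}

#' Write / read 16-bit instance label masks
#'
#' Labels (0 = background) are stored losslessly in the 16-bit sample range.
#'
#' @param lab Integer label matrix with values in 0..65535.
#' @param path TIFF path.
#' @export
write_label_tiff <- function(lab, path) {
  if (max(lab) > 65535) stop("label values exceed 16-bit range")
  ok <- try(tiff::writeTIFF(lab / 65535, path, bits.per.sample = 16),
            silent = TRUE)
  if (inherits(ok, "try-error")) stop("cannot write TIFF: ", path)
  invisible(path)
}

#' @rdname write_label_tiff
#' @export
read_label_mask <- function(path) {
  img <- as_channel(read_tiff_checked(path))
  matrix(as.integer(round(img * 65535)), nrow(img), ncol(img))
}

#' Read a dataset manifest written by [write_dataset()]
#'
#' @param directory Dataset directory containing `manifest.json`.
#' @return Tibble manifest with existence-checked paths.
#' @export
read_manifest <- function(directory) {
  path <- file.path(directory, "manifest.json")
  if (!file.exists(path)) stop("no manifest.json under ", directory)
  m <- tibble::as_tibble(jsonlite::read_json(path, simplifyVector = TRUE))
  for (col in c("nucleus", "cell", "cell_mask", "nucleus_mask")) {
    missing <- !file.exists(m[[col]])
    if (any(missing)) stop("manifest references missing file(s): ",
                           paste(m[[col]][missing], collapse = ", "))
  }
  m
}

#' Extract the clustered-cells subset from ground truth
#'
#' Finds connected groups of two or more mutually touching cell instances
#' (8-adjacency between masks) and emits one fixed-size patch centred on each
#' cluster (clamped to the frame). Isolated cells yield no patches; every
#' patch contains at least one cluster.
#'
#' @param samples List of `synthetic_sample`s (or any list with `image_pair`
#'   and `cell_truth`/`nucleus_truth` fields).
#' @param patch_size Patch side length in pixels (default 256).
#' @return List of patch samples with cropped channels and truth.
#' @export
make_clustered_subset <- function(samples, patch_size = 256) {
  out <- list()
  for (s in samples) {
    lab <- as_label_matrix(s$cell_truth)
    adj <- label_adjacency(lab)
    if (nrow(adj) == 0) next
    g <- components_from_edges(adj, n_instances(s$cell_truth))
    clusters <- split(seq_along(g), g)
    clusters <- clusters[vapply(clusters, length, 0L) >= 2]
    for (cl in clusters) {
      labs <- s$cell_truth$meta$label[cl]
      px <- which(matrix(lab %in% labs, nrow(lab), ncol(lab)), arr.ind = TRUE)
      cy <- mean(px[, 1]); cx <- mean(px[, 2])
      H <- nrow(lab); W <- ncol(lab)
      half <- patch_size / 2
      y0 <- round(min(max(cy - half, 0), max(H - patch_size, 0)))
      x0 <- round(min(max(cx - half, 0), max(W - patch_size, 0)))
      y1 <- min(y0 + patch_size, H); x1 <- min(x0 + patch_size, W)
      out <- c(out, list(crop_sample(s, y0 + 1, y1, x0 + 1, x1)))
    }
  }
  out
}

# 8-adjacency edges between instance labels in a label matrix
label_adjacency <- function(lab) {
  edges <- matrix(integer(0), 0, 2)
  shifts <- list(c(0, 1), c(1, 0), c(1, 1), c(1, -1))
  for (sft in shifts) {
    sh <- shift_mat(lab, sft[1], sft[2], fill = 0L)
    sel <- lab > 0 & sh > 0 & sh != lab
    if (any(sel)) {
      e <- cbind(lab[sel], sh[sel])
      edges <- rbind(edges, t(apply(e, 1, sort)))
    }
  }
  unique(edges)
}

components_from_edges <- function(edges, n) {
  parent <- seq_len(n)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  if (nrow(edges) > 0) {
    for (k in seq_len(nrow(edges))) {
      a <- find(edges[k, 1]); b <- find(edges[k, 2])
      if (a != b) parent[max(a, b)] <- min(a, b)
    }
  }
  vapply(seq_len(n), find, 0L)
}

crop_sample <- function(s, y0, y1, x0, x1) {
  crop_set <- function(iset) {
    masks <- lapply(iset$masks, function(m) m[y0:y1, x0:x1, drop = FALSE])
    keep <- vapply(masks, any, TRUE)
    if (!any(keep)) {
      return(empty_instance_set(c(y1 - y0 + 1, x1 - x0 + 1),
                                iset$meta$class[1] %||% "cell"))
    }
    instance_set(masks[keep], score = iset$meta$score[keep],
                 class = iset$meta$class[keep],
                 label = iset$meta$label[keep])
  }
  out <- s
  out$cell_truth <- crop_set(s$cell_truth)
  out$nucleus_truth <- crop_set(s$nucleus_truth)
  if (!is.null(s$image_pair)) {
    out$image_pair <- list(
      nucleus = s$image_pair$nucleus[y0:y1, x0:x1, drop = FALSE],
      cell = s$image_pair$cell[y0:y1, x0:x1, drop = FALSE])
  }
  if (!is.null(out$config)) {
    out$config$image_height <- y1 - y0 + 1L
    out$config$image_width <- x1 - x0 + 1L
  }
  keep_nuc <- out$nucleus_truth$meta$label
  out$nucleus_to_cell <- s$nucleus_to_cell[as.character(keep_nuc)]
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Evaluate several prediction sets into a publication-style report table
#'
#' Produces one row per method with the nine per-threshold APs, the mean AP,
#' and (when a baseline method is named) the relative mean-AP improvement in
#' percent.
#'
#' @param predictions Named list; each element is a list of predicted
#'   `instance_set`s (one per image).
#' @param gts List of ground-truth `instance_set`s.
#' @param mode `"mask"` or `"box"`.
#' @param baseline Optional method name used as the improvement baseline.
#' @return A tibble with columns `method`, `ap_0.5` ... `ap_0.9`, `mean_ap`,
#'   `improvement_pct`.
#' @export
run_experiment <- function(predictions, gts, mode = c("mask", "box"),
                           baseline = NULL) {
  mode <- match.arg(mode)
  reports <- purrr::map(predictions, evaluate_detections, gts = gts,
                        mode = mode)
  rows <- purrr::imap_dfr(reports, function(r, name) {
    aps <- stats::setNames(as.list(r$ap_by_threshold$ap),
                           paste0("ap_", r$ap_by_threshold$threshold))
    tibble::tibble(method = name, !!!aps, mean_ap = r$mean_ap)
  })
  if (!is.null(baseline)) {
    if (!baseline %in% rows$method) stop("unknown baseline method: ", baseline)
    base <- rows$mean_ap[rows$method == baseline]
    rows$improvement_pct <- vapply(rows$mean_ap, relative_improvement,
                                   numeric(1), baseline_mean_ap = base)
  }
  rows
}
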
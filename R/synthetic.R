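#' Configuration for synthetic two-channel fluorescence scenes
#'
#' The generator emulates 20x fluorescence frames of adherent macrophage-like
#' cells: round, well-separated nuclei (DNA stain channel) inside irregular
#' star-convex cytoplasm outlines (cytoplasm stain channel), a fraction of
#' cells arranged in touching clusters where the cytoplasm signal dims
#' faintly along the cell-cell contact band, occasional cells carrying two
#' nuclei (mitotic phase), and border-truncated instances at the frame edge.
#'
#' @param image_height,image_width Frame size in pixels.
#' @param n_cells Number of cell instances to place.
#' @param cluster_fraction Fraction of cells placed in touching clusters,
#'   in \[0, 1\].
#' @param multinucleate_rate Probability that a cell carries 2 nuclei.
#' @param nucleus_radius_range,cell_radius_range Radius ranges `(min, max)`
#'   in pixels; nuclei must be strictly smaller than cells.
#' @param contact_attenuation Relative dimming of the cytoplasm signal along
#'   cell-cell boundary bands, in \[0, 1\] (0 = no dimming).
#' @param noise_sd Standard deviation of additive Gaussian intensity noise.
#' @param background_level Background intensity (channels are kept in
#'   \[0, 1\]).
#' @param cell_intensity,nucleus_intensity Interior plateau intensities of
#'   the two stains.
#' @param seed Integer seed; all randomness of a scene flows from it.
#' @return A `scene_config` list.
#' @export
scene_config <- function(image_height = 512, image_width = 512,
                         n_cells = 12, cluster_fraction = 0.5,
                         multinucleate_rate = 0.05,
                         nucleus_radius_range = c(6, 10),
                         cell_radius_range = c(14, 26),
                         contact_attenuation = 0.3,
                         noise_sd = 0.02, background_level = 0.05,
                         cell_intensity = 0.55, nucleus_intensity = 0.8,
                         seed = 1L) {
  stopifnot(
    image_height >= 32, image_width >= 32, n_cells >= 0,
    cluster_fraction >= 0, cluster_fraction <= 1,
    multinucleate_rate >= 0, multinucleate_rate <= 1,
    all(nucleus_radius_range > 0), all(cell_radius_range > 0),
    max(nucleus_radius_range) < min(cell_radius_range),
    contact_attenuation >= 0, contact_attenuation <= 1,
    noise_sd >= 0, background_level >= 0
  )
  structure(list(
    image_height = as.integer(image_height),
    image_width = as.integer(image_width),
    n_cells = as.integer(n_cells),
    cluster_fraction = cluster_fraction,
    multinucleate_rate = multinucleate_rate,
    nucleus_radius_range = nucleus_radius_range,
    cell_radius_range = cell_radius_range,
    contact_attenuation = contact_attenuation,
    noise_sd = noise_sd, background_level = background_level,
    cell_intensity = cell_intensity, nucleus_intensity = nucleus_intensity,
    seed = as.integer(seed)
  ), class = "scene_config")
}

# star-convex radial profile: ellipse base with low-order harmonic ripple.
# Returns a function of angle giving the outline radius.
star_profile <- function(base_radius, rng_draws) {
  ratio <- 0.7 + 0.3 * rng_draws$ratio          # minor/major axis
  phi <- rng_draws$phi                           # orientation
  amps <- rng_draws$amps * c(0.10, 0.07, 0.05)   # harmonics 2..4
  phases <- rng_draws$phases
  function(theta) {
    # ellipse radius at angle theta (rotated by phi)
    a <- base_radius; b <- base_radius * ratio
    ct <- cos(theta - phi); st <- sin(theta - phi)
    r_ell <- a * b / sqrt((b * ct)^2 + (a * st)^2)
    ripple <- 1 +
      amps[1] * cos(2 * theta + phases[1]) +
      amps[2] * cos(3 * theta + phases[2]) +
      amps[3] * cos(4 * theta + phases[3])
    r_ell * pmax(ripple, 0.7)
  }
}

draw_profile <- function(base_radius) {
  star_profile(base_radius, list(
    ratio = stats::runif(1), phi = stats::runif(1, 0, pi),
    amps = stats::runif(3), phases = stats::runif(3, 0, 2 * pi)
  ))
}

# Rasterize one star-convex shape: returns the normalized radial coordinate
# d / R(theta) for every pixel of the frame (Inf far away), so overlapping
# shapes can be partitioned by the pixel-wise argmin (a Voronoi-like split
# in normalized radial distance).
shape_field <- function(cx, cy, profile, rmax, H, W) {
  y0 <- max(1, floor(cy - rmax)); y1 <- min(H, ceiling(cy + rmax))
  x0 <- max(1, floor(cx - rmax)); x1 <- min(W, ceiling(cx + rmax))
  f <- matrix(Inf, H, W)
  if (y0 > y1 || x0 > x1) return(f)
  ys <- y0:y1; xs <- x0:x1
  dy <- ys - cy
  dx <- xs - cx
  D <- sqrt(outer(dy^2, dx^2, `+`))
  TH <- atan2(outer(dy, rep(1, length(dx))), outer(rep(1, length(dy)), dx))
  R <- matrix(profile(as.vector(TH)), length(ys), length(xs))
  f[ys, xs] <- D / pmax(R, 1e-9)
  f
}

#' Sample the instance geometry of a synthetic scene
#'
#' Places `n_cells` star-convex cells (a requested fraction in touching
#' clusters, resolved by a normalized-radial Voronoi partition of overlap
#' regions), then one round nucleus per cell — two with probability
#' `multinucleate_rate` — strictly inside the cell mask. Cells may be
#' truncated by the frame border. Deterministic given `config$seed`.
#'
#' @param config A [scene_config()].
#' @return A `synthetic_sample` without rendered channels: list with
#'   `cell_truth` and `nucleus_truth` (`instance_set`s) and `nucleus_to_cell`
#'   (named integer vector: nucleus label -> cell label).
#' @export
sample_geometry <- function(config) {
  stopifnot(inherits(config, "scene_config"))
  H <- config$image_height; W <- config$image_width
  n <- config$n_cells
  withr_seed <- config$seed
  old <- globalenv()$.Random.seed
  set.seed(withr_seed)
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  })

  if (n == 0) {
    return(structure(list(
      cell_truth = empty_instance_set(c(H, W), "cell"),
      nucleus_truth = empty_instance_set(c(H, W), "nucleus"),
      nucleus_to_cell = stats::setNames(integer(0), character(0)),
      config = config
    ), class = "synthetic_sample"))
  }

  rr <- config$cell_radius_range
  n_clustered <- round(config$cluster_fraction * n)
  if (n_clustered == 1) n_clustered <- if (n >= 2) 2 else 0
  # partition clustered cells into clusters of size 2..4
  cluster_sizes <- integer(0)
  left <- n_clustered
  while (left > 0) {
    s <- min(left, sample(2:4, 1))
    if (left - s == 1) s <- s + 1   # avoid a leftover singleton
    s <- min(s, left)
    cluster_sizes <- c(cluster_sizes, s)
    left <- left - s
  }

  max_tries <- 200L
  for (attempt in seq_len(max_tries)) {
    radii <- stats::runif(n, rr[1], rr[2])
    centers <- matrix(NA_real_, n, 2) # (x, y)
    profiles <- vector("list", n)
    margin <- 4
    placed <- 0L
    ok <- TRUE
    place_free <- function(r_new, existing_idx, sep_factor = 1.15) {
      for (k in seq_len(60L)) {
        cx <- stats::runif(1, margin, W - margin)
        cy <- stats::runif(1, margin, H - margin)
        good <- TRUE
        for (j in existing_idx) {
          d <- sqrt((cx - centers[j, 1])^2 + (cy - centers[j, 2])^2)
          if (d < sep_factor * (r_new + radii[j])) { good <- FALSE; break }
        }
        if (good) return(c(cx, cy))
      }
      NULL
    }
    # clusters first
    idx <- 1L
    for (s in cluster_sizes) {
      members <- idx:(idx + s - 1)
      anchor <- place_free(radii[members[1]] + sum(radii[members]) / 2,
                           seq_len(placed))
      if (is.null(anchor)) { ok <- FALSE; break }
      centers[members[1], ] <- anchor
      placed <- placed + 1L
      for (m in members[-1]) {
        got <- FALSE
        for (k in seq_len(60L)) {
          ref <- sample(members[members < m & members >= members[1]], 1)
          ang <- stats::runif(1, 0, 2 * pi)
          # centers closer than the radius sum -> raw shapes overlap,
          # guaranteeing shared boundaries after the Voronoi split
          d <- 0.75 * (radii[m] + radii[ref])
          cx <- centers[ref, 1] + d * cos(ang)
          cy <- centers[ref, 2] + d * sin(ang)
          if (cx < margin || cx > W - margin ||
              cy < margin || cy > H - margin) next
          # avoid swallowing: keep at least a nucleus-sized offset
          if (d < 1.2 * max(config$nucleus_radius_range)) next
          clash <- FALSE
          for (j in seq_len(placed)) {
            jj <- which(!is.na(centers[, 1]))[j]
            if (jj %in% members) next
            dd <- sqrt((cx - centers[jj, 1])^2 + (cy - centers[jj, 2])^2)
            if (dd < 1.15 * (radii[m] + radii[jj])) { clash <- TRUE; break }
          }
          if (!clash) {
            centers[m, ] <- c(cx, cy); placed <- placed + 1L; got <- TRUE
            break
          }
        }
        if (!got) { ok <- FALSE; break }
      }
      if (!ok) break
      idx <- idx + s
    }
    if (ok) {
      for (i in idx:n) {
        if (i > n) break
        p <- place_free(radii[i], which(!is.na(centers[, 1])))
        if (is.null(p)) { ok <- FALSE; break }
        centers[i, ] <- p
        placed <- placed + 1L
      }
    }
    if (!ok) next

    for (i in seq_len(n)) profiles[[i]] <- draw_profile(radii[i])

    # rasterize: normalized radial fields, argmin partition of overlaps
    lab <- matrix(0L, H, W)
    best <- matrix(Inf, H, W)
    for (i in seq_len(n)) {
      f <- shape_field(centers[i, 1], centers[i, 2], profiles[[i]],
                       radii[i] * 1.6, H, W)
      upd <- f <= 1 & f < best
      lab[upd] <- i
      best[upd] <- f[upd]
    }
    if (length(unique(lab[lab > 0])) < n) next  # a cell vanished entirely

    # nuclei: round (slightly elliptic) disks strictly inside the cell mask
    nrr <- config$nucleus_radius_range
    two <- stats::runif(n) < config$multinucleate_rate
    nuc_masks <- list(); nuc_to_cell <- integer(0)
    nuc_centers <- matrix(numeric(0), 0, 3)  # (cx, cy, r)
    min_gap <- 4  # nuclei stay clearly separable (survives closing radius 2)
    nuc_ok <- TRUE
    for (i in seq_len(n)) {
      cell_px <- lab == i
      k_nuc <- if (two[i]) 2L else 1L
      placed_nuc <- 0L
      dirs <- stats::runif(1, 0, 2 * pi)
      for (kk in seq_len(k_nuc)) {
        done <- FALSE
        for (t in seq_len(40L)) {
          r_n <- stats::runif(1, nrr[1], nrr[2])
          if (k_nuc == 2) {
            off <- (0.45 + 0.1 * stats::runif(1)) * radii[i]
            ang <- dirs + (kk - 1) * pi + stats::runif(1, -0.4, 0.4)
          } else {
            off <- stats::runif(1, 0, 0.3 * radii[i])
            ang <- stats::runif(1, 0, 2 * pi)
          }
          cx <- centers[i, 1] + off * cos(ang)
          cy <- centers[i, 2] + off * sin(ang)
          if (nrow(nuc_centers) > 0) {
            d <- sqrt((cx - nuc_centers[, 1])^2 + (cy - nuc_centers[, 2])^2)
            if (any(d < r_n + nuc_centers[, 3] + min_gap)) next
          }
          m <- disk_mask(cx, cy, r_n, H, W)
          if (sum(m) >= 4 && all(cell_px[m])) {
            nuc_masks <- c(nuc_masks, list(m))
            nuc_to_cell <- c(nuc_to_cell, i)
            nuc_centers <- rbind(nuc_centers, c(cx, cy, r_n))
            placed_nuc <- placed_nuc + 1L
            done <- TRUE
            break
          }
          # shrink and retry near the end of the budget
          if (t > 25) nrr <- c(max(2, nrr[1] * 0.9), max(3, nrr[2] * 0.9))
        }
        nrr <- config$nucleus_radius_range
        if (!done) { nuc_ok <- FALSE; break }  # retry the whole scene
      }
      if (!nuc_ok) break
    }
    if (!nuc_ok) next

    cell_truth <- instance_set(lab, class = "cell")
    nucleus_truth <- instance_set(nuc_masks, class = "nucleus",
                                  label = seq_along(nuc_masks))
    names(nuc_to_cell) <- seq_along(nuc_masks)
    return(structure(list(
      cell_truth = cell_truth, nucleus_truth = nucleus_truth,
      nucleus_to_cell = nuc_to_cell, config = config
    ), class = "synthetic_sample"))
  }
  stop(sprintf(
    "could not pack %d cells of radius %.0f-%.0f into a %dx%d frame after %d attempts",
    n, rr[1], rr[2], H, W, max_tries))
}

disk_mask <- function(cx, cy, r, H, W) {
  y0 <- max(1, floor(cy - r)); y1 <- min(H, ceiling(cy + r))
  x0 <- max(1, floor(cx - r)); x1 <- min(W, ceiling(cx + r))
  m <- matrix(FALSE, H, W)
  if (y0 > y1 || x0 > x1) return(m)
  ys <- y0:y1; xs <- x0:x1
  D <- outer((ys - cy)^2, (xs - cx)^2, `+`)
  m[ys, xs] <- D <= r^2
  m
}

#' Render the two fluorescence channels of a synthetic scene
#'
#' The nucleus channel is bright inside nuclei; the cell channel is bright
#' inside cells, with the signal dimmed by `contact_attenuation` along 2-px
#' bands at cell-cell contacts (the faint boundaries that make clustered
#' cells hard to separate). Gaussian noise with `noise_sd` is added to both
#' channels; rendering is a pure function of `(truth, config)` via
#' `config$seed`.
#'
#' @param truth A `synthetic_sample` from [sample_geometry()].
#' @param config A [scene_config()]; defaults to the one stored in `truth`.
#' @return The `truth` object with an `image_pair` field: list of matrices
#'   `nucleus` and `cell` in \[0, 1\].
#' @export
render_channels <- function(truth, config = truth$config) {
  H <- config$image_height; W <- config$image_width
  cell_lab <- as_label_matrix(truth$cell_truth)
  nuc_any <- Reduce(`|`, truth$nucleus_truth$masks,
                    matrix(FALSE, H, W))
  bg <- config$background_level
  cell_ch <- matrix(bg, H, W)
  cell_ch[cell_lab > 0] <- config$cell_intensity
  band <- contact_band(cell_lab)
  cell_ch[band] <- config$cell_intensity * (1 - config$contact_attenuation)
  nuc_ch <- matrix(bg, H, W)
  nuc_ch[nuc_any] <- config$nucleus_intensity
  if (config$noise_sd > 0) {
    old <- globalenv()$.Random.seed
    set.seed(config$seed + 777L)
    cell_ch <- cell_ch + stats::rnorm(H * W, 0, config$noise_sd)
    nuc_ch <- nuc_ch + stats::rnorm(H * W, 0, config$noise_sd)
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
    cell_ch <- pmin(pmax(cell_ch, 0), 1)
    nuc_ch <- pmin(pmax(nuc_ch, 0), 1)
  }
  truth$image_pair <- list(nucleus = nuc_ch, cell = cell_ch)
  truth
}

# pixels of a cell that touch (8-neighbourhood) a *different* cell
contact_band <- function(lab) {
  H <- nrow(lab); W <- ncol(lab)
  band <- matrix(FALSE, H, W)
  shifts <- list(c(1, 0), c(-1, 0), c(0, 1), c(0, -1),
                 c(1, 1), c(1, -1), c(-1, 1), c(-1, -1))
  for (s in shifts) {
    sh <- shift_mat(lab, s[1], s[2], fill = 0L)
    band <- band | (lab > 0 & sh > 0 & sh != lab)
  }
  band
}

shift_mat <- function(m, dy, dx, fill = 0L) {
  H <- nrow(m); W <- ncol(m)
  out <- matrix(fill, H, W)
  ys <- seq_len(H) - dy; xs <- seq_len(W) - dx
  oky <- ys >= 1 & ys <= H; okx <- xs >= 1 & xs <= W
  out[oky, okx] <- m[ys[oky], xs[okx]]
  out
}

#' Simulate a complete synthetic scene (geometry + rendering)
#'
#' @param config A [scene_config()].
#' @return A `synthetic_sample` with `image_pair`, `cell_truth`,
#'   `nucleus_truth` and `nucleus_to_cell`.
#' @export
simulate_scene <- function(config = scene_config()) {
  render_channels(sample_geometry(config))
}

#' Generate a dataset of synthetic scenes
#'
#' Per-sample seeds are derived from the master seed by a fixed affine
#' counter so each scene has an independent reproducible stream.
#'
#' @param n Number of scenes.
#' @param config Template [scene_config()]; its `seed` is replaced per scene.
#' @param seed Master seed.
#' @return List of `synthetic_sample`s.
#' @export
generate_dataset <- function(n, config = scene_config(), seed = 1L) {
  lapply(seq_len(n), function(i) {
    cfg <- config
    cfg$seed <- as.integer((seed * 1000L + i * 7919L) %% .Machine$integer.max)
    simulate_scene(cfg)
  })
}

#' @export
print.synthetic_sample <- function(x, ...) {
  cat(sprintf(
    "<synthetic_sample: %d cells, %d nuclei, %dx%d frame%s>\n",
    n_instances(x$cell_truth), n_instances(x$nucleus_truth),
    x$config$image_height, x$config$image_width,
    if (is.null(x$image_pair)) ", unrendered" else ""))
  invisible(x)
}

#' Write a synthetic dataset to disk
#'
#' Writes per-sample single-channel TIFFs (nucleus, cell; 16-bit), 16-bit
#' label-mask TIFFs for both channels, and a JSON manifest with a train/test
#' split. Everything round-trips losslessly through [read_image_pair()] and
#' [read_label_mask()].
#'
#' @param samples List of rendered `synthetic_sample`s.
#' @param directory Output directory (created if missing).
#' @param n_train Number of samples labelled `train` in the manifest split;
#'   the remainder are `test`.
#' @return The manifest as a tibble (invisibly also written to
#'   `manifest.json`).
#' @export
write_dataset <- function(samples, directory, n_train = NULL) {
  dir.create(directory, showWarnings = FALSE, recursive = TRUE)
  n <- length(samples)
  if (is.null(n_train)) n_train <- floor(0.8 * n)
  split <- c(rep("train", min(n_train, n)),
             rep("test", max(0, n - n_train)))
  rows <- purrr::imap(samples, function(s, i) {
    base <- sprintf("sample_%03d", i)
    paths <- list(
      nucleus = file.path(directory, paste0(base, "_nucleus.tif")),
      cell = file.path(directory, paste0(base, "_cell.tif")),
      cell_mask = file.path(directory, paste0(base, "_cell_mask.tif")),
      nucleus_mask = file.path(directory, paste0(base, "_nucleus_mask.tif"))
    )
    write_intensity_tiff(s$image_pair$nucleus, paths$nucleus)
    write_intensity_tiff(s$image_pair$cell, paths$cell)
    write_label_tiff(as_label_matrix(s$cell_truth), paths$cell_mask)
    write_label_tiff(as_label_matrix(s$nucleus_truth), paths$nucleus_mask)
    tibble::tibble(sample = base, split = split[i],
                   nucleus = paths$nucleus, cell = paths$cell,
                   cell_mask = paths$cell_mask,
                   nucleus_mask = paths$nucleus_mask)
  })
  manifest <- dplyr::bind_rows(rows)
  jsonlite::write_json(manifest, file.path(directory, "manifest.json"),
                       dataframe = "rows", auto_unbox = TRUE, digits = NA)
  invisible(manifest)
}
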
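#' Configuration for the border-weighted mask loss
#'
#' Pixels near cell contours are up-weighted in the mask loss so training
#' focuses on the hard-to-segment cell borders, especially inside clusters.
#' The weight field is a Gaussian blur of the 1-px instance contours,
#' peak-normalized and mapped affinely to `[1, max_weight]`.
#'
#' @param kernel_size Odd kernel side length in pixels (default 25).
#' @param sigma Gaussian standard deviation in pixels (default 5).
#' @param max_weight Maximum per-pixel loss multiplier (default 2).
#' @return A `weight_config` list.
#' @export
weight_config <- function(kernel_size = 25, sigma = 5, max_weight = 2) {
  if (kernel_size %% 2 == 0) stop("kernel_size must be odd")
  if (sigma <= 0) stop("sigma must be positive")
  if (max_weight < 1) stop("max_weight must be >= 1")
  structure(list(kernel_size = kernel_size, sigma = sigma,
                 max_weight = max_weight), class = "weight_config")
}

#' Isotropic Gaussian kernel
#'
#' Evaluates \eqn{G(x, y) = \frac{1}{2\pi\sigma^2} e^{-(x^2+y^2)/(2\sigma^2)}}
#' at integer offsets from the kernel center.
#'
#' @param config A [weight_config()].
#' @return A `kernel_size x kernel_size` numeric matrix.
#' @export
gaussian_kernel <- function(config = weight_config()) {
  k <- config$kernel_size
  if (k %% 2 == 0) stop("kernel_size must be odd")
  r <- (k - 1) / 2
  off <- seq(-r, r)
  g <- exp(-outer(off^2, off^2, `+`) / (2 * config$sigma^2)) /
    (2 * pi * config$sigma^2)
  g
}

#' Extract 1-px instance contours from a label mask
#'
#' A contour pixel is a labelled pixel 4-adjacent to a pixel of a different
#' label (background included). Image borders count as background.
#'
#' @param label_mask Integer label matrix (0 = background).
#' @return Logical matrix marking contour pixels.
#' @export
instance_contours <- function(label_mask) {
  m <- label_mask
  H <- nrow(m); W <- ncol(m)
  pad <- -1L
  up <- rbind(m[-1, , drop = FALSE], pad)
  dn <- rbind(pad, m[-H, , drop = FALSE])
  lf <- cbind(m[, -1, drop = FALSE], pad)
  rt <- cbind(pad, m[, -W, drop = FALSE])
  (m > 0) & (up != m | dn != m | lf != m | rt != m)
}

#' Border weight map from a full-image label mask
#'
#' Convolves the contour indicator with the Gaussian kernel (zero padding),
#' normalizes by the kernel peak `G(0, 0)` and maps the field to
#' `min(1 + (max_weight - 1) * normalized, max_weight)`. Weights therefore
#' lie in `[1, max_weight]`, equal exactly `max_weight` on contour pixels
#' (an isolated contour pixel receives the kernel's own peak), equal 1
#' beyond kernel reach, and are monotone in the contour set: adding contour
#' pixels never decreases any weight.
#'
#' @param label_mask Integer label matrix (0 = background).
#' @param config A [weight_config()].
#' @return A numeric matrix of per-pixel loss multipliers (class
#'   `weight_map`).
#' @export
contour_weight_map <- function(label_mask, config = weight_config()) {
  contours <- instance_contours(label_mask)
  wm <- matrix(1, nrow(label_mask), ncol(label_mask))
  if (any(contours)) {
    g <- gaussian_kernel(config)
    blurred <- conv2_zero(contours * 1, g) / g[(config$kernel_size + 1) / 2,
                                               (config$kernel_size + 1) / 2]
    wm <- pmin(1 + (config$max_weight - 1) * blurred, config$max_weight)
  }
  structure(wm, class = c("weight_map", "matrix", "array"))
}

# dense 2-D convolution with zero padding (kernel centered)
conv2_zero <- function(x, k) {
  kh <- nrow(k); kw <- ncol(k)
  ry <- (kh - 1) / 2; rx <- (kw - 1) / 2
  H <- nrow(x); W <- ncol(x)
  xp <- matrix(0, H + 2 * ry, W + 2 * rx)
  xp[(ry + 1):(ry + H), (rx + 1):(rx + W)] <- x
  out <- matrix(0, H, W)
  nz <- which(k != 0, arr.ind = TRUE)
  for (t in seq_len(nrow(nz))) {
    i <- nz[t, 1]; j <- nz[t, 2]
    out <- out + k[i, j] * xp[i:(i + H - 1), j:(j + W - 1)]
  }
  out
}

#' Crop and resize a weight map (or any raster) to a 28x28 proposal crop
#'
#' Bilinearly samples the boxed region at a regular grid (RoI-Align sampling
#' convention: one sample at each output-cell center, pixel centers at
#' half-integer continuous coordinates, edge-clamped).
#'
#' @param weight_map Numeric matrix.
#' @param box Numeric `(x0, y0, x1, y1)`, 0-based half-open, within the image.
#' @param out_size Output side length (default 28).
#' @return `out_size x out_size` numeric matrix.
#' @export
crop_weights <- function(weight_map, box, out_size = 28) {
  if (box[3] <= box[1] || box[4] <= box[2]) stop("degenerate box")
  if (box[1] < 0 || box[2] < 0 || box[3] > ncol(weight_map) ||
      box[4] > nrow(weight_map)) stop("box outside image")
  crop_resize_bilinear(weight_map, box, out_size, out_size)
}

# Bilinear crop-resize used for weight crops and mask targets.
# Output cell (i, j) samples the continuous point
#   y = y0 + (i - 0.5) * bh / out_h,  x = x0 + (j - 0.5) * bw / out_w
# where pixel (r, c) (1-based) has center (x, y) = (c - 0.5, r - 0.5).
crop_resize_bilinear <- function(map, box, out_h, out_w) {
  H <- nrow(map); W <- ncol(map)
  bw <- box[3] - box[1]; bh <- box[4] - box[2]
  sy <- box[2] + (seq_len(out_h) - 0.5) * bh / out_h
  sx <- box[1] + (seq_len(out_w) - 0.5) * bw / out_w
  # continuous -> fractional pixel-center index, edge clamped
  fy <- pmin(pmax(sy - 0.5, 0), H - 1)
  fx <- pmin(pmax(sx - 0.5, 0), W - 1)
  y0 <- floor(fy); x0 <- floor(fx)
  y1 <- pmin(y0 + 1, H - 1); x1 <- pmin(x0 + 1, W - 1)
  wy <- fy - y0; wx <- fx - x0
  m00 <- map[cbind(rep(y0 + 1, out_w), rep(x0 + 1, each = out_h))]
  m01 <- map[cbind(rep(y0 + 1, out_w), rep(x1 + 1, each = out_h))]
  m10 <- map[cbind(rep(y1 + 1, out_w), rep(x0 + 1, each = out_h))]
  m11 <- map[cbind(rep(y1 + 1, out_w), rep(x1 + 1, each = out_h))]
  wyv <- rep(wy, out_w); wxv <- rep(wx, each = out_h)
  v <- m00 * (1 - wyv) * (1 - wxv) + m01 * (1 - wyv) * wxv +
    m10 * wyv * (1 - wxv) + m11 * wyv * wxv
  matrix(v, out_h, out_w)
}
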
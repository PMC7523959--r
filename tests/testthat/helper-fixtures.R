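# Shared fixtures: tiny label arrays and micro scene configurations.

mask_from <- function(rows, cols, H = 12, W = 12) {
  m <- matrix(FALSE, H, W)
  m[rows, cols] <- TRUE
  m
}

micro_scene_config <- function(seed = 1, ...) {
  args <- list(image_height = 128, image_width = 128, n_cells = 5,
               cluster_fraction = 0.4, multinucleate_rate = 0.1,
               nucleus_radius_range = c(4, 6),
               cell_radius_range = c(10, 16), seed = seed)
  override <- list(...)
  args[names(override)] <- override
  do.call(scene_config, args)
}

# brute-force 101-point interpolated AP: explicit prefix counting and grid
# scan, no shared code with the implementation
ap_bruteforce <- function(scores, is_tp, n_gt) {
  if (n_gt == 0) return(NA_real_)
  if (length(scores) == 0) return(0)
  ord <- order(scores, decreasing = TRUE)
  is_tp <- is_tp[ord]
  n <- length(is_tp)
  prec <- numeric(n); rec <- numeric(n)
  for (k in seq_len(n)) {
    tp <- sum(is_tp[seq_len(k)])
    prec[k] <- tp / k
    rec[k] <- tp / n_gt
  }
  total <- 0
  for (r in seq(0, 1, by = 0.01)) {
    best <- 0
    for (k in seq_len(n)) {
      if (rec[k] >= r && prec[k] > best) best <- prec[k]
    }
    total <- total + best
  }
  total / 101
}

random_match_case <- function() {
  n_gt <- sample(0:20, 1)
  n_det <- sample(0:40, 1)
  list(scores = stats::runif(n_det),
       is_tp = if (n_det == 0) logical(0) else {
         # at most n_gt detections can be true positives
         tp <- rep(FALSE, n_det)
         if (n_gt > 0 && n_det > 0) {
           k <- sample(0:min(n_gt, n_det), 1)
           if (k > 0) tp[sample(n_det, k)] <- TRUE
         }
         tp
       },
       n_gt = n_gt)
}

# wrap a scored TP/FP sequence as a match_result for interpolated_ap()
as_match_result <- function(case) {
  structure(list(
    detections = tibble::tibble(score = case$scores, tp = case$is_tp,
                                iou = as.numeric(case$is_tp),
                                matched_gt = NA_integer_),
    fn = case$n_gt - sum(case$is_tp), n_gt = case$n_gt, t = 0.5,
    mode = "mask"), class = "match_result")
}

# independent closed-form parameter tally for a bottleneck ResNet;
# shares no code with count_parameters()
tally_backbone_params <- function(in_ch, conv1, widths, blocks) {
  stage <- function(cin, w, nblk) {
    tot <- 0
    for (b in seq_len(nblk)) {
      ic <- if (b == 1) cin else 4 * w
      tot <- tot + ic * w + 9 * w * w + w * 4 * w +  # three convs, no bias
        2 * (w + w + 4 * w)                           # their BN scale/shift
      if (b == 1) tot <- tot + ic * 4 * w + 2 * 4 * w # projection + BN
    }
    tot
  }
  tot <- 7 * 7 * in_ch * conv1 + 2 * conv1
  prev <- conv1
  for (s in 1:4) {
    tot <- tot + stage(prev, widths[s], blocks[s])
    prev <- 4 * widths[s]
  }
  tot
}

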
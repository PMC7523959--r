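#' Intersection over union of two binary masks
#'
#' \deqn{IoU(A, B) = |A \cap B| / |A \cup B|}
#' Defined as 0 when both masks are empty.
#'
#' @param a,b Logical matrices of identical dimension.
#' @return A value in \[0, 1\].
#' @export
mask_iou <- function(a, b) {
  if (!identical(dim(a), dim(b))) stop("mask shapes differ")
  inter <- sum(a & b)
  uni <- sum(a | b)
  if (uni == 0) return(0)
  inter / uni
}

#' Intersection over union of two boxes
#'
#' Boxes are 0-based half-open `(x0, y0, x1, y1)`.
#'
#' @param a,b Numeric length-4 vectors.
#' @return A value in \[0, 1\].
#' @export
box_iou <- function(a, b) {
  iw <- max(0, min(a[3], b[3]) - max(a[1], b[1]))
  ih <- max(0, min(a[4], b[4]) - max(a[2], b[2]))
  inter <- iw * ih
  uni <- (a[3] - a[1]) * (a[4] - a[2]) + (b[3] - b[1]) * (b[4] - b[2]) - inter
  if (uni <= 0) return(0)
  inter / uni
}

pairwise_iou <- function(dets, gts, mode = c("mask", "box")) {
  mode <- match.arg(mode)
  nd <- n_instances(dets); ng <- n_instances(gts)
  ious <- matrix(0, nd, ng)
  if (nd == 0 || ng == 0) return(ious)
  if (mode == "mask") {
    areas_d <- vapply(dets$masks, sum, numeric(1))
    areas_g <- vapply(gts$masks, sum, numeric(1))
    for (i in seq_len(nd)) {
      for (j in seq_len(ng)) {
        inter <- sum(dets$masks[[i]] & gts$masks[[j]])
        uni <- areas_d[i] + areas_g[j] - inter
        ious[i, j] <- if (uni > 0) inter / uni else 0
      }
    }
  } else {
    for (i in seq_len(nd)) {
      for (j in seq_len(ng)) {
        ious[i, j] <- box_iou(
          as.numeric(dets$meta[i, c("x0", "y0", "x1", "y1")]),
          as.numeric(gts$meta[j, c("x0", "y0", "x1", "y1")]))
      }
    }
  }
  ious
}

#' Match detections to ground truth at an IoU threshold
#'
#' Detections are truncated to the 100 top-scoring per image, then processed
#' in descending score order; each is greedily matched to the not yet matched
#' ground-truth instance of highest IoU, provided that IoU reaches the
#' threshold `t`; otherwise it is a false positive. Ground-truth instances
#' left unmatched are false negatives.
#'
#' @param dets Predicted `instance_set` with scores.
#' @param gts Ground-truth `instance_set`.
#' @param t IoU threshold in (0, 1).
#' @param mode `"mask"` (pixel IoU) or `"box"` (bounding-box IoU).
#' @param top_k Per-image detection budget (default 100).
#' @return A `match_result`: list with `detections` (tibble of `score`, `tp`,
#'   `iou`, `matched_gt`), `fn` (count), `n_gt`, `t`, `mode`.
#' @export
match_detections <- function(dets, gts, t, mode = c("mask", "box"),
                             top_k = 100) {
  mode <- match.arg(mode)
  ord <- order(dets$meta$score, decreasing = TRUE)
  ord <- ord[seq_len(min(length(ord), top_k))]
  dets <- dets[ord]
  nd <- n_instances(dets); ng <- n_instances(gts)
  ious <- pairwise_iou(dets, gts, mode)
  matched <- rep(FALSE, ng)
  tp <- rep(FALSE, nd)
  best_iou <- rep(0, nd)
  matched_gt <- rep(NA_integer_, nd)
  for (i in seq_len(nd)) {
    if (ng == 0) break
    cand <- ious[i, ]
    cand[matched] <- -1
    j <- which.max(cand)
    if (length(j) == 1 && cand[j] >= t) {
      matched[j] <- TRUE
      tp[i] <- TRUE
      matched_gt[i] <- gts$meta$label[j]
      best_iou[i] <- ious[i, j]
    }
  }
  structure(list(
    detections = tibble::tibble(score = dets$meta$score, tp = tp,
                                iou = best_iou, matched_gt = matched_gt),
    fn = sum(!matched), n_gt = ng, t = t, mode = mode
  ), class = "match_result")
}

#' 101-point interpolated average precision
#'
#' Pools the scored TP/FP decisions of all test images, builds the
#' precision/recall curve in descending score order, and averages the
#' interpolated precision \eqn{p_{interp}(r) = \max_{\tilde r \ge r} p(\tilde r)}
#' over the recall grid \eqn{r \in \{0, 0.01, \ldots, 1\}}.
#'
#' @param matches A `match_result` or a list of them (one per image, same
#'   threshold).
#' @param n_gt_total Total ground-truth count; defaults to the sum over
#'   `matches`.
#' @return AP in \[0, 1\], or `NA` when there is no ground truth (an
#'   undefined AP).
#' @export
interpolated_ap <- function(matches, n_gt_total = NULL) {
  if (inherits(matches, "match_result")) matches <- list(matches)
  det <- dplyr::bind_rows(lapply(matches, `[[`, "detections"))
  if (is.null(n_gt_total)) n_gt_total <- sum(vapply(matches, `[[`, 0, "n_gt"))
  if (n_gt_total == 0) return(NA_real_)
  if (nrow(det) == 0) return(0)
  det <- det[order(det$score, decreasing = TRUE), ]
  tp_cum <- cumsum(det$tp)
  fp_cum <- cumsum(!det$tp)
  precision <- tp_cum / (tp_cum + fp_cum)
  recall <- tp_cum / n_gt_total
  grid <- seq(0, 1, by = 0.01)
  # p_interp(r): max precision among measured points with recall >= r
  p_interp <- vapply(grid, function(r) {
    ok <- recall >= r
    if (!any(ok)) 0 else max(precision[ok])
  }, numeric(1))
  mean(p_interp)
}

#' Mean average precision over the 9 IoU thresholds
#'
#' The protocol averages AP over IoU thresholds 0.50 to 0.90 in steps of
#' 0.05 (nine thresholds).
#'
#' @param ap_by_threshold Named numeric vector or tibble with columns
#'   `threshold` and `ap` covering all nine thresholds.
#' @param na_action `"error"` (default) or `"omit"` for undefined entries.
#' @return The arithmetic mean of the nine AP values.
#' @export
mean_ap <- function(ap_by_threshold, na_action = c("error", "omit")) {
  na_action <- match.arg(na_action)
  ths <- ap_thresholds()
  if (is.data.frame(ap_by_threshold)) {
    aps <- ap_by_threshold$ap[match(ths, ap_by_threshold$threshold)]
  } else if (!is.null(names(ap_by_threshold))) {
    aps <- ap_by_threshold[match(format(ths), names(ap_by_threshold))]
    if (anyNA(match(format(ths), names(ap_by_threshold)))) {
      aps <- ap_by_threshold[match(as.character(ths), names(ap_by_threshold))]
    }
  } else {
    aps <- ap_by_threshold
  }
  if (length(aps) != 9) stop("expected AP values at all 9 IoU thresholds")
  if (anyNA(aps)) {
    if (na_action == "error") stop("AP missing/undefined at some threshold")
    aps <- aps[!is.na(aps)]
  }
  mean(as.numeric(aps))
}

ap_thresholds <- function() seq(0.5, 0.9, by = 0.05)

#' Relative improvement between two mean APs
#'
#' @param new_mean_ap,baseline_mean_ap Mean AP values; baseline must be
#'   positive.
#' @return Percent improvement `100 * (new - baseline) / baseline`.
#' @export
relative_improvement <- function(new_mean_ap, baseline_mean_ap) {
  if (baseline_mean_ap <= 0) stop("baseline mean AP must be positive")
  100 * (new_mean_ap - baseline_mean_ap) / baseline_mean_ap
}

#' Evaluate predicted instances against ground truth
#'
#' Runs the full metric protocol: greedy top-100 matching per image at each
#' IoU threshold 0.50–0.90 (step 0.05), pooled 101-point interpolated AP per
#' threshold, the mean AP, and TP/FP/FN with precision/recall at a reporting
#' threshold.
#'
#' @param preds List of predicted `instance_set`s (one per image), or one set.
#' @param gts List of ground-truth `instance_set`s matching `preds`.
#' @param mode `"mask"` or `"box"`.
#' @param report_t IoU threshold for the TP/FP/FN table (default 0.75).
#' @param top_k Per-image detection budget.
#' @return An `eval_report`: tibble `ap_by_threshold`, scalar `mean_ap`,
#'   counts `tp`, `fp`, `fn`, `precision`, `recall` at `report_t`.
#' @export
evaluate_detections <- function(preds, gts, mode = c("mask", "box"),
                                report_t = 0.75, top_k = 100) {
  mode <- match.arg(mode)
  if (inherits(preds, "instance_set")) preds <- list(preds)
  if (inherits(gts, "instance_set")) gts <- list(gts)
  stopifnot(length(preds) == length(gts))
  ths <- ap_thresholds()
  ap <- vapply(ths, function(t) {
    ms <- purrr::map2(preds, gts, match_detections, t = t, mode = mode,
                      top_k = top_k)
    interpolated_ap(ms)
  }, numeric(1))
  ms_rep <- purrr::map2(preds, gts, match_detections, t = report_t,
                        mode = mode, top_k = top_k)
  tp <- sum(vapply(ms_rep, function(m) sum(m$detections$tp), numeric(1)))
  fp <- sum(vapply(ms_rep, function(m) sum(!m$detections$tp), numeric(1)))
  fn <- sum(vapply(ms_rep, `[[`, 0, "fn"))
  structure(list(
    ap_by_threshold = tibble::tibble(threshold = ths, ap = ap),
    mean_ap = if (anyNA(ap)) NA_real_ else mean(ap),
    tp = tp, fp = fp, fn = fn,
    precision = if (tp + fp > 0) tp / (tp + fp) else NA_real_,
    recall = if (tp + fn > 0) tp / (tp + fn) else NA_real_,
    report_t = report_t, mode = mode, n_images = length(preds)
  ), class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf("<eval_report: %s IoU, %d image(s)>\n", x$mode, x$n_images))
  cat(sprintf("  mean AP = %.3f\n", x$mean_ap))
  cat(sprintf("  at t=%.2f: TP=%d FP=%d FN=%d  precision=%.3f recall=%.3f\n",
              x$report_t, x$tp, x$fp, x$fn, x$precision, x$recall))
  invisible(x)
}

#' @rdname evaluate_detections
#' @param x An `eval_report`.
#' @param ... Unused.
#' @exportS3Method generics::tidy
tidy.eval_report <- function(x, ...) x$ap_by_threshold

#' @rdname evaluate_detections
#' @exportS3Method generics::glance
glance.eval_report <- function(x, ...) {
  tibble::tibble(mean_ap = x$mean_ap, tp = x$tp, fp = x$fp, fn = x$fn,
                 precision = x$precision, recall = x$recall,
                 report_t = x$report_t, mode = x$mode,
                 n_images = x$n_images)
}

#' @rdname evaluate_detections
#' @param object An `eval_report`.
#' @exportS3Method ggplot2::autoplot
autoplot.eval_report <- function(object, ...) {
  ggplot2::ggplot(object$ap_by_threshold,
                  ggplot2::aes(x = .data$threshold, y = .data$ap)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::ylim(0, 1) +
    ggplot2::labs(x = "IoU threshold", y = "interpolated AP",
                  title = sprintf("mean AP = %.3f (%s IoU)",
                                  object$mean_ap, object$mode))
}
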
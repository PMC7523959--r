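#' Published benchmark summary tables for the macrophage two-channel dataset
#'
#' Per-IoU-threshold average precisions and TP/FP/FN counts reported for the
#' public macrophage benchmark (82 two-channel fluorescence images, 64 train /
#' 18 test, 508 test cells) in the dataset's original publication. These are
#' reference *inputs* for the metric arithmetic in this package — e.g. the
#' nine per-threshold APs of a method feed [mean_ap()], and pairs of mean APs
#' feed [relative_improvement()] — not values this package claims to
#' recompute from images.
#'
#' @return A named list of tibbles:
#' \describe{
#'   \item{cells_detection}{AP per IoU threshold (0.50–0.90) per method on
#'     the full cell test set, plus the reported mean AP (`mean_ap_printed`).}
#'   \item{cells_segmentation}{Same layout for segmentation masks.}
#'   \item{clustered_detection, clustered_segmentation}{Same layout on the
#'     clustered-cells subset (78 patches of 256x256, 255 cells).}
#'   \item{cells_seg_counts}{TP/FP/FN at IoU 0.75 on the full cell test set,
#'     with the reported mean AP at that threshold family.}
#'   \item{improvements}{Reported relative mean-AP improvements (percent) of
#'     the best fusion variant over the stated baselines.}
#' }
#' @export
benchmark_reference_tables <- function() {
  th <- ap_thresholds()
  ap_tbl <- function(method, aps, mean_printed) {
    tibble::tibble(method = method,
                   threshold = list(th), ap = list(aps),
                   mean_ap_printed = mean_printed)
  }
  cells_det <- dplyr::bind_rows(
    ap_tbl("no nucleus",
           c(0.886, 0.870, 0.845, 0.790, 0.743, 0.675, 0.548, 0.426, 0.230),
           0.668),
    ap_tbl("nucleus input",
           c(0.921, 0.910, 0.886, 0.865, 0.821, 0.727, 0.619, 0.448, 0.221),
           0.713),
    ap_tbl("fpf concat",
           c(0.944, 0.932, 0.912, 0.884, 0.848, 0.771, 0.613, 0.480, 0.237),
           0.736),
    ap_tbl("fpf add",
           c(0.935, 0.925, 0.901, 0.886, 0.842, 0.758, 0.633, 0.479, 0.220),
           0.731),
    ap_tbl("fpf concat weighted",
           c(0.944, 0.932, 0.897, 0.883, 0.842, 0.767, 0.633, 0.453, 0.228),
           0.731),
    ap_tbl("fpf add weighted",
           c(0.942, 0.932, 0.916, 0.891, 0.841, 0.766, 0.648, 0.484, 0.224),
           0.738)
  )
  cells_seg <- dplyr::bind_rows(
    ap_tbl("no nucleus",
           c(0.898, 0.870, 0.858, 0.838, 0.811, 0.751, 0.657, 0.499, 0.226),
           0.712),
    ap_tbl("nucleus input",
           c(0.931, 0.909, 0.908, 0.881, 0.866, 0.807, 0.733, 0.585, 0.236),
           0.762),
    ap_tbl("fpf concat",
           c(0.943, 0.943, 0.920, 0.905, 0.885, 0.830, 0.746, 0.600, 0.284),
           0.784),
    ap_tbl("fpf add",
           c(0.935, 0.935, 0.909, 0.908, 0.896, 0.840, 0.762, 0.592, 0.246),
           0.780),
    ap_tbl("fpf concat weighted",
           c(0.946, 0.934, 0.921, 0.890, 0.876, 0.835, 0.753, 0.605, 0.253),
           0.779),
    ap_tbl("fpf add weighted",
           c(0.941, 0.930, 0.930, 0.911, 0.890, 0.849, 0.764, 0.603, 0.247),
           0.785)
  )
  clustered_det <- dplyr::bind_rows(
    ap_tbl("no nucleus",
           c(0.772, 0.726, 0.667, 0.623, 0.566, 0.482, 0.334, 0.218, 0.057),
           0.494),
    ap_tbl("nucleus input",
           c(0.852, 0.839, 0.792, 0.747, 0.688, 0.581, 0.447, 0.261, 0.066),
           0.586),
    ap_tbl("fpf concat",
           c(0.856, 0.825, 0.825, 0.756, 0.699, 0.640, 0.438, 0.256, 0.073),
           0.596),
    ap_tbl("fpf add",
           c(0.851, 0.837, 0.815, 0.763, 0.706, 0.591, 0.473, 0.280, 0.063),
           0.598),
    ap_tbl("fpf concat weighted",
           c(0.856, 0.847, 0.827, 0.785, 0.747, 0.618, 0.475, 0.271, 0.078),
           0.612),
    ap_tbl("fpf add weighted",
           c(0.861, 0.849, 0.825, 0.775, 0.694, 0.625, 0.481, 0.267, 0.059),
           0.604)
  )
  clustered_seg <- dplyr::bind_rows(
    ap_tbl("no nucleus",
           c(0.779, 0.720, 0.684, 0.673, 0.631, 0.558, 0.459, 0.319, 0.104),
           0.548),
    ap_tbl("nucleus input",
           c(0.839, 0.826, 0.815, 0.777, 0.754, 0.676, 0.589, 0.416, 0.142),
           0.648),
    ap_tbl("fpf concat",
           c(0.856, 0.846, 0.824, 0.805, 0.778, 0.703, 0.615, 0.434, 0.150),
           0.668),
    ap_tbl("fpf add",
           c(0.860, 0.839, 0.814, 0.796, 0.785, 0.712, 0.636, 0.419, 0.136),
           0.666),
    ap_tbl("fpf concat weighted",
           c(0.859, 0.849, 0.829, 0.819, 0.788, 0.718, 0.625, 0.420, 0.160),
           0.674),
    ap_tbl("fpf add weighted",
           c(0.860, 0.848, 0.835, 0.807, 0.785, 0.726, 0.619, 0.427, 0.161),
           0.675)
  )
  counts <- tibble::tibble(
    method = c("stardist", "no nucleus", "nucleus input", "fpf concat",
               "fpf add", "fpf concat weighted", "fpf add weighted"),
    tp = c(379, 409, 427, 441, 443, 445, 450),
    fp = c(91, 93, 79, 82, 65, 69, 66),
    fn = c(129, 99, 81, 67, 65, 63, 58),
    mean_ap_printed = c(0.632, 0.751, 0.807, 0.830, 0.840, 0.835, 0.849)
  )
  improvements <- tibble::tibble(
    comparison = c(
      "detection full: fpf add weighted vs no nucleus",
      "detection full: fpf add weighted vs nucleus input",
      "segmentation full: fpf add weighted vs no nucleus",
      "segmentation full: fpf add weighted vs nucleus input",
      "detection clustered: best fpf vs no nucleus",
      "detection clustered: best fpf vs nucleus input",
      "segmentation clustered: best fpf vs no nucleus",
      "segmentation clustered: best fpf vs nucleus input",
      "detection clustered postprocessed vs no nucleus",
      "detection clustered postprocessed vs nucleus input",
      "segmentation clustered postprocessed vs no nucleus",
      "segmentation clustered postprocessed vs nucleus input"),
    new = c(0.738, 0.738, 0.785, 0.785, 0.612, 0.612, 0.675, 0.675,
            0.650, 0.650, 0.682, 0.682),
    baseline = c(0.668, 0.713, 0.712, 0.762, 0.494, 0.586, 0.548, 0.648,
                 0.494, 0.586, 0.548, 0.648),
    percent_printed = c(10.48, 3.5, 10.25, 3.02, 23.88, 4.43, 23.17, 4.16,
                        31.58, 10.92, 24.45, 5.25)
  )
  list(cells_detection = cells_det,
       cells_segmentation = cells_seg,
       clustered_detection = clustered_det,
       clustered_segmentation = clustered_seg,
       cells_seg_counts = counts,
       improvements = improvements)
}
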
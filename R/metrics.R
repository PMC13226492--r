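# ---------------------------------------------------------------------------
# Evaluation metrics: overlap/confusion metrics plus boundary-distance
# metrics (HD95, ASSD, Boundary IoU).  Distance transforms are computed with
# EBImage's exact Euclidean distance map.
# ---------------------------------------------------------------------------

as_binary_mask <- function(m) {
  v <- as.numeric(m) > 0.5
  dim(v) <- dim(m)[1:2]
  v
}

#' Confusion-count metrics for a binary segmentation
#'
#' @param pred_mask,gt_mask binary masks (matrices or arrays of the same
#'   spatial shape; values are thresholded at 0.5).
#' @param miou_convention `"two_class_mean"` (mean of background and
#'   foreground IoU) or `"foreground"` (foreground IoU only).
#' @return list with `iou_per_class`, `miou`, `dice`, `precision`, `recall`,
#'   `f1` (all as fractions in `[0,1]`).  When ground truth and prediction
#'   are both empty, all ratio metrics are defined as 1 (perfect-empty
#'   convention).
#' @export
confusion_metrics <- function(pred_mask, gt_mask,
                              miou_convention = c("two_class_mean",
                                                  "foreground")) {
  miou_convention <- match.arg(miou_convention)
  p <- as_binary_mask(pred_mask); g <- as_binary_mask(gt_mask)
  if (!identical(dim(p), dim(g))) stop("mask shapes differ")
  tp <- sum(p & g); fp <- sum(p & !g); fn <- sum(!p & g); tn <- sum(!p & !g)
  safe <- function(num, den) if (den == 0) 1 else num / den
  iou_fg <- safe(tp, tp + fp + fn)
  iou_bg <- safe(tn, tn + fp + fn)
  res <- list(
    iou_per_class = c(background = iou_bg, foreground = iou_fg),
    miou = if (miou_convention == "two_class_mean") (iou_fg + iou_bg) / 2
           else iou_fg,
    dice = safe(2 * tp, 2 * tp + fp + fn),
    precision = safe(tp, tp + fp),
    recall = safe(tp, tp + fn),
    counts = c(tp = tp, fp = fp, fn = fn, tn = tn))
  res$f1 <- res$dice
  res
}

# Boundary pixels: foreground pixels with at least one background 4-neighbor
# (image-border foreground pixels count as boundary).
boundary_pixels <- function(mask) {
  m <- as_binary_mask(mask)
  H <- nrow(m); W <- ncol(m)
  up <- rbind(FALSE, m[-H, , drop = FALSE])
  down <- rbind(m[-1, , drop = FALSE], FALSE)
  left <- cbind(FALSE, m[, -W, drop = FALSE])
  right <- cbind(m[, -1, drop = FALSE], FALSE)
  m & !(up & down & left & right)
}

# Exact Euclidean distance from every pixel to the nearest TRUE pixel of
# `target` (0 where target itself is TRUE).
distance_to_set <- function(target) {
  img <- EBImage::Image(1 - target * 1)
  EBImage::imageData(EBImage::distmap(img, metric = "euclidean"))
}

#' Directed boundary-to-boundary surface distances
#'
#' Boundaries are extracted under 4-connectivity; for every boundary pixel
#' of one mask the Euclidean distance to the nearest boundary pixel of the
#' other mask is measured, in both directions.
#'
#' @param pred_mask,gt_mask non-empty binary masks of identical shape.
#' @return list with numeric vectors `pred_to_gt` and `gt_to_pred`; when
#'   either mask is empty both vectors are empty and the attribute
#'   `"undefined"` is set (the sentinel convention for empty masks).
#' @export
surface_distances <- function(pred_mask, gt_mask) {
  p <- as_binary_mask(pred_mask); g <- as_binary_mask(gt_mask)
  if (!identical(dim(p), dim(g))) stop("mask shapes differ")
  if (!any(p) || !any(g)) {
    return(structure(list(pred_to_gt = numeric(0), gt_to_pred = numeric(0)),
                     undefined = TRUE))
  }
  bp <- boundary_pixels(p); bg <- boundary_pixels(g)
  d_to_g <- distance_to_set(bg)
  d_to_p <- distance_to_set(bp)
  list(pred_to_gt = as.numeric(d_to_g[bp]),
       gt_to_pred = as.numeric(d_to_p[bg]))
}

#' 95th-percentile symmetric Hausdorff distance
#'
#' The 95th percentile of the pooled directed surface distances, under the
#' Hazen linear-interpolation definition (quantile type 5: `h = 0.95 n +
#' 1/2`), so e.g. nineteen zeros pooled with a single 10 give 5.0.
#'
#' @param distances result of [surface_distances()].
#' @return distance in pixels.
#' @export
hd95 <- function(distances) {
  if (is.null(distances) || !length(c(distances$pred_to_gt,
                                      distances$gt_to_pred)))
    stop("hd95: empty distance set")

  pooled <- c(distances$pred_to_gt, distances$gt_to_pred)
  as.numeric(stats::quantile(pooled, 0.95, type = 5, names = FALSE))
}

#' Average symmetric surface distance
#'
#' Count-weighted mean of all directed surface distances in both directions.
#'
#' @param distances result of [surface_distances()].
#' @return distance in pixels.
#' @export
assd <- function(distances) {
  if (is.null(distances) || !length(c(distances$pred_to_gt,
                                      distances$gt_to_pred)))
    stop("assd: empty distance set")
  mean(c(distances$pred_to_gt, distances$gt_to_pred))
}

#' Boundary IoU
#'
#' Each mask is restricted to a thin band within `band_px` of its own
#' exterior (mask minus an erosion by `band_px`, realized through the exact
#' Euclidean distance transform); the IoU of the two bands is returned.
#' The default band width is 2% of the image diagonal, rounded up.
#'
#' @param pred_mask,gt_mask binary masks of identical shape.
#' @param band_px band width in pixels (>= 1).
#' @return ratio in `[0,1]`; 1 when both bands are empty.
#' @export
boundary_iou <- function(pred_mask, gt_mask, band_px = NULL) {
  p <- as_binary_mask(pred_mask); g <- as_binary_mask(gt_mask)
  if (!identical(dim(p), dim(g))) stop("mask shapes differ")
  if (is.null(band_px))
    band_px <- ceiling(0.02 * sqrt(nrow(p)^2 + ncol(p)^2))
  if (band_px < 1) stop("band_px must be >= 1")
  band <- function(m) {
    if (!any(m)) return(m)
    d <- EBImage::imageData(EBImage::distmap(EBImage::Image(m * 1),
                                             metric = "euclidean"))
    m & (d <= band_px)
  }
  bp <- band(p); bg <- band(g)
  uni <- sum(bp | bg)
  if (uni == 0) return(1)
  sum(bp & bg) / uni
}

#' Evaluate a set of predictions against ground truths
#'
#' Confusion metrics are aggregated over pooled pixel counts; HD95, ASSD and
#' Boundary IoU are averaged per image over images where they are defined
#' (images with an empty prediction or ground truth are excluded from the
#' distance averages and counted in `hd_undefined`).
#'
#' @param predictions list of binary masks (or probability maps thresholded
#'   at 0.5).
#' @param ground_truths list of binary masks, same length and shapes.
#' @param miou_convention passed to [confusion_metrics()].
#' @param band_px passed to [boundary_iou()].
#' @return object of class `metric_report`: percentages for mIoU, Dice,
#'   precision, recall, F1; pixels for HD95 and ASSD; ratio for Boundary IoU.
#' @export
evaluate_dataset <- function(predictions, ground_truths,
                             miou_convention = "two_class_mean",
                             band_px = NULL) {
  if (length(predictions) != length(ground_truths))
    stop("prediction and ground-truth lists differ in length")
  counts <- c(tp = 0, fp = 0, fn = 0, tn = 0)
  hd <- c(); as_ <- c(); bi <- c(); undef <- 0L
  for (i in seq_along(predictions)) {
    cm <- confusion_metrics(predictions[[i]], ground_truths[[i]],
                            miou_convention)
    counts <- counts + cm$counts
    sd <- surface_distances(predictions[[i]], ground_truths[[i]])
    if (isTRUE(attr(sd, "undefined"))) undef <- undef + 1L
    else { hd <- c(hd, hd95(sd)); as_ <- c(as_, assd(sd)) }
    bi <- c(bi, boundary_iou(predictions[[i]], ground_truths[[i]], band_px))
  }
  tp <- counts["tp"]; fp <- counts["fp"]; fn <- counts["fn"]
  tn <- counts["tn"]
  safe <- function(num, den) if (den == 0) 1 else num / den
  iou_fg <- safe(tp, tp + fp + fn); iou_bg <- safe(tn, tn + fp + fn)
  miou <- if (miou_convention == "two_class_mean") (iou_fg + iou_bg) / 2
          else iou_fg
  dice <- safe(2 * tp, 2 * tp + fp + fn)
  rep <- list(miou = 100 * unname(miou), dice = 100 * unname(dice),
              precision = 100 * unname(safe(tp, tp + fp)),
              recall = 100 * unname(safe(tp, tp + fn)),
              f1 = 100 * unname(dice),
              hd95 = if (length(hd)) mean(hd) else NA_real_,
              assd = if (length(as_)) mean(as_) else NA_real_,
              biou = mean(bi),
              hd_undefined = undef,
              n_images = length(predictions))
  class(rep) <- "metric_report"
  rep
}

#' @export
print.metric_report <- function(x, ...) {
  cat(sprintf(
    "mIoU(%%) %.2f | Dice(%%) %.2f | Prec.(%%) %.2f | Rec.(%%) %.2f | F1(%%) %.2f | HD95(px) %s | ASSD %s | BIoU %.3f\n",
    x$miou, x$dice, x$precision, x$recall, x$f1,
    ifelse(is.na(x$hd95), "NA", sprintf("%.2f", x$hd95)),
    ifelse(is.na(x$assd), "NA", sprintf("%.2f", x$assd)), x$biou))
  if (x$hd_undefined > 0)
    cat(sprintf("  (%d image(s) excluded from distance averages)\n",
                x$hd_undefined))
  invisible(x)
}

#' Serialize a metric report to a one-row data frame
#' @param report a `metric_report`.
#' @return data.frame in the standard column order.
#' @export
metric_report_row <- function(report) {
  data.frame(miou = report$miou, dice = report$dice,
             precision = report$precision, recall = report$recall,
             f1 = report$f1, hd95 = report$hd95, assd = report$assd,
             biou = report$biou)
}
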
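#' Region areas of a mask pair
#'
#' Pixel-count areas underlying the region-fraction metrics: `sa` (segmented
#' disc area), `oa` (ground-truth disc area), `ba` (background, total minus
#' `oa`), their `overlap`, and `total`.
#'
#' @param pred,truth Binary masks (numeric or logical matrices of identical
#'   dimension; values `> 0.5` count as disc).
#' @return A one-row tibble with columns `sa`, `oa`, `ba`, `overlap`, `total`.
#' @export
region_areas <- function(pred, truth) {
  if (!identical(dim(pred), dim(truth))) {
    stop("`pred` and `truth` must have identical dimensions")
  }
  p <- pred > 0.5
  t <- truth > 0.5
  tibble::tibble(
    sa = sum(p),
    oa = sum(t),
    ba = length(t) - sum(t),
    overlap = sum(p & t),
    total = length(t)
  )
}

#' Region-fraction confusion values
#'
#' Converts region areas to the fractional confusion values `tp`, `fp`, `tn`,
#' `fn` in `[0, 1]`.  In the default `"fractional"` mode the over- and
#' under-segmented amounts are the **set-difference** areas: with
#' `miss = |OA \ SA|` and `spill = |SA \ OA|`,
#'
#' * `tp = 1 - miss / oa`, `fn = miss / oa` (so `tp + fn = 1`),
#' * `fp = spill / (ba - oa)`, `tn = 1 - fp` (so `tn + fp = 1`).
#'
#' `mode = "strict"` uses the scalar area differences instead (`oa - sa` and
#' `sa - oa`, floored at 0), which scores any equal-area prediction as
#' perfect regardless of position — provided for literal comparability only.
#'
#' @param areas A one-row tibble from [region_areas()].
#' @param mode `"fractional"` (set differences, default) or `"strict"`
#'   (scalar areas).
#' @return A one-row tibble with columns `tp`, `fp`, `tn`, `fn`.
#' @export
fractional_confusion <- function(areas, mode = c("fractional", "strict")) {
  mode <- match.arg(mode)
  if (areas$oa == 0) stop("ground truth contains no disc pixels (OA = 0)")
  if (areas$ba <= areas$oa) {
    stop("background smaller than the disc: fractional FP denominator (BA - OA) <= 0")
  }
  if (mode == "fractional") {
    miss <- areas$oa - areas$overlap
    spill <- areas$sa - areas$overlap
  } else {
    miss <- max(0, areas$oa - areas$sa)
    spill <- max(0, areas$sa - areas$oa)
  }
  fn <- miss / areas$oa
  fp <- spill / (areas$ba - areas$oa)
  tibble::tibble(tp = 1 - fn, fp = fp, tn = 1 - fp, fn = fn)
}

#' Segmentation accuracy
#'
#' `Acc = (TN + TP) / (TN + FN + FP + TP)`.
#'
#' @param tp,fp,tn,fn Confusion values (fractions or counts).
#' @return The accuracy.
#' @export
accuracy <- function(tp, fp, tn, fn) {
  (tn + tp) / (tn + fn + fp + tp)
}

#' Dice similarity
#'
#' `Dice = 2 TP / (2 TP + FP + FN)`; an empty comparison (all three zero) is
#' scored 1 by convention.
#'
#' @param tp,fp,fn Confusion values (fractions or counts).
#' @return The Dice coefficient.
#' @export
dice <- function(tp, fp, fn) {
  den <- 2 * tp + fp + fn
  ifelse(den == 0, 1, 2 * tp / den)
}

#' Overlapping error
#'
#' `E = 1 - TP / (TP + FP + FN)`, the primary per-image error measure; 0 for
#' an empty comparison.
#'
#' @param tp,fp,fn Confusion values (fractions or counts).
#' @return The overlap error.
#' @export
overlap_error <- function(tp, fp, fn) {
  den <- tp + fp + fn
  ifelse(den == 0, 0, 1 - tp / den)
}

#' Evaluate a predicted mask against ground truth
#'
#' One-stop evaluation: computes areas, the confusion values in the requested
#' mode, and accuracy / Dice / overlap error.  `mode = "pixelwise"` uses the
#' standard per-pixel confusion matrix normalized by the image area (so
#' accuracy is plain pixel accuracy, Dice the usual overlap Dice, and the
#' overlap error equals one minus the Jaccard index).
#'
#' @param pred Predicted binary mask.
#' @param truth Ground-truth mask; a soft (multi-rater) grayscale map is
#'   binarized at `truth_threshold` first.
#' @param mode `"fractional"`, `"strict"` or `"pixelwise"`.
#' @param truth_threshold Binarization threshold for soft truth (default
#'   0.75).
#' @return A one-row tibble: `tp`, `fp`, `tn`, `fn`, `accuracy`, `dice`,
#'   `overlap_error`, `mode`.
#' @examples
#' m <- matrix(0, 10, 10); m[3:7, 3:7] <- 1
#' evaluate_masks(m, m)
#' @export
evaluate_masks <- function(pred, truth,
                           mode = c("fractional", "strict", "pixelwise"),
                           truth_threshold = 0.75) {
  mode <- match.arg(mode)
  if (!identical(dim(pred), dim(truth))) {
    stop("`pred` and `truth` must have identical dimensions")
  }
  truth_bin <- truth >= ifelse(max(truth) > 1, truth_threshold * 255, truth_threshold)
  areas <- region_areas(pred, truth_bin)
  if (mode == "pixelwise") {
    tp <- areas$overlap / areas$total
    fp <- (areas$sa - areas$overlap) / areas$total
    fn <- (areas$oa - areas$overlap) / areas$total
    tn <- 1 - tp - fp - fn
    conf <- tibble::tibble(tp = tp, fp = fp, tn = tn, fn = fn)
  } else {
    conf <- fractional_confusion(areas, mode)
  }
  tibble::tibble(
    tp = conf$tp, fp = conf$fp, tn = conf$tn, fn = conf$fn,
    accuracy = accuracy(conf$tp, conf$fp, conf$tn, conf$fn),
    dice = dice(conf$tp, conf$fp, conf$fn),
    overlap_error = overlap_error(conf$tp, conf$fp, conf$fn),
    mode = mode
  )
}

#' Cumulative overlap-error report
#'
#' Summarizes a batch of per-image results the way segmentation studies
#' report them: the proportion of images with overlap error `E <= tau` for a
#' ladder of thresholds, plus mean `E`, accuracy and Dice.
#'
#' @param metrics A tibble with an `overlap_error` column (optionally
#'   `accuracy` and `dice`), or a bare numeric vector of `E` values.
#' @param thresholds Error thresholds `tau` (default `0.1 ... 0.5`).
#' @return A one-row tibble with one proportion column per threshold (named
#'   `e_le_<tau>`, values in `[0, 1]`) and `mean_overlap_error`,
#'   `mean_accuracy`, `mean_dice` (`NA` when the input lacks those columns).
#' @export
cumulative_error_report <- function(metrics, thresholds = seq(0.1, 0.5, by = 0.1)) {
  if (is.numeric(metrics)) {
    metrics <- tibble::tibble(overlap_error = metrics)
  }
  if (nrow(metrics) == 0) stop("no per-image metrics supplied")
  e <- metrics$overlap_error
  props <- vapply(thresholds, function(tau) mean(e <= tau), numeric(1))
  out <- tibble::as_tibble(as.list(stats::setNames(
    props, sprintf("e_le_%g", thresholds)
  )))
  out$mean_overlap_error <- mean(e)
  out$mean_accuracy <- if ("accuracy" %in% names(metrics)) mean(metrics$accuracy) else NA_real_
  out$mean_dice <- if ("dice" %in% names(metrics)) mean(metrics$dice) else NA_real_
  out
}
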
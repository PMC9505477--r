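# Pixel confusion counts, Dice / IoU, and the combined training loss.

#' Pixel confusion counts
#'
#' Binarises a probability map at `threshold` and tallies TP/FP/TN/FN pixels
#' against a binary ground-truth mask.
#'
#' @param pred_prob predicted foreground probabilities, `[H, W]` or
#'   `[1, H, W]`.
#' @param gt_mask binary `[H, W]` mask (0/1).
#' @param threshold binarisation threshold in (0, 1); default 0.5.
#' @return list of class `confusion_counts` with integer `tp`, `fp`, `tn`,
#'   `fn`; they always sum to the pixel count.
#' @export
confusion_counts <- function(pred_prob, gt_mask, threshold = 0.5) {
  d <- dim(pred_prob)
  if (length(d) == 3L && d[1] == 1L) {
    pred_prob <- array(pred_prob, d[2:3])
  }
  if (!identical(dim(pred_prob), dim(gt_mask)))
    stop("prediction and mask shapes differ")
  if (!all(gt_mask %in% c(0, 1))) stop("ground-truth mask must be binary 0/1")
  if (threshold <= 0 || threshold >= 1) stop("threshold must lie in (0, 1)")
  pb <- pred_prob >= threshold
  gb <- gt_mask == 1
  structure(list(tp = sum(pb & gb), fp = sum(pb & !gb),
                 tn = sum(!pb & !gb), fn = sum(!pb & gb)),
            class = "confusion_counts")
}

#' Dice and IoU from confusion counts
#'
#' `dice = 2 TP / (2 TP + FP + FN)` and `iou = TP / (TP + FP + FN)`; the
#' identity `iou = dice / (2 - dice)` holds for every count set. When both
#' masks are empty (`tp = fp = fn = 0`) both metrics are defined as 1.
#'
#' @param c a `confusion_counts` object (or list with `tp`, `fp`, `fn`).
#' @return list with `dice` and `iou`, both in `[0, 1]`.
#' @export
dice_iou <- function(c) {
  pos <- 2 * c$tp + c$fp + c$fn
  if (pos == 0) return(list(dice = 1, iou = 1))
  list(dice = 2 * c$tp / pos, iou = c$tp / (c$tp + c$fp + c$fn))
}

#' Per-image metric report
#'
#' @param pred_probs list of probability maps; @param gt_masks list of
#'   matching binary masks; @param ids optional image identifiers.
#' @param threshold binarisation threshold.
#' @return object of class `metric_report`: a data frame (`image_id`,
#'   `dice`, `iou`) with mean Dice/IoU in attributes `mean_dice`,
#'   `mean_iou`.
#' @export
metric_report <- function(pred_probs, gt_masks, ids = NULL, threshold = 0.5) {
  stopifnot(length(pred_probs) == length(gt_masks))
  if (is.null(ids)) ids <- sprintf("img%03d", seq_along(pred_probs))
  rows <- lapply(seq_along(pred_probs), function(i) {
    m <- dice_iou(confusion_counts(pred_probs[[i]], gt_masks[[i]], threshold))
    data.frame(image_id = ids[i], dice = m$dice, iou = m$iou,
               stringsAsFactors = FALSE)
  })
  rep <- do.call(rbind, rows)
  attr(rep, "mean_dice") <- mean(rep$dice)
  attr(rep, "mean_iou") <- mean(rep$iou)
  class(rep) <- c("metric_report", class(rep))
  rep
}

#' Write a metric report as CSV plus JSON summary
#'
#' @param rep a [metric_report]; @param csv_path,json_path output files.
#' @export
write_metric_report <- function(rep, csv_path, json_path) {
  utils::write.csv(as.data.frame(rep), csv_path, row.names = FALSE)
  jsonlite::write_json(list(mean_dice = attr(rep, "mean_dice"),
                            mean_iou = attr(rep, "mean_iou"),
                            n_images = nrow(rep)),
                       json_path, auto_unbox = TRUE, digits = NA)
}

#' Combined cross-entropy + Dice training loss
#'
#' `w_ce * BCE(sigmoid(logits), gt) + w_dice * (1 - softDice)`, the soft
#' Dice computed on probabilities with smoothing `smooth`. Non-negative and
#' differentiable; this is the exact quantity the training loop minimises.
#'
#' @param logits logit array; @param gt_mask binary array of the same shape.
#' @param w_ce,w_dice term weights (default 0.5 each).
#' @param smooth soft-Dice smoothing constant.
#' @return scalar loss value.
#' @export
combined_loss <- function(logits, gt_mask, w_ce = 0.5, w_dice = 0.5,
                          smooth = 1e-5) {
  if (!identical(dim(logits), dim(gt_mask)) &&
      length(logits) != length(gt_mask))
    stop("logit and mask shapes differ")
  tp <- tape_new()
  tp_seg_loss(tp_leaf(tp, as.numeric(logits)), as.numeric(gt_mask),
              w_ce, w_dice, smooth)$value
}
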
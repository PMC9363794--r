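# Segmentation evaluation: one-vs-rest confusion counts per class, IoU and
# pixel accuracy with their unweighted means over all classes (background
# included), and Euclidean center errors.

CLASS_NAMES <- c("background", "disc", "macula")

#' Per-class one-vs-rest confusion counts
#'
#' For each class the mask pair is binarized (class vs rest) and pixel
#' counts TP/FP/FN/TN are accumulated; the four counts sum to the total
#' pixel count for every class.
#'
#' @param predicted,truth Integer matrices of identical size with values in
#'   `{0, 1, 2}`.
#' @return A data frame with one row per class: `class`, `tp`, `fp`, `fn`, `tn`.
#' @export
confusion_counts <- function(predicted, truth) {
  if (!identical(dim(predicted), dim(truth)))
    stop_dfameter("shape_mismatch", sprintf(
      "mask shapes differ: %s vs %s",
      paste(dim(predicted), collapse = "x"), paste(dim(truth), collapse = "x")))
  total <- length(truth)
  rows <- lapply(0:2, function(cl) {
    p <- predicted == cl
    t <- truth == cl
    tp <- sum(p & t)
    fp <- sum(p & !t)
    fn <- sum(!p & t)
    data.frame(class = CLASS_NAMES[cl + 1L], tp = tp, fp = fp, fn = fn,
               tn = total - tp - fp - fn)
  })
  do.call(rbind, rows)
}

#' IoU, pixel accuracy, and their means from confusion counts
#'
#' Per class, `IoU = TP / (FN + FP + TP)` and
#' `PA = (TP + TN) / (FN + FP + TP + TN)`; `MIoU` and `MPA` are the
#' unweighted means over all k+1 = 3 classes, background included. A class
#' absent from both masks has an undefined IoU ratio (0/0); it is reported
#' as 1.0 — nothing to find and nothing found — and flagged in `undefined`.
#'
#' @param counts Data frame from [confusion_counts()].
#' @return A list with per-class named vectors `iou` and `pa`, scalars
#'   `miou` and `mpa`, and a logical vector `undefined`.
#' @export
iou_pa <- function(counts) {
  stopifnot(all(c("tp", "fp", "fn", "tn") %in% names(counts)))
  denom <- counts$tp + counts$fp + counts$fn
  undefined <- denom == 0
  iou <- ifelse(undefined, 1.0, counts$tp / denom)
  pa <- (counts$tp + counts$tn) / (counts$tp + counts$fp + counts$fn + counts$tn)
  names(iou) <- names(pa) <- names(undefined) <- counts$class
  list(iou = iou, pa = pa, miou = mean(iou), mpa = mean(pa),
       undefined = undefined)
}

#' Euclidean center localization error
#'
#' Distance in pixels between a true and a predicted region center: `DO` for
#' the optic disc, `DM` for the macula.
#'
#' @param truth,predicted Numeric `(x, y)` coordinates.
#' @return Non-negative distance in pixels.
#' @export
center_error <- function(truth, predicted) {
  stopifnot(length(truth) == 2, length(predicted) == 2,
            is.finite(truth), is.finite(predicted))
  sqrt(sum((as.numeric(predicted) - as.numeric(truth))^2))
}

#' Min / max / average summary of per-image values
#'
#' The summary layout used for per-image DFA and center errors.
#'
#' @param values Non-empty numeric vector.
#' @return Named numeric `(min, max, average)`.
#' @export
summarize_values <- function(values) {
  if (length(values) == 0)
    stop_dfameter("empty_values", "cannot summarize an empty vector")
  stopifnot(is.numeric(values), all(is.finite(values)))
  c(min = min(values), max = max(values), average = mean(values))
}
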
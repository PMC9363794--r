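# End-to-end orchestration: dataset splitting with the 7:3 then 9:1
# protocol, per-image DFA measurement, and test-set evaluation producing
# the three summary tables (DFA error, IoU/PA, center errors).

#' Split image ids into train-pool/test and train/validation
#'
#' Shuffles the ids with a seeded uniform permutation, takes
#' `floor(N * 7/10)` for the training pool and the remainder for testing,
#' then splits the pool `floor(|pool| * 9/10)` / remainder into training and
#' validation. The floor arithmetic reproduces the published protocol
#' exactly: 682 ids give 477/205, and the 477 pool gives 429/48.
#'
#' @param ids Non-empty vector of image identifiers.
#' @param train_test Ratio pair for the first split (default `c(7, 3)`).
#' @param train_val Ratio pair for the second split (default `c(9, 1)`).
#' @param seed Integer seed for the shuffle.
#' @return A list with `train_pool`, `test`, `train`, `validation`;
#'   the three leaf sets are disjoint and exhaustive.
#' @export
split_dataset <- function(ids, train_test = c(7, 3), train_val = c(9, 1),
                          seed = 1L) {
  n <- length(ids)
  if (n == 0) stop_dfameter("empty_dataset", "no ids to split")
  stopifnot(all(train_test > 0), all(train_val > 0))
  perm <- with_seed(seed, sample(n))
  n_pool <- floor(n * train_test[1] / sum(train_test))
  pool <- ids[perm[seq_len(n_pool)]]
  test <- ids[perm[setdiff(seq_len(n), seq_len(n_pool))]]
  n_train <- floor(n_pool * train_val[1] / sum(train_val))
  list(train_pool = pool,
       test = test,
       train = pool[seq_len(n_train)],
       validation = pool[setdiff(seq_len(n_pool), seq_len(n_train))])
}

#' Measure the DFA from a segmentation mask
#'
#' The geometry + angle stages of the pipeline, independent of any model:
#' extracts the two centers from a three-class mask and computes the signed
#' DFA. A mask missing one of the structure classes yields
#' `status = "unmeasurable"` instead of an error.
#'
#' @param mask Integer matrix with values in `{0, 1, 2}`.
#' @param method Center definition passed to [extract_centers()].
#' @param id Optional record identifier.
#' @param true_dfa Optional ground-truth angle; when given, `dfa_err` is
#'   filled in.
#' @return A one-row data frame: `id`, `status`, `disc_x`, `disc_y`,
#'   `macula_x`, `macula_y`, `dfa_pred`, `dfa_true`, `dfa_err`.
#' @export
measure_from_mask <- function(mask, method = c("circle", "rectangle"),
                              id = NA_character_, true_dfa = NA_real_) {
  method <- match.arg(method)
  rec <- data.frame(id = id, status = "ok",
                    disc_x = NA_real_, disc_y = NA_real_,
                    macula_x = NA_real_, macula_y = NA_real_,
                    dfa_pred = NA_real_, dfa_true = true_dfa,
                    dfa_err = NA_real_)
  ctr <- tryCatch(extract_centers(mask, method),
                  dfameter_missing_class = function(e) e)
  if (inherits(ctr, "condition")) {
    rec$status <- "unmeasurable"
    attr(rec, "diagnostic") <- conditionMessage(ctr)
    return(rec)
  }
  rec$disc_x <- ctr$disc[["x"]]; rec$disc_y <- ctr$disc[["y"]]
  rec$macula_x <- ctr$macula[["x"]]; rec$macula_y <- ctr$macula[["y"]]
  rec$dfa_pred <- compute_dfa(ctr$disc, ctr$macula)
  if (is.finite(true_dfa)) rec$dfa_err <- dfa_error(rec$dfa_pred, true_dfa)
  rec
}

#' Measure the DFA of a single fundus image with a trained model
#'
#' Runs the full per-image flow: predict the segmentation mask, rescale it
#' to native resolution (nearest neighbour) when requested, extract the
#' disc and macula centers, and compute the signed DFA.
#'
#' @param image `H x W x 3` array in `[0, 1]`.
#' @param model A fitted [fit_segmenter()] model.
#' @param method Center definition (`"circle"` or `"rectangle"`).
#' @param native_resolution Measure at the image's native size (default
#'   `TRUE`); otherwise at network resolution.
#' @param id,true_dfa Optional record identifier / ground truth.
#' @return A one-row data frame as in [measure_from_mask()].
#' @export
measure_image <- function(image, model, method = c("circle", "rectangle"),
                          native_resolution = TRUE, id = NA_character_,
                          true_dfa = NA_real_) {
  stopifnot(inherits(model, "dfa_segmenter"))
  method <- match.arg(method)
  mask <- predict(model, list(image))[[1]]
  if (native_resolution && !all(dim(mask) == dim(image)[1:2]))
    mask <- resize_mask(mask, dim(image)[1], dim(image)[2])
  measure_from_mask(mask, method, id = id, true_dfa = true_dfa)
}

#' Evaluate a trained model on a labeled test set
#'
#' For each test image: predicts the mask, compares it with the ground
#' truth (per-class IoU and pixel accuracy), extracts centers and scores
#' the center errors DO/DM against the true centers, and measures the DFA
#' error. Produces the per-image table plus three summaries: min/max/average
#' DFA error, the IoU/PA table with MIoU/MPA, and min/max/average DO/DM.
#' Unmeasurable images (a structure class absent from the prediction) are
#' excluded from the angle and center summaries and counted separately.
#'
#' @param images,masks Lists: test images and their ground-truth masks.
#' @param model A fitted [fit_segmenter()] model, or `NULL` to evaluate the
#'   ground-truth masks against themselves (oracle mode; isolates the
#'   geometry + angle stages).
#' @param manifest Data frame with columns `id`, `disc_x`, `disc_y`,
#'   `fovea_x`, `fovea_y`, `true_dfa_deg` (as written by [make_dataset()]).
#' @param method Center definition.
#' @param native_resolution Compare masks and measure centers at native
#'   image resolution (default) rather than network resolution.
#' @param pooled Also compute IoU/PA from globally pooled pixel counts
#'   instead of per-image averaging.
#' @return A `dfa_evaluation` object: list with `per_image`, `dfa_summary`,
#'   `seg_summary`, `center_summary`, `n_unmeasurable`.
#' @export
evaluate_model <- function(images, masks, model, manifest,
                           method = c("circle", "rectangle"),
                           native_resolution = TRUE, pooled = FALSE) {
  method <- match.arg(method)
  n <- length(images)
  if (n == 0) stop_dfameter("empty_dataset", "no test images")
  stopifnot(length(masks) == n, nrow(manifest) == n)

  rows <- vector("list", n)
  pooled_counts <- NULL
  for (i in seq_len(n)) {
    truth <- masks[[i]]
    if (is.null(model)) {
      pred <- truth
    } else {
      pred <- predict(model, list(images[[i]]))[[1]]
      if (native_resolution && !all(dim(pred) == dim(truth)))
        pred <- resize_mask(pred, nrow(truth), ncol(truth))
      if (!native_resolution && !all(dim(truth) == dim(pred)))
        truth <- resize_mask(truth, nrow(pred), ncol(pred))
    }
    cc <- confusion_counts(pred, truth)
    sm <- iou_pa(cc)
    if (pooled) {
      pooled_counts <- if (is.null(pooled_counts)) cc else {
        pc <- pooled_counts
        pc[, c("tp", "fp", "fn", "tn")] <- pc[, c("tp", "fp", "fn", "tn")] +
          cc[, c("tp", "fp", "fn", "tn")]
        pc
      }
    }
    mr <- measure_from_mask(pred, method, id = manifest$id[i],
                            true_dfa = manifest$true_dfa_deg[i])
    scale <- if (is.null(model) || native_resolution) 1 else
      nrow(pred) / nrow(masks[[i]])
    do_px <- if (mr$status == "ok")
      center_error(c(manifest$disc_x[i], manifest$disc_y[i]) * scale,
                   c(mr$disc_x, mr$disc_y)) else NA_real_
    dm_px <- if (mr$status == "ok")
      center_error(c(manifest$fovea_x[i], manifest$fovea_y[i]) * scale,
                   c(mr$macula_x, mr$macula_y)) else NA_real_
    rows[[i]] <- data.frame(
      id = manifest$id[i], status = mr$status,
      iou_bg = sm$iou[["background"]], iou_disc = sm$iou[["disc"]],
      iou_macula = sm$iou[["macula"]],
      pa_bg = sm$pa[["background"]], pa_disc = sm$pa[["disc"]],
      pa_macula = sm$pa[["macula"]],
      do_px = do_px, dm_px = dm_px,
      dfa_pred = mr$dfa_pred, dfa_true = mr$dfa_true, dfa_err = mr$dfa_err)
  }
  per_image <- do.call(rbind, rows)
  ok <- per_image$status == "ok"

  seg_summary <- data.frame(
    class = c(CLASS_NAMES, "average"),
    iou = c(mean(per_image$iou_bg), mean(per_image$iou_disc),
            mean(per_image$iou_macula), NA),
    pa = c(mean(per_image$pa_bg), mean(per_image$pa_disc),
           mean(per_image$pa_macula), NA))
  seg_summary$iou[4] <- mean(seg_summary$iou[1:3])
  seg_summary$pa[4] <- mean(seg_summary$pa[1:3])

  dfa_summary <- if (any(ok)) summarize_values(per_image$dfa_err[ok]) else
    c(min = NA, max = NA, average = NA)
  center_summary <- if (any(ok))
    rbind(DO = summarize_values(per_image$do_px[ok]),
          DM = summarize_values(per_image$dm_px[ok]))
  else matrix(NA, 2, 3, dimnames = list(c("DO", "DM"),
                                        c("min", "max", "average")))

  out <- list(per_image = per_image, dfa_summary = dfa_summary,
              seg_summary = seg_summary, center_summary = center_summary,
              n_unmeasurable = sum(!ok),
              pooled = if (pooled) iou_pa(pooled_counts) else NULL)
  class(out) <- "dfa_evaluation"
  out
}

#' @export
print.dfa_evaluation <- function(x, ...) {
  cat("DFA measurement evaluation\n")
  cat(sprintf("  images: %d measurable, %d unmeasurable\n",
              sum(x$per_image$status == "ok"), x$n_unmeasurable))
  cat("\nDFA error (deg):\n")
  print(round(x$dfa_summary, 4))
  cat("\nSegmentation (fractions; multiply by 100 for %):\n")
  print(transform(x$seg_summary, iou = round(iou, 4), pa = round(pa, 4)),
        row.names = FALSE)
  cat("\nCenter errors (px):\n")
  print(round(x$center_summary, 4))
  invisible(x)
}
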
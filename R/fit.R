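#' Fit a fundus segmentation network
#'
#' Trains a three-class (background / optic disc / virtual macula)
#' segmentation network on image/mask pairs with unweighted per-pixel
#' softmax cross-entropy and the Adam optimizer (linear warmup over the
#' first two epochs, cosine decay to 10% of `learning_rate`), recording
#' per-epoch training and validation losses. The returned model keeps the
#' parameters of the epoch with the lowest validation loss (earliest epoch
#' on ties), which is what [predict.dfa_segmenter()] uses.
#'
#' Training is multi-start: if, after a run, one of the structure classes
#' is absent from every validation prediction (a collapsed optimum where
#' the disc and macula are not separated), the fit restarts from a
#' reseeded initialization — up to four attempts, with collapsed attempts
#' abandoned at mid-training — and the best non-collapsed attempt (lowest
#' validation loss) is kept. `$n_restarts` on the result records how many
#' restarts occurred.
#'
#' Architectures: `"deeplabv3plus"` (MobileNetV2-style encoder of 17
#' inverted-residual bottlenecks with a low-level tap after the first three,
#' ASPP over the high-level features, and a decoder that fuses the two
#' streams), plus `"unet"` and `"pspnet"` baselines in canonical minimal
#' form. `width_multiplier` scales every channel count, allowing desk-scale
#' CPU training.
#'
#' @param images List of `H x W x 3` arrays with values in `[0, 1]`.
#' @param masks List of integer matrices with values in `{0, 1, 2}`.
#' @param architecture One of `"deeplabv3plus"`, `"unet"`, `"pspnet"`.
#' @param input_size Square network resolution (default 512); inputs are
#'   resized to it (bilinear for images, nearest for masks). Must be
#'   divisible by `output_stride`.
#' @param width_multiplier Channel width scale in `(0, 1]`.
#' @param num_classes Number of classes (3).
#' @param atrous_rates ASPP dilation rates (DeepLabv3+ only).
#' @param output_stride Encoder output stride, 8 or 16 (DeepLabv3+ only).
#' @param epochs Training epochs (default 100).
#' @param learning_rate Adam step size (default 5e-5).
#' @param batch_size Mini-batch size (default 4).
#' @param validation Either `NULL` (split `validation_split` off the given
#'   data, by seeded shuffle with floor arithmetic) or a list with elements
#'   `images` and `masks`.
#' @param validation_split Fraction held out when `validation` is `NULL`
#'   (default 1/10, i.e. a 9:1 train/validation split).
#' @param seed Integer seed governing initialization, splitting and batch
#'   order.
#' @param checkpoint_dir If non-`NULL`, per-epoch parameter checkpoints are
#'   written there as RDS files.
#' @param verbose Print per-epoch losses.
#' @return An object of class `dfa_segmenter`.
#' @export
fit_segmenter <- function(images, masks,
                          architecture = c("deeplabv3plus", "unet", "pspnet"),
                          input_size = 512L, width_multiplier = 1,
                          num_classes = 3L, atrous_rates = c(6L, 12L, 18L),
                          output_stride = 16L,
                          epochs = 100L, learning_rate = 5e-5,
                          batch_size = 4L,
                          validation = NULL, validation_split = 1 / 10,
                          seed = 1L, checkpoint_dir = NULL,
                          verbose = FALSE) {
  architecture <- match.arg(architecture)
  if (length(images) == 0 || length(images) != length(masks))
    stop_dfameter("empty_dataset",
                  "need a non-empty, equal-length set of images and masks")
  if (input_size %% output_stride != 0)
    stop_dfameter("bad_config", sprintf(
      "input_size %d is not divisible by output_stride %d",
      input_size, output_stride))
  if (epochs < 1 || learning_rate <= 0)
    stop_dfameter("bad_config", "epochs must be >= 1 and learning_rate > 0")

  config <- list(architecture = architecture,
                 input_size = as.integer(input_size),
                 width_multiplier = width_multiplier,
                 num_classes = as.integer(num_classes),
                 atrous_rates = as.integer(atrous_rates),
                 output_stride = as.integer(output_stride))
  fns <- arch_registry(architecture)

  prep_x <- function(img) {
    if (!all(dim(img)[1:2] == input_size))
      img <- resize_image(img, input_size, input_size)
    img
  }
  prep_y <- function(m) {
    if (!all(dim(m) == input_size)) m <- resize_mask(m, input_size, input_size)
    m
  }
  images <- lapply(images, prep_x)
  masks <- lapply(masks, prep_y)

  if (is.null(validation)) {
    n <- length(images)
    n_train <- max(1L, floor(n * (1 - validation_split)))
    perm <- with_seed(seed, sample(n))
    tr <- perm[seq_len(n_train)]
    va <- if (n_train < n) perm[(n_train + 1L):n] else tr[1L]
    validation <- list(images = images[va], masks = masks[va])
    images <- images[tr]
    masks <- masks[tr]
  } else {
    validation <- list(images = lapply(validation$images, prep_x),
                       masks = lapply(validation$masks, prep_y))
  }

  # Small networks trained from scratch occasionally start in a basin where
  # the two structure classes are not separated (typically: every blob
  # labeled macula). Multi-start training detects such a collapse — a
  # structure class absent from every validation prediction — and retries
  # from a reseeded initialization, keeping the best attempt.
  max_attempts <- 4L
  attempts <- list()
  for (try in seq_len(max_attempts)) {
    attempt_seed <- seed + (try - 1L) * 1009L
    run <- train_segmenter_once(images, masks, validation, config, fns,
                                epochs, learning_rate, batch_size,
                                attempt_seed, checkpoint_dir, verbose,
                                abort_on_collapse = try < max_attempts)
    run$collapsed <- run$aborted ||
      segmenter_collapsed(run$params, validation, config, fns)
    attempts[[try]] <- run
    if (!run$collapsed) break
    if (verbose && try < max_attempts)
      message(sprintf(
        "attempt %d: a structure class is missing from every validation prediction; restarting", try))
  }
  ok <- !vapply(attempts, function(a) a$collapsed, TRUE)
  pool <- if (any(ok)) attempts[ok] else {
    # nothing separated the classes: fall back to completed runs (the
    # final attempt always runs to full length)
    attempts[!vapply(attempts, function(a) a$aborted, TRUE)]
  }
  run <- pool[[which.min(vapply(pool, function(a) a$best_loss, 0))]]

  structure(list(params = run$params, final_params = run$final_params,
                 config = config, history = run$history,
                 best_epoch = run$best_epoch, seed = seed,
                 n_restarts = length(attempts) - 1L,
                 n_parameters = tree_count(run$params)),
            class = "dfa_segmenter")
}

# One seeded training run: init, Adam with linear warmup (2 epochs) and
# cosine decay to 10% of the base rate, per-epoch train/validation losses,
# lowest-validation-loss parameter tracking.
train_segmenter_once <- function(images, masks, validation, config, fns,
                                 epochs, learning_rate, batch_size, seed,
                                 checkpoint_dir, verbose,
                                 abort_on_collapse = FALSE) {
  input_size <- config$input_size
  history <- data.frame(epoch = integer(), train_loss = numeric(),
                        val_loss = numeric())
  best <- list(loss = Inf, params = NULL, epoch = NA_integer_)
  aborted <- FALSE
  # late separation does happen: a run with no disc predictions halfway
  # through can still converge, so the abort check sits at 3/4 of training
  check_epoch <- max(2L, (3L * epochs) %/% 4L)

  batch_tensor <- function(imgs, msks, idx) {
    b <- length(idx)
    x <- array(0, c(input_size, input_size, 3L, b))
    y <- array(0L, c(input_size, input_size, b))
    for (k in seq_len(b)) {
      x[, , , k] <- imgs[[idx[k]]]
      y[, , k] <- msks[[idx[k]]]
    }
    list(x = x, y = y)
  }

  eval_loss <- function(p, imgs, msks) {
    n <- length(imgs)
    tot <- 0
    i <- 1L
    while (i <= n) {
      idx <- i:min(n, i + batch_size - 1L)
      bt <- batch_tensor(imgs, msks, idx)
      out <- fns$fwd(p, bt$x, config)
      tot <- tot + softmax_ce(out$logits, bt$y)$loss * length(idx)
      i <- i + batch_size
    }
    tot / n
  }

  with_seed(seed, {
    params <- fns$init(config)
    opt <- adam_init(params)
    n_train <- length(images)
    steps_per_epoch <- ceiling(n_train / batch_size)
    warmup_steps <- max(1L, 2L * steps_per_epoch)
    step <- 0L
    for (ep in seq_len(epochs)) {
      ord <- sample(n_train)
      ep_loss <- 0
      i <- 1L
      while (i <= n_train) {
        idx <- ord[i:min(n_train, i + batch_size - 1L)]
        bt <- batch_tensor(images, masks, idx)
        out <- fns$fwd(params, bt$x, config)
        ls <- softmax_ce(out$logits, bt$y)
        if (!is.finite(ls$loss))
          stop_dfameter("nonfinite_loss", sprintf(
            "non-finite training loss at epoch %d (batch starting %d)", ep, i))
        grads <- fns$bwd(params, out$cache, ls$dlogits, config)
        step <- step + 1L
        lr_t <- learning_rate * min(1, step / warmup_steps) *
          (0.1 + 0.9 * 0.5 * (1 + cos(pi * (ep - 1) / epochs)))
        st <- adam_step(params, grads, opt, lr_t)
        params <- st$params
        opt <- st$opt
        ep_loss <- ep_loss + ls$loss * length(idx)
        i <- i + batch_size
      }
      ep_loss <- ep_loss / n_train
      vl <- eval_loss(params, validation$images, validation$masks)
      history <- rbind(history, data.frame(epoch = ep, train_loss = ep_loss,
                                           val_loss = vl))
      if (verbose)
        message(sprintf("epoch %3d  train %.4f  val %.4f", ep, ep_loss, vl))
      if (!is.null(checkpoint_dir)) {
        dir.create(checkpoint_dir, recursive = TRUE, showWarnings = FALSE)
        saveRDS(list(epoch = ep, params = params, config = config,
                     train_loss = ep_loss, val_loss = vl),
                file.path(checkpoint_dir, sprintf("epoch%03d.rds", ep)))
      }
      if (vl < best$loss) best <- list(loss = vl, params = params, epoch = ep)
      if (abort_on_collapse && ep == check_epoch &&
          segmenter_collapsed(params, validation, config, fns)) {
        if (verbose)
          message(sprintf(
            "epoch %3d  structure class still missing from validation predictions; abandoning attempt", ep))
        aborted <- TRUE
        break
      }
    }
  })
  list(params = best$params, final_params = params, history = history,
       best_epoch = best$epoch, best_loss = best$loss, aborted = aborted)
}

# TRUE when a structure class (disc or macula) is absent from every
# validation prediction — the signature of a collapsed run.
segmenter_collapsed <- function(params, validation, config, fns) {
  s <- config$input_size
  seen <- c(FALSE, FALSE)
  for (img in validation$images) {
    x <- array(img, c(s, s, 3L, 1L))
    lm <- matrix(fns$fwd(params, x, config)$logits, s * s, config$num_classes)
    cls <- max.col(lm, ties.method = "first") - 1L
    seen <- seen | c(any(cls == 1L), any(cls == 2L))
    if (all(seen)) return(FALSE)
  }
  TRUE
}

#' Build an untrained segmentation model
#'
#' Initializes network parameters for the requested architecture without
#' training; useful for inspecting shapes and parameter counts, and as the
#' starting point that [fit_segmenter()] optimizes.
#'
#' @inheritParams fit_segmenter
#' @return A `dfa_segmenter` with random weights and an empty history.
#' @export
build_segmenter <- function(architecture = c("deeplabv3plus", "unet", "pspnet"),
                            input_size = 512L, width_multiplier = 1,
                            num_classes = 3L, atrous_rates = c(6L, 12L, 18L),
                            output_stride = 16L, seed = 1L) {
  architecture <- match.arg(architecture)
  if (input_size %% output_stride != 0)
    stop_dfameter("bad_config", sprintf(
      "input_size %d is not divisible by output_stride %d",
      input_size, output_stride))
  config <- list(architecture = architecture,
                 input_size = as.integer(input_size),
                 width_multiplier = width_multiplier,
                 num_classes = as.integer(num_classes),
                 atrous_rates = as.integer(atrous_rates),
                 output_stride = as.integer(output_stride))
  params <- with_seed(seed, arch_registry(architecture)$init(config))
  structure(list(params = params, final_params = params, config = config,
                 history = data.frame(epoch = integer(),
                                      train_loss = numeric(),
                                      val_loss = numeric()),
                 best_epoch = NA_integer_, seed = seed,
                 n_parameters = tree_count(params)),
            class = "dfa_segmenter")
}

#' Epoch with the lowest validation loss
#'
#' Pure function of a training history: returns the checkpoint (epoch
#' number) with minimal validation loss; ties resolve to the earliest epoch.
#'
#' @param history A `dfa_segmenter`, or a data frame with columns `epoch`
#'   and `val_loss`.
#' @return Integer epoch number.
#' @export
select_best_checkpoint <- function(history) {
  if (inherits(history, "dfa_segmenter")) history <- history$history
  if (!is.data.frame(history) || nrow(history) == 0)
    stop_dfameter("empty_history", "history must be a non-empty data frame")
  as.integer(history$epoch[which.min(history$val_loss)])
}

#' Predict label masks for new images
#'
#' Runs the fitted network on each image (resized to the network input
#' size) and takes the per-pixel argmax over the three class scores; ties
#' break toward the lowest class index. With `type = "prob"` the raw
#' softmax fields are returned instead.
#'
#' @param object A `dfa_segmenter`.
#' @param images A list of `H x W x 3` arrays (a single array is accepted).
#' @param type `"mask"` (default) or `"prob"`.
#' @param ... Unused.
#' @return A list of integer matrices (values 0/1/2) or probability arrays,
#'   at `input_size x input_size` resolution.
#' @export
predict.dfa_segmenter <- function(object, images, type = c("mask", "prob"),
                                  ...) {
  type <- match.arg(type)
  if (is.array(images) && length(dim(images)) == 3) images <- list(images)
  fns <- arch_registry(object$config$architecture)
  s <- object$config$input_size
  lapply(images, function(img) {
    if (!all(dim(img)[1:2] == s)) img <- resize_image(img, s, s)
    x <- array(img, c(s, s, 3L, 1L))
    out <- fns$fwd(object$params, x, object$config)
    lm <- matrix(out$logits, s * s, object$config$num_classes)
    if (type == "prob") {
      e <- exp(lm - apply(lm, 1, max))
      return(array(e / rowSums(e), c(s, s, object$config$num_classes)))
    }
    matrix(max.col(lm, ties.method = "first") - 1L, s, s)
  })
}

#' @export
print.dfa_segmenter <- function(x, ...) {
  cat(sprintf("Fundus segmentation model (%s)\n", x$config$architecture))
  cat(sprintf("  input %d x %d, width multiplier %.2f, %d classes\n",
              x$config$input_size, x$config$input_size,
              x$config$width_multiplier, x$config$num_classes))
  cat(sprintf("  %d trainable parameters\n", x$n_parameters))
  cat(sprintf("  trained %d epochs; best validation loss %.4f at epoch %d\n",
              nrow(x$history), min(x$history$val_loss), x$best_epoch))
  invisible(x)
}

#' @export
summary.dfa_segmenter <- function(object, ...) {
  print(object)
  h <- object$history
  cat(sprintf("  first/last train loss: %.4f / %.4f\n",
              h$train_loss[1], h$train_loss[nrow(h)]))
  cat(sprintf("  first/last val loss:   %.4f / %.4f\n",
              h$val_loss[1], h$val_loss[nrow(h)]))
  invisible(object)
}

#' Plot training and validation loss curves
#'
#' @param x A `dfa_segmenter`.
#' @param ... Passed to [graphics::matplot()].
#' @export
plot.dfa_segmenter <- function(x, ...) {
  h <- x$history
  graphics::matplot(h$epoch, cbind(h$train_loss, h$val_loss), type = "l",
                    lty = 1, col = c("steelblue", "firebrick"),
                    xlab = "epoch", ylab = "loss", ...)
  graphics::legend("topright", c("train", "validation"), lty = 1,
                   col = c("steelblue", "firebrick"), bty = "n")
  graphics::abline(v = x$best_epoch, lty = 3)
  invisible(x)
}

# ---- Adam ----

adam_init <- function(params) {
  zeros <- tree_map(function(p) p * 0, params)
  list(m = zeros, v = zeros, t = 0L)
}

adam_step <- function(params, grads, opt, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  opt$t <- opt$t + 1L
  opt$m <- tree_map2(function(m, g) beta1 * m + (1 - beta1) * g, opt$m, grads)
  opt$v <- tree_map2(function(v, g) beta2 * v + (1 - beta2) * g * g, opt$v, grads)
  bc1 <- 1 - beta1^opt$t
  bc2 <- 1 - beta2^opt$t
  upd <- tree_map2(function(m, v) lr * (m / bc1) / (sqrt(v / bc2) + eps),
                   opt$m, opt$v)
  params <- tree_map2(function(p, u) p - u, params, upd)
  list(params = params, opt = opt)
}
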
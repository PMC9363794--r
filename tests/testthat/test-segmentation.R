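test_that("the encoder plan has 17 bottlenecks split 1/2/14 around the tap", {
  for (w in c(1, 0.25)) {
    plan <- mobilenetv2_plan(w, 16)
    expect_equal(nrow(plan), 17L)
    tap <- which(plan$low_level_tap)
    expect_equal(tap, 3L)
    # 1 + 2 blocks before/at the tap, 14 after
    expect_equal(sum(plan$block <= tap), 3L)
    expect_equal(sum(plan$block > tap), 14L)
    expect_equal(plan$expansion[1], 1)
    expect_true(all(plan$expansion[-1] == 6))
    # residual exactly when the block preserves resolution and channels
    expect_equal(plan$residual, plan$stride == 1 & plan$cin == plan$cout)
  }
  # output-stride control turns late strides into dilation
  p8 <- mobilenetv2_plan(1, 8)
  expect_true(all(cumprod(c(2, p8$stride)) <= 8))
  expect_gt(max(p8$dilation), 1)
})

test_that("bottleneck blocks add the residual exactly when shapes match", {
  env <- asNamespace("dfameter")
  set.seed(71)
  x <- array(rnorm(16 * 16 * 6 * 2), c(16, 16, 6, 2))
  p_res <- env$bottleneck_init(6L, 6L, 6, stride = 1L)
  expect_equal(p_res$meta[["residual"]], 1)
  y_res <- env$bottleneck_fwd(p_res, x)$y
  p_plain <- p_res
  p_plain$meta[["residual"]] <- 0
  y_plain <- env$bottleneck_fwd(p_plain, x)$y
  expect_equal(y_res, y_plain + x)          # output = conv path + input
  # changed channel count or stride: no residual
  expect_equal(env$bottleneck_init(6L, 8L, 6, stride = 1L)$meta[["residual"]], 0)
  expect_equal(env$bottleneck_init(6L, 6L, 6, stride = 2L)$meta[["residual"]], 0)
  y_s2 <- env$bottleneck_fwd(env$bottleneck_init(6L, 6L, 6, stride = 2L), x)$y
  expect_equal(dim(y_s2), c(8, 8, 6, 2))
})

test_that("models produce full-resolution three-class score maps", {
  for (arch in c("deeplabv3plus", "unet", "pspnet")) {
    m <- build_segmenter(arch, input_size = 64, width_multiplier = 0.25, seed = 2)
    img <- array(runif(64 * 64 * 3), c(64, 64, 3))
    pr <- predict(m, img, type = "prob")[[1]]
    expect_equal(dim(pr), c(64, 64, 3))
    expect_equal(max(abs(apply(pr, c(1, 2), sum) - 1)), 0, tolerance = 1e-8)
    mk <- predict(m, img)[[1]]
    expect_true(all(mk %in% 0:2))
    expect_equal(dim(mk), c(64, 64))
  }
})

test_that("width multiplier shrinks the parameter count", {
  small <- build_segmenter("deeplabv3plus", input_size = 64,
                           width_multiplier = 0.25)
  big <- build_segmenter("deeplabv3plus", input_size = 64,
                         width_multiplier = 0.5)
  expect_lt(small$n_parameters, big$n_parameters)
})

test_that("argmax ties break toward the lowest class index", {
  m <- build_segmenter("deeplabv3plus", input_size = 32, width_multiplier = 0.25)
  env <- asNamespace("dfameter")
  m$params <- env$tree_map(function(p) p * 0, m$params)  # all logits equal
  mk <- predict(m, array(runif(32 * 32 * 3), c(32, 32, 3)))[[1]]
  expect_true(all(mk == 0L))
})

test_that("the loss prefers correct masks and training reduces it", {
  env <- asNamespace("dfameter")
  set.seed(83)
  y <- array(sample(0:2, 16 * 16 * 2, TRUE), c(16, 16, 2))
  onehot <- array(0, c(16, 16, 3, 2))
  for (k in 0:2) onehot[, , k + 1, ][y == k] <- 10
  bg <- array(0, c(16, 16, 3, 2)); bg[, , 1, ] <- 10
  expect_lt(env$softmax_ce(onehot, y)$loss, env$softmax_ce(bg, y)$loss)

  ds <- make_dataset(10, width = 64, height = 64, seed = 31,
                     dist_frac_range = c(0.32, 0.36))
  fit <- fit_segmenter(ds$images[1:8], ds$masks[1:8], "deeplabv3plus",
                       input_size = 64, width_multiplier = 0.25,
                       epochs = 3, learning_rate = 1e-3, batch_size = 4,
                       validation = list(images = ds$images[9:10],
                                         masks = ds$masks[9:10]),
                       seed = 3)
  h <- fit$history
  expect_equal(nrow(h), 3)
  expect_lt(h$train_loss[3], h$train_loss[1])
  expect_true(all(is.finite(h$val_loss)))
  expect_equal(fit$best_epoch, select_best_checkpoint(fit))
})

test_that("checkpoint selection is a pure minimum with earliest-epoch ties", {
  h <- data.frame(epoch = 1:3, val_loss = c(0.9, 0.5, 0.7))
  expect_equal(select_best_checkpoint(h), 2L)
  h2 <- data.frame(epoch = 1:2, val_loss = c(0.5, 0.5))
  expect_equal(select_best_checkpoint(h2), 1L)
  h3 <- data.frame(epoch = 1:4, val_loss = c(4, 3, 2, 1))
  expect_equal(select_best_checkpoint(h3), 4L)
  expect_identical(select_best_checkpoint(h), select_best_checkpoint(h))
  expect_error(select_best_checkpoint(data.frame()),
               class = "dfameter_empty_history")
})

test_that("invalid configurations are rejected", {
  expect_error(build_segmenter("deeplabv3plus", input_size = 100),
               class = "dfameter_bad_config")
  expect_error(fit_segmenter(list(), list()), class = "dfameter_empty_dataset")
})
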
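test_that("confusion counts match a hand count on a 2x2 example", {
  truth <- matrix(c(1, 0, 1, 2), 2, 2)      # [[1,1],[0,2]] by rows
  pred <- matrix(c(1, 0, 0, 2), 2, 2)       # [[1,0],[0,2]] by rows
  cc <- confusion_counts(pred, truth)
  c1 <- cc[cc$class == "disc", ]
  expect_equal(c1$tp, 1)
  expect_equal(c1$fn, 1)
  expect_equal(c1$fp, 0)
  expect_equal(c1$tn, 2)
  # partition identity: the four counts always sum to the pixel total
  expect_true(all(rowSums(cc[, c("tp", "fp", "fn", "tn")]) == 4))
  m <- iou_pa(cc)
  expect_equal(m$iou[["disc"]], 1 / 2)
  expect_equal(m$pa[["disc"]], 3 / 4)
})

test_that("perfect prediction gives unit metrics and zero errors", {
  set.seed(5)
  truth <- random_mask(16, 16)
  m <- iou_pa(confusion_counts(truth, truth))
  expect_equal(unname(m$iou), rep(1, 3))
  expect_equal(unname(m$pa), rep(1, 3))
  expect_equal(m$miou, 1)
  expect_equal(m$mpa, 1)
})

test_that("metric identities hold on random masks against per-pixel recomputation", {
  set.seed(17)
  for (i in 1:25) {
    truth <- random_mask(16, 16)
    pred <- random_mask(16, 16)
    cc <- confusion_counts(pred, truth)
    m <- iou_pa(cc)
    expect_equal(m$miou, mean(m$iou), tolerance = 1e-12)
    expect_equal(m$mpa, mean(m$pa), tolerance = 1e-12)
    for (cl in 0:2) {
      ref <- direct_iou_pa(pred, truth, cl)
      expect_equal(m$iou[[cl + 1]], ref$iou, tolerance = 1e-12)
      expect_equal(m$pa[[cl + 1]], ref$pa, tolerance = 1e-12)
      expect_gte(m$iou[[cl + 1]], 0)
      expect_lte(m$iou[[cl + 1]], m$pa[[cl + 1]])
      expect_lte(m$pa[[cl + 1]], 1)
    }
  }
})

test_that("per-class IoU is invariant to relabeling the other classes", {
  set.seed(29)
  truth <- random_mask(12, 12)
  pred <- random_mask(12, 12)
  swap <- function(m) { out <- m; out[m == 0] <- 2L; out[m == 2] <- 0L; out }
  a <- iou_pa(confusion_counts(pred, truth))
  b <- iou_pa(confusion_counts(swap(pred), swap(truth)))
  expect_equal(a$iou[["disc"]], b$iou[["disc"]])
})

test_that("a class absent from both masks scores IoU 1 and is flagged", {
  truth <- matrix(c(0L, 1L, 1L, 0L), 2, 2)
  pred <- truth
  m <- iou_pa(confusion_counts(pred, truth))
  expect_equal(m$iou[["macula"]], 1)
  expect_true(m$undefined[["macula"]])
  expect_false(any(m$undefined[c("background", "disc")]))
})

test_that("shape mismatches are rejected", {
  expect_error(confusion_counts(matrix(0L, 2, 2), matrix(0L, 2, 3)),
               class = "dfameter_shape_mismatch")
})

test_that("center error is the Euclidean distance and is symmetric", {
  expect_equal(center_error(c(0, 0), c(3, 4)), 5)
  expect_equal(center_error(c(7, 7), c(7, 7)), 0)
  set.seed(41)
  for (i in 1:100) {
    a <- runif(2, 0, 2000); b <- runif(2, 0, 2000)
    expect_equal(center_error(a, b), center_error(b, a))
    expect_gte(center_error(a, b), 0)
  }
})

test_that("summaries report exact min, max and mean", {
  expect_equal(unname(summarize_values(0.76)), c(0.76, 0.76, 0.76))
  expect_equal(unname(summarize_values(c(0, 1, 2))), c(0, 2, 1))
  set.seed(53)
  x <- runif(1000)
  s <- summarize_values(x)
  expect_lt(abs(s[["average"]] - 0.5), 3 * sd(x) / sqrt(1000))
  expect_error(summarize_values(numeric(0)), class = "dfameter_empty_values")
})
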
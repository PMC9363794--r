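test_that("minimum enclosing circle handles degenerate and small cases", {
  f1 <- min_enclosing_circle(cbind(5, 5))
  expect_equal(unname(f1$center), c(5, 5))
  expect_equal(f1$radius, 0)
  f2 <- min_enclosing_circle(cbind(c(0, 2), c(0, 0)))
  expect_equal(unname(f2$center), c(1, 0))
  expect_equal(f2$radius, 1)
  f3 <- min_enclosing_circle(cbind(c(0, 4, 2), c(0, 0, 2)))
  expect_equal(unname(f3$center), c(2, 0))
  expect_equal(f3$radius, 2)
  expect_error(min_enclosing_circle(matrix(numeric(0), 0, 2)),
               class = "dfameter_empty_points")
})

test_that("minimum enclosing circle matches the brute-force oracle and its invariants", {
  set.seed(21)
  for (i in 1:60) {
    n <- sample(1:10, 1)
    pts <- cbind(runif(n, 0, 100), runif(n, 0, 100))
    fit <- min_enclosing_circle(pts)
    oracle <- brute_force_mec(pts)
    expect_lt(abs(fit$radius - oracle$radius), 1e-6)
    # containment: every point inside the fitted circle
    d <- sqrt((pts[, 1] - fit$center[["x"]])^2 + (pts[, 2] - fit$center[["y"]])^2)
    expect_true(all(d <= fit$radius + 1e-7))
  }
})

test_that("largest 8-connected component agrees with a flood-fill oracle", {
  set.seed(33)
  for (i in 1:20) {
    mask <- matrix(sample(0:2, 32 * 32, replace = TRUE, prob = c(0.8, 0.1, 0.1)),
                   32, 32)
    for (cl in 1:2) {
      got <- largest_component(mask, cl)
      lab <- flood_fill_components(mask == cl)
      if (max(lab) == 0) {
        expect_equal(nrow(got), 0L)
      } else {
        sizes <- tabulate(lab[lab > 0])
        expect_equal(nrow(got), max(sizes))
        # the returned pixels form one oracle component
        ids <- unique(lab[cbind(got[, "y"], got[, "x"])])
        expect_length(ids, 1)
        expect_equal(sum(lab == ids), nrow(got))
      }
    }
  }
})

test_that("largest component picks the bigger blob and handles absent classes", {
  mask <- matrix(0L, 10, 10)
  mask[2:3, 2:3] <- 1L            # 4 pixels
  mask[7:8, 6:9] <- 1L            # 8 pixels
  got <- largest_component(mask, 1L)
  expect_equal(nrow(got), 8L)
  expect_true(all(got[, "y"] %in% 7:8))
  expect_equal(nrow(largest_component(mask, 2L)), 0L)
})

test_that("extract_centers finds symmetric centers under both methods", {
  mask <- matrix(0L, 30, 30)
  mask[11:21, 11:21] <- 1L        # solid 11x11 square centered at (16, 16)
  mask[24:26, 24:26] <- 2L
  for (m in c("circle", "rectangle")) {
    ctr <- extract_centers(mask, m)
    expect_equal(unname(ctr$disc), c(16, 16))
    expect_equal(unname(ctr$macula), c(25, 25))
  }
})

test_that("circle and rectangle centers agree for rasterized discs", {
  sc <- make_scene(256, 256, dfa = 4, disc_fovea_distance = 80, seed = 2)
  mask <- render_labels(sc)
  c1 <- extract_centers(mask, "circle")
  c2 <- extract_centers(mask, "rectangle")
  expect_lt(max(abs(c1$disc - c2$disc)), 1)
  expect_lt(max(abs(c1$macula - c2$macula)), 1)
})

test_that("extract_centers ignores background and smaller other-class speckle", {
  sc <- make_scene(256, 256, dfa = -3, disc_fovea_distance = 80, seed = 4)
  mask <- render_labels(sc)
  base <- extract_centers(mask)
  noisy <- mask
  noisy[1:2, 1:2] <- 1L           # small disc speckle far from the real disc
  noisy[254:255, 1:2] <- 2L       # small macula speckle
  again <- extract_centers(noisy)
  expect_equal(again$disc, base$disc)
  expect_equal(again$macula, base$macula)
})

test_that("a missing structure class raises a classed error", {
  mask <- matrix(0L, 8, 8)
  mask[2, 2] <- 1L
  expect_error(extract_centers(mask), class = "dfameter_missing_class")
  cnd <- tryCatch(extract_centers(mask), condition = function(e) e)
  expect_equal(cnd$which, "macula")
})
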
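test_that("scene construction places the fovea at the requested angle and distance", {
  s0 <- make_scene(2584, 1985, dfa = 0, disc_fovea_distance = 800, seed = 1)
  expect_equal(s0$fovea_center[["y"]], s0$disc_center[["y"]])
  expect_equal(s0$fovea_center[["x"]] - s0$disc_center[["x"]], 800)

  set.seed(61)
  for (i in 1:20) {
    dfa <- runif(1, -12, 12)
    d <- runif(1, 700, 900)
    s <- make_scene(2584, 1985, dfa, d, seed = i)
    got_d <- sqrt(sum((s$fovea_center - s$disc_center)^2))
    expect_lt(abs(got_d - d), 1)
    expect_equal(s$true_dfa, compute_dfa(s$disc_center, s$fovea_center))
  }

  s <- make_scene(512, 512, dfa = -7.13, disc_fovea_distance = 200, seed = 7)
  expect_lt(abs(compute_dfa(s$disc_center, s$fovea_center) - (-7.13)), 0.3)
})

test_that("impossible placements and bad parameters are rejected", {
  expect_error(make_scene(128, 128, dfa = 0, disc_fovea_distance = 200, seed = 1),
               class = "dfameter_placement_impossible")
  expect_error(make_scene(512, 512, dfa = 0, disc_fovea_distance = 40, seed = 1),
               class = "dfameter_placement_impossible")  # regions would overlap
  expect_error(make_scene(32, 32, dfa = 0, disc_fovea_distance = 10),
               class = "dfameter_bad_scene")
  expect_error(make_scene(512, 512, dfa = 95, disc_fovea_distance = 150),
               class = "dfameter_bad_scene")
})

test_that("label masks obey the pixel-center geometry", {
  s <- make_scene(512, 512, dfa = 5, disc_fovea_distance = 170, seed = 3)
  mask <- render_labels(s)
  expect_true(all(mask %in% 0:2))
  # macula pixels: exactly those within the label radius of the center
  idx <- which(mask == 2L, arr.ind = TRUE)
  d <- sqrt((idx[, 2] - s$fovea_center[["x"]])^2 +
              (idx[, 1] - s$fovea_center[["y"]])^2)
  expect_true(all(d <= s$macula_label_radius))
  outside <- which(mask != 2L, arr.ind = TRUE)
  od <- sqrt((outside[, 2] - s$fovea_center[["x"]])^2 +
               (outside[, 1] - s$fovea_center[["y"]])^2)
  expect_true(all(od > s$macula_label_radius))
  # rasterized area close to the analytic disc area
  expect_lt(abs(sum(mask == 2L) - pi * s$macula_label_radius^2) /
              (pi * s$macula_label_radius^2), 0.005)
})

test_that("a degenerate half-pixel disc rasterizes to at most one pixel", {
  s <- make_scene(512, 512, dfa = 0, disc_fovea_distance = 200, seed = 9,
                  disc_radii = c(0.5, 0.5))
  expect_equal(sum(render_labels(s) == 1L), 1L)  # integer center: exactly one
  s_off <- s
  s_off$disc_center <- s$disc_center + 0.5       # off-grid center
  expect_lte(sum(render_labels(s_off) == 1L), 1L)
})

test_that("rendered images have the expected photometric structure", {
  s <- make_scene(256, 256, dfa = 6, disc_fovea_distance = 85, seed = 13,
                  n_vessels = 0L, noise_sigma = 0)
  img <- render_image(s)
  expect_equal(dim(img), c(256, 256, 3))
  expect_true(all(img >= 0 & img <= 1))
  lum <- (img[, , 1] + img[, , 2] + img[, , 3]) / 3
  mask <- render_labels(s)
  ring <- mask == 0 &
    outer((seq_len(256) - s$disc_center[["y"]])^2,
          (seq_len(256) - s$disc_center[["x"]])^2, "+") <
      (3 * max(s$disc_radii))^2
  expect_gt(mean(lum[mask == 1]), mean(lum[ring]))
  near_fovea <- outer((seq_len(256) - s$fovea_center[["y"]])^2,
                      (seq_len(256) - s$fovea_center[["x"]])^2, "+") < 25^2
  expect_lt(mean(lum[near_fovea]), mean(lum[mask == 0 & !ring]))
})

test_that("rendering is deterministic and ground truth round-trips", {
  s <- make_scene(256, 256, dfa = -4, disc_fovea_distance = 82, seed = 17)
  expect_identical(render_image(s), render_image(s))
  expect_identical(render_labels(s), render_labels(s))
  ctr <- extract_centers(render_labels(s))
  expect_lt(center_error(s$disc_center, ctr$disc), 1.5)
  expect_lt(center_error(s$fovea_center, ctr$macula), 1.5)
  expect_lt(dfa_error(compute_dfa(ctr$disc, ctr$macula), s$true_dfa), 0.3)
})

test_that("datasets are reproducible and carry consistent ground truth", {
  d1 <- make_dataset(4, width = 160, height = 160, seed = 23)
  d2 <- make_dataset(4, width = 160, height = 160, seed = 23)
  expect_identical(d1$manifest, d2$manifest)
  expect_identical(d1$images, d2$images)
  for (i in 1:4) {
    expect_true(all(d1$masks[[i]] %in% 0:2))
    expect_equal(compute_dfa(c(d1$manifest$disc_x[i], d1$manifest$disc_y[i]),
                             c(d1$manifest$fovea_x[i], d1$manifest$fovea_y[i])),
                 d1$manifest$true_dfa_deg[i])
  }
})

test_that("written datasets round-trip through PNG and CSV", {
  dir <- withr::local_tempdir()
  make_dataset(2, dir = dir, width = 128, height = 128, seed = 29)
  ds <- read_dataset(dir)
  expect_equal(nrow(ds$manifest), 2)
  expect_true(all(file.exists(file.path(dir, ds$manifest$image_path))))
  expect_true(all(vapply(ds$masks, function(m) all(m %in% 0:2), TRUE)))
  # masks survive the 8-bit PNG round trip exactly
  mem <- make_dataset(2, width = 128, height = 128, seed = 29)
  expect_identical(ds$masks[[1]], mem$masks[[1]])
})
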
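test_that("worked examples match the arctan form and sign rule", {
  # horizontal and vertical limiting cases
  expect_equal(compute_dfa(c(100, 100), c(300, 100)), 0)
  expect_equal(compute_dfa(c(100, 100), c(100, 300)), -90)
  expect_equal(compute_dfa(c(100, 100), c(100, 50)), 90)
  # arctan(60/600) * 180/pi = 5.7106, negated when the fovea is below
  expect_equal(compute_dfa(c(1000, 1000), c(1600, 940)), 5.7106, tolerance = 1e-4)
  expect_equal(compute_dfa(c(1000, 1000), c(1600, 1060)), -5.7106, tolerance = 1e-4)
})

test_that("coincident centers are rejected", {
  expect_error(compute_dfa(c(5, 5), c(5, 5)), class = "dfameter_coincident_centers")
})

test_that("angle range, mirror antisymmetry and translation invariance hold", {
  set.seed(101)
  for (i in 1:200) {
    o <- runif(2, 0, 2000)
    m <- o + c(runif(1, 10, 800) * sample(c(-1, 1), 1), runif(1, -800, 800))
    a <- compute_dfa(o, m)
    expect_gte(a, -90)
    expect_lte(a, 90)
    # reflect the fovea across the horizontal through the disc center
    expect_equal(compute_dfa(o, c(m[1], 2 * o[2] - m[2])), -a, tolerance = 1e-12)
    # translation invariance
    sh <- runif(2, -500, 500)
    expect_equal(compute_dfa(o + sh, m + sh), a, tolerance = 1e-9)
  }
})

test_that("small angles agree with the linear ratio approximation", {
  set.seed(7)
  for (i in 1:100) {
    dx <- runif(1, 300, 900)
    dy <- runif(1, 0, dx * tan(10 * pi / 180))
    a <- compute_dfa(c(0, 0), c(dx, -dy))
    lin <- (dy / dx) * 180 / pi
    expect_lt(abs(a - lin), 0.35)
  }
})

test_that("dfa_error is a symmetric absolute difference", {
  expect_equal(dfa_error(0.76, 0.76), 0)
  expect_equal(dfa_error(-5, 5), 10)
  set.seed(11)
  a <- runif(100, -90, 90); b <- runif(100, -90, 90)
  expect_equal(dfa_error(a, b), dfa_error(b, a))
  expect_true(all(dfa_error(a, b) >= 0))
})
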
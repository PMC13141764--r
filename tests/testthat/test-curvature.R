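test_that("a circle's curvature profile is flat at 1/r", {
  semi <- circle_arc(10, 180, 400)
  pr <- estimate_curvature(semi, smoothing = 0.3)
  interior <- pr$s > 0.05 * max(pr$s) & pr$s < 0.95 * max(pr$s)
  expect_true(all(abs(abs(pr$kappa[interior]) - 0.1) < 0.005))
  expect_equal(total_curvature(pr), pi, tolerance = 0.02)
  expect_equal(average_curvature(pr), 0.1, tolerance = 0.005)
  expect_lt(curvature_variation(pr), 5e-3)
  # a closed circle has constant curvature: near-zero variation
  closed <- estimate_curvature(circle_arc(5, 360, 300, closed = TRUE), smoothing = 0.3)
  expect_equal(max_curvature(closed), 0.2, tolerance = 0.05)
  expect_lt(curvature_variation(closed), 1e-3)
})

test_that("a straight segment has (numerically) zero curvature everywhere", {
  pr <- estimate_curvature(straight_segment(100, 101), smoothing = 0.3)
  expect_lt(max_curvature(pr), 1e-3)
  expect_lt(total_curvature(pr), 0.01)
  expect_lt(curvature_variation(pr), 1e-3)
})

test_that("a full closed contour integrates to 2*pi", {
  circ <- circle_arc(10, 360, 720, closed = TRUE)
  pr <- estimate_curvature(circ, smoothing = 0.3)
  expect_equal(total_curvature(pr), 2 * pi, tolerance = 0.02)
})

test_that("average curvature never exceeds maximum curvature", {
  set.seed(11)
  for (i in 1:10) {
    n <- 80
    cv <- boundary_curve(cumsum(runif(n, 0.2, 1)), cumsum(rnorm(n, 0, 0.3)))
    pr <- estimate_curvature(cv)
    expect_lte(average_curvature(pr), max_curvature(pr) + 1e-12)
  }
})

test_that("piecewise and mixed fixtures match their analytic values", {
  # two joined arcs, radii 10 then 5: the tighter arc dominates the maximum
  th1 <- seq(-pi / 3, pi / 3, length.out = 200)
  a1 <- cbind(10 * cos(th1), 10 * sin(th1))
  ctr <- a1[200, ] - 5 * c(cos(pi / 3), sin(pi / 3))
  th2 <- seq(pi / 3, pi, length.out = 200)
  joined <- boundary_curve(
    c(a1[, 1], ctr[1] + 5 * cos(th2)[-1]),
    c(a1[, 2], ctr[2] + 5 * sin(th2)[-1])
  )
  expect_equal(max_curvature(estimate_curvature(joined, smoothing = 0.3)), 0.2,
    tolerance = 0.1
  )
  # half straight + half circular arc (r = 10) of equal length: mean = 0.05
  L_half <- 10 * pi / 2
  th <- seq(-pi / 2, -pi / 2 + L_half / 10, length.out = 300)
  half <- boundary_curve(
    c(seq(-L_half, 0, length.out = 300), (10 * cos(th))[-1]),
    c(rep(0, 300), (10 + 10 * sin(th))[-1])
  )
  expect_equal(average_curvature(estimate_curvature(half, smoothing = 0.3)), 0.05,
    tolerance = 0.1
  )
})

test_that("curvature variation recovers the clothoid rate", {
  cl <- make_shape(shape_spec("clothoid", rate = 0.005, length = 100))$curve
  pr <- estimate_curvature(cl, smoothing = 0.3)
  expect_equal(curvature_variation(pr), 0.005, tolerance = 0.1)
})

test_that("the default smoothing absorbs 0.2 mm jitter on a circle", {
  for (s in 1:3) {
    noisy <- make_shape(shape_spec("arc",
      radius = 10, angle = 360, size = 64,
      jitter = 0.2, seed = s
    ))$curve
    pr <- estimate_curvature(noisy)
    expect_equal(mean(abs(pr$kappa)), 0.1, tolerance = 0.1)
  }
})

test_that("curvature estimation refuses degenerate input", {
  expect_error(estimate_curvature(boundary_curve(c(0, 1, 2, 3, 4), rep(0, 5))),
    class = "glioshape_too_few_points"
  )
})
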
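test_that("ellipse phantom renders by pixel-center membership", {
  img <- make_ellipse_phantom(disc_spec())
  expect_equal(img$data[32, 32], 1.0)
  expect_equal(img$data[1, 1], 0.0)
  expect_equal(dim(img), c(64L, 64L))

  empty <- make_ellipse_phantom(phantom_spec())
  expect_true(all(empty$data == 0))
  expect_equal(dim(empty), c(64L, 64L))
})

test_that("disc pixel area matches the analytic area within the perimeter bound", {
  n <- 512L
  img <- make_ellipse_phantom(disc_spec(grid_size = n))
  frac <- mean(img$data > 0)
  analytic <- pi * 0.25 / 4
  # all uncertainty lives in the one-pixel-wide boundary band
  perimeter_bound <- 2 * pi * 0.5 * (2 / n) / 4
  expect_lt(abs(frac - analytic), perimeter_bound)

  # refining the grid shrinks the discrepancy below the coarse-grid bound
  frac64 <- mean(make_ellipse_phantom(disc_spec(grid_size = 64L))$data > 0)
  bound64 <- 2 * pi * 0.5 * (2 / 64) / 4
  expect_lt(abs(frac64 - analytic), bound64)
})

test_that("phantom spec validation rejects bad geometry", {
  expect_error(phantom_spec(grid_size = 4), "grid_size")
  expect_error(phantom_spec(fov = -1), "fov")
  expect_error(phantom_spec(data.frame(cx = 0, cy = 0, a = -1, b = 1,
                                       rot_deg = 0, intensity = 1)),
               "semi-axes")
  expect_error(myocardial_spec(outer_radius = 0.4, inner_radius = 0.5),
               "inner_radius")
})

test_that("myocardial phantom places defects by polar angle", {
  spec <- myocardial_spec(outer_radius = 0.6, inner_radius = 0.4,
                          base_counts = 100,
                          defects = data.frame(start_deg = 0, end_deg = 60,
                                               scale = 0.3))
  img <- make_myocardial_phantom(spec)
  # probe annulus pixels at polar angles 30 (defect) and 90 (normal)
  probe <- function(angle_deg, r = 0.5) {
    n <- nrow(img$data)
    x <- r * cos(angle_deg * pi / 180)
    y <- r * sin(angle_deg * pi / 180)
    col <- round(x / (2 / n) + (n + 1) / 2)
    row <- round(-y / (2 / n) + (n + 1) / 2)
    img$data[row, col]
  }
  expect_equal(probe(30), 30.0)
  expect_equal(probe(90), 100.0)
  # cavity and exterior are zero
  expect_equal(img$data[32, 32], 0)
  expect_equal(img$data[1, 1], 0)
})

test_that("defect of scale 1 is invisible and no-defect phantom is 4-fold symmetric", {
  base <- make_myocardial_phantom(myocardial_spec())
  trivial <- make_myocardial_phantom(
    myocardial_spec(defects = data.frame(start_deg = 10, end_deg = 100,
                                         scale = 1)))
  expect_identical(base$data, trivial$data)

  # 90-degree grid rotation maps pixel centers onto pixel centers exactly
  rot90 <- t(base$data)[, nrow(base$data):1]
  expect_equal(rot90, base$data)
})

test_that("gated series follows the cosine cavity schedule", {
  spec <- myocardial_spec(outer_radius = 0.6, inner_radius = 0.35)
  g <- make_gated_series(spec, n_frames = 8, ed_inner_radius = 0.4,
                         es_inner_radius = 0.2)
  expect_length(g$frames, 8L)
  expect_identical(g$ed_index, 1L)
  cavity <- vapply(g$frames, function(f) {
    n <- nrow(f$data)
    cc <- pixel_centers(n, f$fov)
    R <- sqrt(outer(cc^2, cc^2, `+`))
    sum(f$data[R < 0.45] == 0)
  }, numeric(1))
  expect_gt(cavity[g$ed_index], cavity[g$es_index])
  # unique maximal-area frame at index 1
  expect_identical(which(cavity == max(cavity)), 1L)
  # monotone from ED to ES along the schedule
  expect_true(all(diff(cavity[1:g$es_index]) <= 0))

  # degenerate: ED radius = ES radius gives identical frames and EF 0
  g0 <- make_gated_series(spec, 8, ed_inner_radius = 0.3,
                          es_inner_radius = 0.3)
  expect_identical(g0$frames[[1]]$data, g0$frames[[5]]$data)
  expect_equal(compute_function_params(g0)$EF, 0)

  expect_error(make_gated_series(spec, 8, ed_inner_radius = 0.2,
                                 es_inner_radius = 0.4), "es_inner_radius")
  expect_error(make_gated_series(spec, 1), "n_frames")
})

test_that("Poisson noise is seeded, mean-preserving, and rejects negatives", {
  zero <- ect_image(matrix(0, 64, 64))
  expect_identical(add_poisson_noise(zero, 1)$data, zero$data)

  flat <- ect_image(matrix(100, 64, 64))
  n1 <- add_poisson_noise(flat, 42)
  n2 <- add_poisson_noise(flat, 42)
  expect_identical(n1$data, n2$data)
  n3 <- add_poisson_noise(flat, 43)
  expect_false(identical(n1$data, n3$data))
  # 4096 independent Poisson(100) draws: mean within 3 sd of the mean
  expect_gt(mean(n1$data), 98.5)
  expect_lt(mean(n1$data), 101.5)

  neg <- ect_image(matrix(-1, 8, 8))
  expect_error(add_poisson_noise(neg, 1), "nonnegative")
})

test_that("noise call does not disturb the caller's RNG stream", {
  set.seed(7)
  a <- stats::runif(1)
  set.seed(7)
  invisible(add_poisson_noise(ect_image(matrix(1, 8, 8)), seed = 99))
  b <- stats::runif(1)
  expect_identical(a, b)
})
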
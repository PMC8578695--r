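test_that("ramp filter annihilates DC and preserves zero", {
  d <- 64L
  tt <- pixel_centers(d, 1)
  const <- ect_sinogram(matrix(5, 3, d), c(0, 60, 120), tt, 1)
  f <- ramp_filter(const)
  expect_lt(max(abs(rowMeans(f$data))), 1e-8 * 5)
  expect_lt(max(abs(f$data)), 1e-8 * 5)

  zero <- ect_sinogram(matrix(0, 2, d), c(0, 90), tt, 1)
  expect_true(all(ramp_filter(zero)$data == 0))

  expect_error(filter_spec(cutoff = 0), "cutoff")
  expect_error(filter_spec(cutoff = 1.5), "cutoff")
})

test_that("frequency-domain filtering equals direct circular convolution", {
  d <- 64L
  tt <- pixel_centers(d, 1)
  dx <- 2 / d
  spec <- filter_spec(pad_factor = 2)
  n_pad <- 2L * d
  H <- ectfbp:::ramp_response(n_pad, dx, spec)
  kernel <- Re(stats::fft(H, inverse = TRUE)) / n_pad

  imp <- matrix(0, 1, d); imp[1, 17] <- 1
  sino <- ect_sinogram(imp, 0, tt, 1)
  got <- ramp_filter(sino, spec)$data[1, ]

  # brute-force circular convolution on the padded grid
  p <- c(imp[1, ], rep(0, n_pad - d))
  direct <- vapply(seq_len(n_pad), function(j) {
    sum(p * kernel[((j - seq_len(n_pad)) %% n_pad) + 1])
  }, numeric(1))
  expect_lt(max(abs(got - direct[seq_len(d)])) / max(abs(got)), 1e-6)
})

test_that("sampled ramp kernel matches the analytic band-limited kernel", {
  d <- 64L
  dx <- 2 / d
  n_pad <- 2L * d
  H <- ectfbp:::ramp_response(n_pad, dx, filter_spec())
  kernel <- Re(stats::fft(H, inverse = TRUE)) / n_pad
  analytic <- function(m) {
    ifelse(m == 0, 1 / (4 * dx),
           ifelse(m %% 2 == 0, 0, -1 / (pi^2 * m^2 * dx)))
  }
  taps <- 0:9
  expect_lt(max(abs(kernel[taps + 1] - analytic(taps))), 1e-3 * kernel[1])
})

test_that("windowed filters attenuate high frequencies but keep DC at zero", {
  d <- 64L
  dx <- 2 / d
  for (kind in c("ramp-hamming", "ramp-shepp")) {
    H <- ectfbp:::ramp_response(2L * d, dx, filter_spec(kind))
    Hr <- ectfbp:::ramp_response(2L * d, dx, filter_spec("ramp"))
    expect_identical(H[1], 0)
    expect_true(all(H <= Hr + 1e-12))
    expect_lt(H[d + 1], Hr[d + 1])  # Nyquist bin attenuated
  }
})

test_that("single-view back projection smears a constant row at pi/M", {
  d <- 64L
  tt <- pixel_centers(d, 1)
  cval <- 2.5
  fs <- ect_sinogram(matrix(cval, 1, d), 37, tt, 1)
  img <- backproject(fs)
  # central region is fully covered by the detector at every angle
  n <- 64L
  cc <- pixel_centers(n, 1)
  R <- sqrt(outer(cc^2, cc^2, `+`))
  expect_true(all(abs(img$data[R < 0.5] - cval * pi) < 1e-9))

  zero <- ect_sinogram(matrix(0, 8, d), uniform_angles(8), tt, 1)
  expect_true(all(backproject(zero)$data == 0))
})

test_that("positioning counter tallies one evaluation per pixel and view", {
  set.seed(11)
  fs <- random_fsino(20, 32)
  ctr <- op_counter()
  backproject(fs, grid_size = 32, counter = ctr)
  expect_identical(ctr$positioning_ops, 20 * 32^2)
  expect_true(ctr$multiplications > 0 && ctr$additions > 0 &&
                ctr$roundings > 0)
})

test_that("quarter-symmetry back projection equals the standard kernel", {
  set.seed(42)
  for (m in c(4L, 8L, 60L)) {
    fs <- random_fsino(m, 32)
    ctr_s <- op_counter(); ctr_q <- op_counter()
    a <- backproject(fs, counter = ctr_s)
    b <- backproject_symmetric(fs, counter = ctr_q)
    rng <- diff(range(a$data))
    expect_lt(max(abs(a$data - b$data)), 1e-9 * rng)
    expect_identical(ctr_q$positioning_ops / ctr_s$positioning_ops, 0.25)
    expect_identical(attr(b, "maps_computed"), as.integer(m / 4))
    expect_true(attr(b, "exact_quarter"))
  }
})

test_that("quarter-symmetry impulse case matches at the smallest M", {
  d <- 32L
  tt <- pixel_centers(d, 1)
  imp <- matrix(0, 4, d); imp[cbind(1:4, c(5, 12, 20, 28))] <- 1
  fs <- ect_sinogram(imp, uniform_angles(4), tt, 1)
  a <- backproject(fs)
  b <- backproject_symmetric(fs)
  expect_lt(max(abs(a$data - b$data)), 1e-12)
})

test_that("non-uniform view sets still reconstruct, flagged as not exact quarter", {
  set.seed(3)
  d <- 32L
  tt <- pixel_centers(d, 1)
  angles <- c(0, 10, 25, 40, 77, 132)  # M = 6, irregular
  fs <- ect_sinogram(matrix(stats::rnorm(6 * d), 6, d), angles, tt, 1)
  a <- backproject(fs)
  b <- backproject_symmetric(fs)
  expect_lt(max(abs(a$data - b$data)), 1e-9 * diff(range(a$data)))
  expect_false(attr(b, "exact_quarter"))
})

test_that("fbp_reconstruct is linear and its accelerated path is identical", {
  ph <- make_ellipse_phantom(disc_spec())
  sino <- project(ph, uniform_angles(60))
  rec1 <- fbp_reconstruct(sino)
  sino3 <- ect_sinogram(3 * sino$data, sino$angles_deg,
                        sino$detector_coords, sino$fov)
  rec3 <- fbp_reconstruct(sino3)
  expect_equal(rec3$image$data, 3 * rec1$image$data, tolerance = 1e-10)

  reca <- fbp_reconstruct(sino, accelerated = TRUE)
  expect_lt(max(abs(reca$image$data - rec1$image$data)),
            1e-9 * diff(range(rec1$image$data)))
  expect_identical(reca$counter$positioning_ops,
                   rec1$counter$positioning_ops / 4)
})

test_that("reconstruction error shrinks as views increase", {
  ph <- make_ellipse_phantom(disc_spec())
  err <- vapply(c(8L, 30L, 180L), function(m) {
    rmse(fbp_reconstruct(project(ph, uniform_angles(m)))$image, ph)
  }, numeric(1))
  expect_true(err[3] < err[2])
  expect_true(err[2] < err[1])
})

test_that("the ramp response has exactly zero DC on any view", {
  set.seed(5)
  d <- 64L
  # unpadded (circular) filtering: the zero DC bin makes every filtered
  # view sum to zero exactly, whatever the input
  for (rep in 1:3) {
    raw <- matrix(stats::runif(10 * d, 0, 4), 10, d)
    sino <- ect_sinogram(raw, uniform_angles(10), pixel_centers(d, 1), 1)
    f <- ramp_filter(sino, filter_spec(pad_factor = 1))
    expect_lt(max(abs(rowMeans(f$data))), 1e-8 * max(rowMeans(raw)))
  }
  # padded filtering keeps the property for constant views
  const <- ect_sinogram(matrix(7, 4, d), uniform_angles(4),
                        pixel_centers(d, 1), 1)
  f2 <- ramp_filter(const, filter_spec(pad_factor = 2))
  expect_lt(max(abs(rowMeans(f2$data))), 1e-8 * 7)
})

test_that("unfiltered back projection blurs and streaks; filtering removes both", {
  ph <- make_ellipse_phantom(disc_spec())
  sino <- project(ph, uniform_angles(180))
  unf <- backproject_unfiltered(sino)
  fil <- fbp_reconstruct(sino)$image
  expect_gt(rmse(unf, ph), rmse(fil, ph))

  # 8-view point source: radial streaks along the back projected rays
  n <- 64L
  m <- matrix(0, n, n); m[33, 33] <- 1
  ps <- ect_image(m, 1)
  star <- backproject_unfiltered(project(ps, uniform_angles(8)))
  contrast <- streak_contrast(star, (uniform_angles(8) + 90) %% 360)
  expect_gt(contrast, 2)

  zero <- ect_sinogram(matrix(0, 4, 64), uniform_angles(4),
                       pixel_centers(64, 1), 1)
  expect_true(all(backproject_unfiltered(zero)$data == 0))
})
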
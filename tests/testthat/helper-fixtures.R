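# Shared fixture builders for the test suite.

disc_spec <- function(grid_size = 64L, r = 0.5, intensity = 1) {
  phantom_spec(data.frame(cx = 0, cy = 0, a = r, b = r, rot_deg = 0,
                          intensity = intensity),
               grid_size = grid_size)
}

gaussian_blob <- function(grid_size = 64L, cx = 0.1, cy = -0.05,
                          sigma = 0.15, fov = 1.0) {
  cc <- pixel_centers(grid_size, fov)
  X <- matrix(cc, grid_size, grid_size, byrow = TRUE)
  Y <- matrix(-cc, grid_size, grid_size)
  ect_image(exp(-((X - cx)^2 + (Y - cy)^2) / (2 * sigma^2)), fov)
}

# random filtered-sinogram stand-in (arbitrary smooth-ish rows) for
# back projection equivalence properties
random_fsino <- function(m, d = 64L, fov = 1.0) {
  dt <- 2 * fov / d
  tt <- (seq_len(d) - (d + 1) / 2) * dt
  data <- matrix(stats::rnorm(m * d), m, d)
  ect_sinogram(data, uniform_angles(m), tt, fov)
}

# maximum angular streak contrast of an image at a given radius:
# ratio of the weakest on-streak peak to the strongest off-streak value
streak_contrast <- function(image, streak_deg, radius = 0.5,
                            halfwidth_deg = 3) {
  th_deg <- seq(0, 359.5, 0.5)
  th <- th_deg * pi / 180
  vals <- ectfbp:::bilinear_sample(image$data, radius * cos(th),
                                   radius * sin(th), image$fov)
  dirs <- c(streak_deg, (streak_deg + 180)) %% 360
  near <- function(a) abs(((th_deg - a + 180) %% 360) - 180) <= halfwidth_deg
  on_streak <- vapply(dirs, function(a) max(vals[near(a)]), numeric(1))
  gap <- diff(sort(unique(streak_deg %% 360)))
  mid <- (sort(unique(streak_deg %% 360)) + min(gap) / 2)
  mids <- c(mid, mid + 180) %% 360
  off_streak <- vapply(mids, function(a) max(vals[near(a)]), numeric(1))
  min(on_streak) / max(off_streak)
}

# run the scikit-image iradon reference on an ect_sinogram; returns the
# reconstructed matrix in the package's image orientation
oracle_fbp <- function(sino, grid_size = ncol(sino$data)) {
  py <- Sys.which("python")
  if (py == "") stop("python not found on PATH")
  script <- system.file("oracle", "iradon_oracle.py", package = "ectfbp")
  td <- tempfile("oracle")
  dir.create(td)
  on.exit(unlink(td, recursive = TRUE))
  sfile <- file.path(td, "sino.csv")
  afile <- file.path(td, "angles.txt")
  ofile <- file.path(td, "rec.csv")
  dt <- diff(sino$detector_coords[1:2])
  utils::write.table(sino$data / dt, sfile, sep = ",", row.names = FALSE,
                     col.names = FALSE)
  writeLines(format(sino$angles_deg, digits = 17), afile)
  status <- system2(py, c(script, sfile, afile, ofile))
  if (status != 0) stop("oracle reconstruction failed")
  as.matrix(utils::read.csv(ofile, header = FALSE))
}
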
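#' Rotated (view-frame) coordinates
#'
#' Coordinates of a point in the frame of a detector at view angle
#' `phi_deg`: `x_r` runs along the detector, `y_r` along the ray
#' direction. `x_r = x cos(phi) + y sin(phi)`,
#' `y_r = -x sin(phi) + y cos(phi)`; the rotation preserves radius.
#'
#' @param x,y physical coordinates (vectors recycle).
#' @param phi_deg view angle in degrees.
#' @return list with numeric `x_r` and `y_r`.
#' @examples
#' rotate_coords(1, 0, 90)  # x_r = 0, y_r = -1
#' @export
rotate_coords <- function(x, y, phi_deg) {
  phi <- phi_deg * pi / 180
  list(x_r = x * cos(phi) + y * sin(phi),
       y_r = -x * sin(phi) + y * cos(phi))
}

#' Sinogram container
#'
#' Line-integral projections `p_phi(x_r)` of an image: one row per view
#' angle, one column per detector bin. Detector coordinates are uniform,
#' symmetric about 0, with spacing equal to the image pixel spacing.
#'
#' @param data M x D numeric matrix of line integrals.
#' @param angles_deg strictly increasing view angles in `[0, 180)`.
#' @param detector_coords physical `x_r` positions of the D bins.
#' @param fov field-of-view half-width inherited from the source image.
#' @return An object of class `ect_sinogram`.
#' @export
ect_sinogram <- function(data, angles_deg, detector_coords, fov = 1.0) {
  if (!is.matrix(data)) data <- matrix(data, nrow = length(angles_deg))
  if (nrow(data) != length(angles_deg))
    stop("one sinogram row per view angle required", call. = FALSE)
  if (ncol(data) != length(detector_coords))
    stop("one sinogram column per detector bin required", call. = FALSE)
  if (length(angles_deg) < 1L) stop("at least one view required", call. = FALSE)
  if (length(detector_coords) < 2L)
    stop("at least two detector bins required", call. = FALSE)
  if (any(diff(angles_deg) <= 0))
    stop("'angles_deg' must be strictly increasing", call. = FALSE)
  if (abs(sum(detector_coords)) > 1e-9 * max(abs(detector_coords)))
    stop("'detector_coords' must be symmetric about 0", call. = FALSE)
  structure(list(data = data, angles_deg = angles_deg,
                 detector_coords = detector_coords, fov = fov),
            class = "ect_sinogram")
}

#' @export
print.ect_sinogram <- function(x, ...) {
  cat(sprintf("<ect_sinogram> %d views x %d bins, angles [%g, %g] deg, fov %g\n",
              nrow(x$data), ncol(x$data), min(x$angles_deg), max(x$angles_deg),
              x$fov))
  invisible(x)
}

#' @export
plot.ect_sinogram <- function(x, ...) {
  graphics::image(x$detector_coords, x$angles_deg, t(x$data),
                  xlab = "detector x_r", ylab = "view angle (deg)",
                  col = grDevices::gray.colors(256, start = 0, end = 1), ...)
  invisible(x)
}

#' Uniform view angles over a half turn
#'
#' `m` angles uniformly spaced on `[0, 180)` degrees, the standard
#' parallel-beam acquisition arc (views at `phi` and `phi + 180` are
#' redundant).
#'
#' @param m number of views.
#' @return numeric vector of length `m`.
#' @export
uniform_angles <- function(m) {
  if (m < 1L) stop("'m' must be >= 1", call. = FALSE)
  (seq_len(m) - 1L) * 180 / m
}

#' Forward projection (discrete Radon transform)
#'
#' Computes the sinogram of a square image: for each view angle, the
#' line integrals of the image along rays perpendicular to the detector,
#' sampled with bilinear interpolation at pixel-spacing steps along the
#' ray and scaled by the physical step, so a unit-intensity disc of
#' radius r projects to a central-bin value near the chord length 2r.
#'
#' @param image an [ect_image()].
#' @param angles_deg view angles in degrees, in `[0, 180)`; default 180
#'   uniformly spaced views.
#' @param n_detector_bins number of detector bins; default the grid size
#'   (detector spacing = pixel spacing).
#' @return an [ect_sinogram()].
#' @examples
#' disc <- make_ellipse_phantom(phantom_spec(
#'   data.frame(cx = 0, cy = 0, a = 0.5, b = 0.5, rot_deg = 0, intensity = 1)))
#' sino <- project(disc, uniform_angles(30))
#' @export
project <- function(image, angles_deg = uniform_angles(180),
                    n_detector_bins = nrow(image$data)) {
  stopifnot(inherits(image, "ect_image"))
  if (length(angles_deg) == 0L)
    stop("'angles_deg' must not be empty", call. = FALSE)
  if (any(angles_deg < 0 | angles_deg >= 180))
    stop("view angles must lie in [0, 180) degrees", call. = FALSE)
  n <- nrow(image$data)
  dx <- 2 * image$fov / n
  # detector bins span the field of view; for the default D = grid_size
  # the bin spacing equals the pixel spacing
  dt <- 2 * image$fov / n_detector_bins
  tt <- (seq_len(n_detector_bins) - (n_detector_bins + 1) / 2) * dt
  # integrate along y_r across the full image diagonal at pixel-spacing steps
  half_span <- image$fov * sqrt(2)
  n_steps <- ceiling(2 * half_span / min(dx, dt)) + 1L
  yr <- seq(-half_span, half_span, length.out = n_steps)
  step <- yr[2] - yr[1]
  D <- length(tt)
  Tm <- matrix(tt, D, n_steps)
  Ym <- matrix(yr, D, n_steps, byrow = TRUE)
  out <- matrix(0, length(angles_deg), D)
  for (k in seq_along(angles_deg)) {
    phi <- angles_deg[k] * pi / 180
    # invert Eq.-style rotation: (x_r, y_r) -> (x, y)
    X <- Tm * cos(phi) - Ym * sin(phi)
    Y <- Tm * sin(phi) + Ym * cos(phi)
    vals <- bilinear_sample(image$data, X, Y, image$fov)
    out[k, ] <- rowSums(matrix(vals, D, n_steps)) * step
  }
  ect_sinogram(out, angles_deg, tt, image$fov)
}

#' Numerical check of the central slice theorem
#'
#' The 1D Fourier transform of the projection at angle `phi` equals the
#' slice of the image's 2D Fourier transform through the origin at that
#' angle. This function computes both sides on matched frequency grids
#' (projection with detector spacing = pixel spacing, 2D DFT of the
#' image sampled along the slice by bilinear interpolation) and returns
#' the maximum relative modulus discrepancy over frequencies up to half
#' the Nyquist rate. Defined as 0 when both spectra vanish (zero image).
#'
#' @param image an [ect_image()]; intended for smooth, band-limited
#'   test objects.
#' @param phi_deg view angle in degrees.
#' @return nonnegative scalar, the residual.
#' @export
central_slice_residual <- function(image, phi_deg) {
  stopifnot(inherits(image, "ect_image"))
  n <- nrow(image$data)
  dx <- 2 * image$fov / n
  phi <- (phi_deg %% 180)

  p <- project(image, angles_deg = phi, n_detector_bins = n)$data[1, ]
  P1 <- abs(stats::fft(p)) * dx             # |P(rho_k)|, rho_k = k/(n*dx)

  F2 <- abs(stats::fft(image$data)) * dx^2  # |F(u, v)| on the DFT grid
  # center the spectrum: frequency index -n/2 .. n/2-1 along each axis
  sh <- function(m) {
    h <- floor(nrow(m) / 2)
    m[c((h + 1):nrow(m), 1:h), c((h + 1):ncol(m), 1:h)]
  }
  F2s <- sh(F2)
  freqs <- (seq_len(n) - 1 - floor(n / 2)) / (n * dx)
  f0 <- floor(n / 2) + 1          # index of frequency 0
  dfr <- freqs[2] - freqs[1]

  kmax <- floor(n / 4)            # half Nyquist
  ks <- 0:kmax
  rho <- ks / (n * dx)
  a <- phi * pi / 180
  u <- rho * cos(a)               # x-frequency -> columns
  v <- rho * sin(a)               # y-frequency; rows run along -v
  cf <- u / dfr + f0
  rf <- -v / dfr + f0
  c0 <- floor(cf); r0 <- floor(rf)
  wc <- cf - c0;   wr <- rf - r0
  at <- function(ri, ci) {
    ok <- ri >= 1 & ri <= n & ci >= 1 & ci <= n
    x <- numeric(length(ri)); x[ok] <- F2s[cbind(ri[ok], ci[ok])]; x
  }
  slice <- at(r0, c0) * (1 - wr) * (1 - wc) + at(r0, c0 + 1) * (1 - wr) * wc +
    at(r0 + 1, c0) * wr * (1 - wc) + at(r0 + 1, c0 + 1) * wr * wc

  ref <- max(slice, P1[ks + 1])
  if (ref == 0) return(0)
  max(abs(P1[ks + 1] - slice)) / ref
}
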
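#' Square ECT image
#'
#' Light container for a square 2D intensity grid with a physical field of
#' view. The image spans `[-fov, +fov]` in both axes. Storage is a plain
#' numeric matrix: column `j` maps to x (rightward), row `i` maps to y
#' (upward), so row 1 is the *top* of the image (largest y). Pixel centers
#' sit at `((k - (n+1)/2) * 2*fov/n)` for index `k`; this (row, column) to
#' (x, y) mapping is used everywhere in the package.
#'
#' @param data numeric matrix, square.
#' @param fov physical half-width of the field of view (> 0); the image
#'   spans `[-fov, fov]^2`. Default 1.
#' @return An object of class `ect_image`: a list with elements `data`
#'   (matrix) and `fov`.
#' @examples
#' img <- ect_image(matrix(0, 64, 64))
#' dim(img)
#' @export
ect_image <- function(data, fov = 1.0) {
  if (!is.matrix(data) || !is.numeric(data))
    stop("'data' must be a numeric matrix", call. = FALSE)
  if (nrow(data) != ncol(data))
    stop("image must be square", call. = FALSE)
  if (!is.numeric(fov) || length(fov) != 1L || !is.finite(fov) || fov <= 0)
    stop("'fov' must be a positive number", call. = FALSE)
  structure(list(data = data, fov = fov), class = "ect_image")
}

#' @export
dim.ect_image <- function(x) dim(x$data)

#' @export
print.ect_image <- function(x, ...) {
  n <- nrow(x$data)
  cat(sprintf("<ect_image> %d x %d, fov = %g, range [%g, %g]\n",
              n, n, x$fov, min(x$data), max(x$data)))
  invisible(x)
}

#' @param x an `ect_image`.
#' @param ... passed to [graphics::image()].
#' @rdname ect_image
#' @export
plot.ect_image <- function(x, ...) {
  n <- nrow(x$data)
  cc <- pixel_centers(n, x$fov)
  # image() draws rows along x; transpose and flip so x is right, y is up
  graphics::image(cc, cc, t(x$data[n:1, , drop = FALSE]),
                  xlab = "x", ylab = "y", asp = 1,
                  col = grDevices::gray.colors(256, start = 0, end = 1), ...)
  invisible(x)
}

#' Pixel-center coordinates
#'
#' Physical coordinates of pixel centers along one axis for an `n`-pixel
#' image spanning `[-fov, fov]`. Column `j` has x = `pixel_centers(n,fov)[j]`;
#' row `i` has y = `-pixel_centers(n,fov)[i]` (y decreases down rows).
#'
#' @param n grid size (pixels per side).
#' @param fov physical half-width.
#' @return numeric vector of length `n`, symmetric about 0.
#' @export
pixel_centers <- function(n, fov = 1.0) {
  (seq_len(n) - (n + 1) / 2) * (2 * fov / n)
}

#' Physical coordinate grids of an image
#'
#' @param image an `ect_image`.
#' @return list with matrices `x` and `y` giving the physical coordinates
#'   of every pixel center.
#' @keywords internal
coord_grids <- function(image) {
  n <- nrow(image$data)
  cc <- pixel_centers(n, image$fov)
  list(x = matrix(cc, n, n, byrow = TRUE),
       y = matrix(-cc, n, n, byrow = FALSE))
}

# Bilinear sample of matrix `m` (an image in the package convention, half
# width `fov`) at physical points (x, y); points outside the grid return 0.
# x, y may be vectors/matrices of equal length.
bilinear_sample <- function(m, x, y, fov) {
  n <- nrow(m)
  dx <- 2 * fov / n
  # fractional (row, col) positions; col 1 center at x = -fov + dx/2
  cf <- x / dx + (n + 1) / 2
  rf <- -y / dx + (n + 1) / 2
  c0 <- floor(cf); r0 <- floor(rf)
  wc <- cf - c0;   wr <- rf - r0

  val <- numeric(length(cf))
  at <- function(ri, ci) {
    ok <- ri >= 1 & ri <= n & ci >= 1 & ci <= n
    v <- numeric(length(ri))
    v[ok] <- m[cbind(ri[ok], ci[ok])]
    v
  }
  val <- at(r0, c0) * (1 - wr) * (1 - wc) +
    at(r0, c0 + 1) * (1 - wr) * wc +
    at(r0 + 1, c0) * wr * (1 - wc) +
    at(r0 + 1, c0 + 1) * wr * wc
  val
}

#' Root-mean-square error between two images
#'
#' @param a,b `ect_image` objects or numeric matrices of equal dimension.
#' @return nonnegative scalar.
#' @export
rmse <- function(a, b) {
  ma <- if (inherits(a, "ect_image")) a$data else a
  mb <- if (inherits(b, "ect_image")) b$data else b
  stopifnot(identical(dim(ma), dim(mb)))
  sqrt(mean((ma - mb)^2))
}
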
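#' Ellipse phantom specification
#'
#' Describes a synthetic test object built from additive ellipses, the
#' classic construction for tomography test images (a Shepp-Logan-style
#' head phantom is one instance, see [shepp_logan_spec()]). Pixel values
#' are the sum of the intensities of all ellipses whose interior contains
#' the pixel center; membership is evaluated at pixel centers with no
#' anti-aliasing, so the geometry is exact and testable.
#'
#' @param ellipses data frame (or coercible) with columns `cx`, `cy`
#'   (center), `a`, `b` (semi-axes), `rot_deg` (counterclockwise rotation),
#'   `intensity` (additive, may be negative). Zero rows give an all-zero
#'   phantom.
#' @param grid_size pixels per side, at least 8. Default 64, the standard
#'   gated-SPECT acquisition matrix.
#' @param fov physical half-width of the field of view. Default 1.
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(ellipses = NULL, grid_size = 64L, fov = 1.0) {
  grid_size <- as.integer(grid_size)
  if (is.na(grid_size) || grid_size < 8L)
    stop("'grid_size' must be an integer >= 8", call. = FALSE)
  if (!is.numeric(fov) || length(fov) != 1L || !is.finite(fov) || fov <= 0)
    stop("'fov' must be a positive number", call. = FALSE)
  cols <- c("cx", "cy", "a", "b", "rot_deg", "intensity")
  if (is.null(ellipses)) {
    ellipses <- as.data.frame(setNames(rep(list(numeric(0)), 6L), cols))
  } else {
    ellipses <- as.data.frame(ellipses)
    if (!all(cols %in% names(ellipses)))
      stop("'ellipses' needs columns: ", paste(cols, collapse = ", "),
           call. = FALSE)
    ellipses <- ellipses[cols]
    if (nrow(ellipses) > 0 && any(ellipses$a <= 0 | ellipses$b <= 0))
      stop("ellipse semi-axes must be positive", call. = FALSE)
  }
  structure(list(ellipses = ellipses, grid_size = grid_size, fov = fov),
            class = "phantom_spec")
}

#' Render an ellipse phantom to an image
#'
#' Deterministic: pixel (i, j) receives the sum of intensities of the
#' ellipses containing that pixel's center.
#'
#' @param spec a [phantom_spec()].
#' @return an [ect_image()] of size `grid_size`.
#' @examples
#' disc <- phantom_spec(data.frame(cx = 0, cy = 0, a = 0.5, b = 0.5,
#'                                 rot_deg = 0, intensity = 1))
#' img <- make_ellipse_phantom(disc)
#' img$data[32, 32]  # 1: center inside the disc
#' @export
make_ellipse_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  n <- spec$grid_size
  out <- matrix(0, n, n)
  if (nrow(spec$ellipses) == 0L) return(ect_image(out, spec$fov))
  cc <- pixel_centers(n, spec$fov)
  X <- matrix(cc, n, n, byrow = TRUE)
  Y <- matrix(-cc, n, n)
  for (k in seq_len(nrow(spec$ellipses))) {
    e <- spec$ellipses[k, ]
    th <- e$rot_deg * pi / 180
    dxp <- X - e$cx
    dyp <- Y - e$cy
    u <- (dxp * cos(th) + dyp * sin(th)) / e$a
    v <- (-dxp * sin(th) + dyp * cos(th)) / e$b
    out <- out + e$intensity * (u * u + v * v <= 1)
  }
  ect_image(out, spec$fov)
}

#' Shepp-Logan-style head phantom specification
#'
#' The standard ten-ellipse head phantom with the high-contrast
#' ("modified") gray levels commonly used to benchmark reconstruction
#' algorithms.
#'
#' @inheritParams phantom_spec
#' @return a `phantom_spec`.
#' @export
shepp_logan_spec <- function(grid_size = 64L, fov = 1.0) {
  e <- data.frame(
    cx  = c(0, 0, 0.22, -0.22, 0, 0, 0, -0.08, 0, 0.06),
    cy  = c(0, -0.0184, 0, 0, 0.35, 0.1, -0.1, -0.605, -0.605, -0.605),
    a   = c(0.69, 0.6624, 0.11, 0.16, 0.21, 0.046, 0.046, 0.046, 0.023, 0.023),
    b   = c(0.92, 0.874, 0.31, 0.41, 0.25, 0.046, 0.046, 0.023, 0.023, 0.046),
    rot_deg = c(90, 90, 72, 108, 90, 0, 0, 0, 0, 90),
    intensity = c(1, -0.8, -0.2, -0.2, 0.1, 0.1, 0.1, 0.1, 0.1, 0.1)
  )
  phantom_spec(e, grid_size = grid_size, fov = fov)
}

#' Annular myocardial phantom specification
#'
#' A short-axis left-ventricle stand-in: a uniform annulus of tracer
#' counts with optional angular "defect" sectors of reduced uptake,
#' emulating resting myocardial perfusion images. Pixels outside the
#' annulus (the ventricular cavity and the exterior) are 0.
#'
#' @param outer_radius,inner_radius annulus radii as fractions of `fov`,
#'   `0 < inner < outer <= 1`.
#' @param base_counts nonnegative intensity of normally perfused
#'   myocardium.
#' @param defects data frame (or coercible) with columns `start_deg`,
#'   `end_deg`, `scale`: each row scales the annulus intensity by
#'   `scale` (in `[0, 1]`) over polar angles `[start_deg, end_deg)`
#'   measured counterclockwise from the +x axis. Sectors may wrap
#'   through 0 when `start_deg > end_deg`.
#' @inheritParams phantom_spec
#' @return An object of class `myocardial_spec`.
#' @export
myocardial_spec <- function(outer_radius = 0.6, inner_radius = 0.35,
                            base_counts = 100, defects = NULL,
                            grid_size = 64L, fov = 1.0) {
  grid_size <- as.integer(grid_size)
  if (is.na(grid_size) || grid_size < 8L)
    stop("'grid_size' must be an integer >= 8", call. = FALSE)
  if (!(inner_radius > 0 && inner_radius < outer_radius && outer_radius <= 1))
    stop("need 0 < inner_radius < outer_radius <= 1", call. = FALSE)
  if (base_counts < 0) stop("'base_counts' must be nonnegative", call. = FALSE)
  cols <- c("start_deg", "end_deg", "scale")
  if (is.null(defects)) {
    defects <- as.data.frame(setNames(rep(list(numeric(0)), 3L), cols))
  } else {
    defects <- as.data.frame(defects)
    if (!all(cols %in% names(defects)))
      stop("'defects' needs columns: ", paste(cols, collapse = ", "),
           call. = FALSE)
    defects <- defects[cols]
    if (nrow(defects) > 0 && any(defects$scale < 0 | defects$scale > 1))
      stop("defect 'scale' must lie in [0, 1]", call. = FALSE)
  }
  structure(list(outer_radius = outer_radius, inner_radius = inner_radius,
                 base_counts = base_counts, defects = defects,
                 grid_size = grid_size, fov = fov),
            class = "myocardial_spec")
}

#' Render an annular myocardial phantom
#'
#' @param spec a [myocardial_spec()].
#' @param inner_radius optional override of the spec's inner radius (used
#'   by the gated series generator to "beat" the cavity).
#' @return an [ect_image()].
#' @examples
#' spec <- myocardial_spec(0.6, 0.4, base_counts = 100,
#'                         defects = data.frame(start_deg = 0, end_deg = 60,
#'                                              scale = 0.3))
#' img <- make_myocardial_phantom(spec)
#' @export
make_myocardial_phantom <- function(spec, inner_radius = NULL) {
  stopifnot(inherits(spec, "myocardial_spec"))
  r_in <- if (is.null(inner_radius)) spec$inner_radius else inner_radius
  if (!(r_in > 0 && r_in < spec$outer_radius))
    stop("inner radius must lie in (0, outer_radius)", call. = FALSE)
  n <- spec$grid_size
  cc <- pixel_centers(n, spec$fov)
  X <- matrix(cc, n, n, byrow = TRUE)
  Y <- matrix(-cc, n, n)
  R <- sqrt(X^2 + Y^2)
  annulus <- R >= r_in * spec$fov & R <= spec$outer_radius * spec$fov
  out <- matrix(0, n, n)
  out[annulus] <- spec$base_counts
  if (nrow(spec$defects) > 0L) {
    ang <- (atan2(Y, X) * 180 / pi) %% 360
    for (k in seq_len(nrow(spec$defects))) {
      d <- spec$defects[k, ]
      s <- d$start_deg %% 360
      e <- d$end_deg %% 360
      insec <- if (s <= e) ang >= s & ang < e else ang >= s | ang < e
      sel <- annulus & insec
      out[sel] <- spec$base_counts * d$scale
    }
  }
  ect_image(out, spec$fov)
}

#' Gated beating-heart phantom series
#'
#' Generates an ordered series of myocardial phantom frames over one
#' cardiac cycle. The cavity (inner) radius follows a cosine schedule
#' from `ed_inner_radius` at frame 1 (end-diastole) down to
#' `es_inner_radius` and back, the simplest smooth volume curve
#' consistent with a single systolic minimum per cycle. Eight frames per
#' cycle is the conventional gating used in clinical acquisition.
#'
#' @param spec a [myocardial_spec()]; its `inner_radius` is ignored in
#'   favor of the schedule.
#' @param n_frames frames per cardiac cycle (>= 2), default 8.
#' @param ed_inner_radius,es_inner_radius cavity radius (fraction of fov)
#'   at end-diastole / end-systole; must satisfy
#'   `0 < es < ed < outer_radius`.
#' @param heart_rate beats per minute.
#' @param slice_thickness physical depth used to convert 2D cavity area
#'   to a volume proxy (same length unit as `fov`).
#' @return An object of class `gated_series`: list with `frames` (list of
#'   [ect_image()]), `inner_radii`, `ed_index` (always 1), `es_index`,
#'   `heart_rate`, `slice_thickness`, `outer_radius`, `fov`.
#' @examples
#' g <- make_gated_series(myocardial_spec(), ed_inner_radius = 0.4,
#'                        es_inner_radius = 0.2)
#' length(g$frames)  # 8
#' @export
make_gated_series <- function(spec, n_frames = 8L,
                              ed_inner_radius = 0.4, es_inner_radius = 0.25,
                              heart_rate = 60, slice_thickness = 1.0) {
  stopifnot(inherits(spec, "myocardial_spec"))
  n_frames <- as.integer(n_frames)
  if (is.na(n_frames) || n_frames < 2L)
    stop("'n_frames' must be >= 2", call. = FALSE)
  if (!(es_inner_radius > 0 && es_inner_radius <= ed_inner_radius &&
        ed_inner_radius < spec$outer_radius))
    stop("need 0 < es_inner_radius <= ed_inner_radius < outer_radius",
         call. = FALSE)
  phase <- 2 * pi * (seq_len(n_frames) - 1L) / n_frames
  radii <- es_inner_radius +
    (ed_inner_radius - es_inner_radius) * (1 + cos(phase)) / 2
  frames <- lapply(radii, function(r) make_myocardial_phantom(spec, r))
  structure(list(frames = frames,
                 inner_radii = radii,
                 ed_index = 1L,
                 es_index = which.min(radii),
                 heart_rate = heart_rate,
                 slice_thickness = slice_thickness,
                 outer_radius = spec$outer_radius,
                 fov = spec$fov),
            class = "gated_series")
}

#' @export
print.gated_series <- function(x, ...) {
  cat(sprintf(
    "<gated_series> %d frames, %d x %d, HR %g bpm, ED frame %d, ES frame %d\n",
    length(x$frames), nrow(x$frames[[1]]$data), ncol(x$frames[[1]]$data),
    x$heart_rate, x$ed_index, x$es_index))
  invisible(x)
}

#' Add Poisson counting noise to an image
#'
#' Emission counts are Poisson distributed; each pixel is replaced by a
#' Poisson draw with mean equal to the pixel value. The draw is fully
#' determined by `seed` (the caller's RNG state is left untouched).
#'
#' @param image an [ect_image()] with nonnegative pixel values.
#' @param seed integer seed; identical seeds give bitwise-identical
#'   output.
#' @return an [ect_image()] of counts.
#' @export
add_poisson_noise <- function(image, seed) {
  stopifnot(inherits(image, "ect_image"))
  ect_image(poisson_draw(image$data, seed), image$fov)
}

# seeded Poisson draw on a plain matrix; restores the caller's RNG state
poisson_draw <- function(mat, seed) {
  if (any(mat < 0))
    stop("image must be nonnegative for Poisson noise", call. = FALSE)
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  matrix(stats::rpois(length(mat), lambda = mat) + 0.0, nrow = nrow(mat))
}
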
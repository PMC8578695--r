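#' Per-segment mean counts of a myocardial image
#'
#' Divides the annular region of interest into `n_segments` equal polar
#' sectors (segment s spans `[(s-1), s) * 360/n_segments` degrees
#' counterclockwise from the +x axis) and returns the mean pixel value
#' in each. The default 17 segments follows the conventional left
#' ventricle segment model; the count is configurable.
#'
#' @param image an [ect_image()] (typically a reconstructed perfusion
#'   slice).
#' @param n_segments number of polar sectors, >= 1. Default 17.
#' @param inner_radius,outer_radius annular region of interest as
#'   fractions of the field of view.
#' @return numeric vector of length `n_segments`.
#' @export
segment_mean_counts <- function(image, n_segments = 17L,
                                inner_radius = 0.25, outer_radius = 0.75) {
  stopifnot(inherits(image, "ect_image"))
  n_segments <- as.integer(n_segments)
  if (is.na(n_segments) || n_segments < 1L)
    stop("'n_segments' must be >= 1", call. = FALSE)
  n <- nrow(image$data)
  cc <- pixel_centers(n, image$fov)
  X <- matrix(cc, n, n, byrow = TRUE)
  Y <- matrix(-cc, n, n)
  R <- sqrt(X^2 + Y^2)
  ann <- R >= inner_radius * image$fov & R <= outer_radius * image$fov
  ang <- (atan2(Y, X) * 180 / pi) %% 360
  seg <- pmin(floor(ang / (360 / n_segments)) + 1L, n_segments)
  vapply(seq_len(n_segments),
         function(s) mean(image$data[ann & seg == s]),
         numeric(1))
}

#' Grade segmental perfusion
#'
#' Assigns each segment an ordinal perfusion grade from its uptake
#' relative to the maximally perfused segment: grade 0 (normal), 1
#' (decreased perfusion), 2 (substantially decreased perfusion), 3
#' (perfusion defect). The clinical scale names the four grades without
#' numeric thresholds; the default bands — relative uptake >= 70%
#' normal, 50-70% grade 1, 30-50% grade 2, < 30% grade 3, all bands
#' half-open at the top — are a documented, configurable convention.
#'
#' @param segment_counts nonnegative per-segment mean counts.
#' @param reference reference uptake (> 0); default the maximal segment.
#' @param bands decreasing thresholds `c(b1, b2, b3)` separating grades
#'   0/1, 1/2, 2/3 on the relative-uptake scale.
#' @return An object of class `segment_grades`: integer vector of grades
#'   with attributes `uptake` (the relative uptake) and `bands`.
#' @examples
#' grade_perfusion(c(100, 65, 25), reference = 100)  # grades 0, 1, 3
#' @export
grade_perfusion <- function(segment_counts, reference = max(segment_counts),
                            bands = c(0.70, 0.50, 0.30)) {
  if (!is.numeric(reference) || length(reference) != 1L || reference <= 0)
    stop("'reference' must be a positive scalar", call. = FALSE)
  if (any(segment_counts < 0))
    stop("'segment_counts' must be nonnegative", call. = FALSE)
  if (length(bands) != 3L || any(diff(bands) >= 0))
    stop("'bands' must be 3 decreasing thresholds", call. = FALSE)
  u <- segment_counts / reference
  g <- ifelse(u >= bands[1], 0L,
              ifelse(u >= bands[2], 1L,
                     ifelse(u >= bands[3], 2L, 3L)))
  structure(as.integer(g), uptake = u, bands = bands,
            class = "segment_grades")
}

#' @export
print.segment_grades <- function(x, ...) {
  cat("<segment_grades>", paste(unclass(x), collapse = " "), "\n")
  invisible(x)
}

#' Grade systolic wall thickening
#'
#' Ordinal 0-3 grade of the percent systolic wall thickening: > 25%
#' normal (grade 0), 10-24% reduced (grade 1), 9-10% substantially
#' reduced (grade 2), < 9% substantially reduced or akinetic (grade 3).
#' Band edges are half-open — `[10, 25)` is grade 1 and `[9, 10)` grade
#' 2 — so every percentage maps to exactly one grade; `>25` is read as
#' `>= 25` belonging to grade 0's complement boundary, i.e. grade 0 is
#' `thickening_pct >= 25`.
#'
#' @param thickening_pct finite percent thickening (vectorized).
#' @param edges decreasing band edges `c(e0, e1, e2)`; grade 0 at or
#'   above `e0`, grade 1 in `[e1, e0)`, grade 2 in `[e2, e1)`, grade 3
#'   below `e2`. Default `c(25, 10, 9)`.
#' @return integer grades in 0-3.
#' @examples
#' grade_wall_thickening(c(30, 15, 5))  # 0, 1, 3
#' @export
grade_wall_thickening <- function(thickening_pct, edges = c(25, 10, 9)) {
  if (any(!is.finite(thickening_pct)))
    stop("'thickening_pct' must be finite", call. = FALSE)
  if (length(edges) != 3L || any(diff(edges) >= 0))
    stop("'edges' must be 3 decreasing values", call. = FALSE)
  as.integer(ifelse(thickening_pct >= edges[1], 0L,
                    ifelse(thickening_pct >= edges[2], 1L,
                           ifelse(thickening_pct >= edges[3], 2L, 3L))))
}

#' Summed segmental score
#'
#' Aggregates per-segment ordinal grades into the summary used in
#' perfusion reporting: the summed score (total of all grades), the
#' number of abnormal segments (grade > 0), and the per-grade tallies.
#' By construction `total = n1 + 2 n2 + 3 n3`.
#'
#' @param grades integer grades in 0-3 (a [grade_perfusion()] result or
#'   plain vector).
#' @return list with `total_score`, `abnormal_count`, and
#'   `per_grade_counts` (named vector for grades 1, 2, 3).
#' @examples
#' summed_score(c(1, 2, 3, 0))  # total 6, abnormal 3
#' @export
summed_score <- function(grades) {
  g <- as.integer(unclass(grades))
  if (any(is.na(g)) || any(g < 0L | g > 3L))
    stop("grades must be integers in 0..3", call. = FALSE)
  per <- vapply(1:3, function(k) sum(g == k), integer(1))
  names(per) <- as.character(1:3)
  list(total_score = sum(g),
       abnormal_count = sum(g > 0L),
       per_grade_counts = per)
}

#' Gated function parameters from per-frame volumes
#'
#' The arithmetic core of gated functional analysis: end-diastolic
#' volume is the frame maximum, end-systolic the minimum, and
#' `SV = EDV - ESV`, `EF = SV / EDV * 100`, `CO = SV * HR / 1000`
#' (volumes in mL, CO in L/min).
#'
#' @param volumes per-frame volumes (mL), length >= 2.
#' @param heart_rate beats per minute.
#' @return An object of class `cardiac_function`: list with `EDV`,
#'   `ESV`, `SV`, `EF` (percent), `CO` (L/min), `heart_rate`,
#'   `volumes`, `ed_index`, `es_index`.
#' @examples
#' function_params(c(100, 90, 70, 50, 55, 70, 85, 95), heart_rate = 60)
#' @export
function_params <- function(volumes, heart_rate = 60) {
  if (length(volumes) < 2L)
    stop("need at least 2 frame volumes", call. = FALSE)
  if (any(!is.finite(volumes)) || any(volumes < 0))
    stop("volumes must be finite and nonnegative", call. = FALSE)
  edv <- max(volumes)
  esv <- min(volumes)
  if (edv <= 0)
    stop("all-zero volumes: ejection fraction undefined", call. = FALSE)
  sv <- edv - esv
  structure(list(EDV = edv, ESV = esv, SV = sv,
                 EF = sv / edv * 100,
                 CO = sv * heart_rate / 1000,
                 heart_rate = heart_rate,
                 volumes = volumes,
                 ed_index = which.max(volumes),
                 es_index = which.min(volumes)),
            class = "cardiac_function")
}

#' @export
print.cardiac_function <- function(x, ...) {
  cat(sprintf(paste0("<cardiac_function> EDV %.1f mL, ESV %.1f mL, ",
                     "SV %.1f mL, EF %.1f%%, CO %.2f L/min (HR %g bpm)\n"),
              x$EDV, x$ESV, x$SV, x$EF, x$CO, x$heart_rate))
  invisible(x)
}

# Cavity area (physical units^2) of one frame within the circular ROI.
# method "deficit": integrate the count deficit (1 - v/ref) clamped to
# [0, 1] over the ROI — exact for binary phantom renderings and
# sub-pixel accurate on smooth reconstructions, because partially
# blurred rim pixels contribute fractionally. The myocardial reference
# level is the median of pixels above half the frame maximum, robust to
# reconstruction overshoot. method "threshold": binary count of pixels
# below cavity_threshold x the frame maximum.
cavity_area <- function(image, cavity_threshold, roi_radius,
                        method = c("deficit", "threshold")) {
  method <- match.arg(method)
  n <- nrow(image$data)
  cc <- pixel_centers(n, image$fov)
  X <- matrix(cc, n, n, byrow = TRUE)
  Y <- matrix(-cc, n, n)
  inside <- sqrt(X^2 + Y^2) < roi_radius * image$fov
  px_area <- (2 * image$fov / n)^2
  v <- image$data
  if (method == "threshold") {
    ref <- max(v)
    return(sum(inside & v < cavity_threshold * ref) * px_area)
  }
  ref <- stats::median(v[v > 0.5 * max(v)])
  w <- pmin(pmax(v / ref, 0), 1)
  sum((1 - w)[inside]) * px_area
}

#' Gated function parameters from a gated image series
#'
#' Measures the ventricular cavity on every frame, converts cavity area
#' to a volume proxy via `slice_thickness`, and derives EDV/ESV/SV/EF/CO
#' with [function_params()]. The default `"deficit"` measurement
#' integrates the count deficit `1 - v/ref` (clamped to `[0, 1]`, `ref`
#' the myocardial plateau level) over the region of interest: on binary
#' phantom renderings this equals the pixel count below threshold, while
#' on smooth reconstructions the partially blurred rim pixels contribute
#' fractionally, making the area sub-pixel accurate. The `"threshold"`
#' method is a plain binary count of pixels below `cavity_threshold`
#' times the frame maximum. Because the volume proxy is area x
#' thickness, absolute volumes depend on the calibration of
#' `slice_thickness`; ratios such as EF do not. The deficit measure
#' assumes uniform uptake in the ROI myocardium; perfusion defects
#' inside the ROI would inflate the cavity estimate.
#'
#' @param series a `gated_series` (see [make_gated_series()]); frames
#'   may be phantom renderings or reconstructions.
#' @param cavity_threshold fraction in (0, 1) of the frame's maximal
#'   counts below which a pixel counts as cavity (`"threshold"` method).
#'   Default 0.5.
#' @param roi_radius outer search radius as a fraction of the field of
#'   view. Defaults to halfway between the end-diastolic inner radius
#'   and the annulus outer radius when the series carries its radii
#'   (keeping the blurred epicardial rim out of the ROI), else the
#'   outer radius.
#' @param method `"deficit"` (default) or `"threshold"`.
#' @return a `cardiac_function` object (volumes in
#'   `fov-units^2 x slice_thickness`, nominally mL).
#' @export
compute_function_params <- function(series, cavity_threshold = 0.5,
                                    roi_radius = NULL,
                                    method = c("deficit", "threshold")) {
  stopifnot(inherits(series, "gated_series"))
  method <- match.arg(method)
  if (!(cavity_threshold > 0 && cavity_threshold < 1))
    stop("'cavity_threshold' must lie in (0, 1)", call. = FALSE)
  if (all(vapply(series$frames, function(f) max(abs(f$data)) == 0, logical(1))))
    stop("all-zero frames: ejection fraction undefined", call. = FALSE)
  if (is.null(roi_radius)) {
    roi_radius <- if (!is.null(series$inner_radii))
      (max(series$inner_radii) + series$outer_radius) / 2
    else series$outer_radius
  }
  vols <- vapply(series$frames,
                 function(f) cavity_area(f, cavity_threshold, roi_radius,
                                         method) * series$slice_thickness,
                 numeric(1))
  function_params(vols, heart_rate = series$heart_rate)
}

#' Reconstruct every frame of a gated series
#'
#' Convenience wrapper running forward projection and filtered back
#' projection on each frame, returning a new `gated_series` of
#' reconstructed images with the same gating metadata.
#'
#' @param series a `gated_series` of phantom (or measured) frames.
#' @param angles_deg view angles for the forward projection.
#' @param spec a [filter_spec()].
#' @param accelerated use the quarter-symmetry back projection.
#' @param n_detector_bins detector bins for the acquisition; frames may
#'   be rendered finer than the acquisition matrix, in which case this
#'   sets the measured resolution. Default 64.
#' @param grid_size reconstruction grid; default the detector bin count.
#' @return a `gated_series` of reconstructed frames.
#' @export
reconstruct_series <- function(series, angles_deg = uniform_angles(90),
                               spec = filter_spec(), accelerated = FALSE,
                               n_detector_bins = 64L,
                               grid_size = n_detector_bins) {
  stopifnot(inherits(series, "gated_series"))
  frames <- lapply(series$frames, function(f) {
    fbp_reconstruct(project(f, angles_deg,
                            n_detector_bins = n_detector_bins),
                    spec = spec, grid_size = grid_size,
                    accelerated = accelerated)$image
  })
  out <- series
  out$frames <- frames
  out
}
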
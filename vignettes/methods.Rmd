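---
title: "Methods: FBP reconstruction and gated cardiac quantification"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: FBP reconstruction and gated cardiac quantification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ectfbp)
```

`ectfbp` implements the computational chain of gated myocardial
perfusion ECT on synthetic phantoms: forward projection, ramp-filtered
back projection with a quarter-symmetry positioning acceleration, an
analytic operation-count model, and segmental perfusion / gated function
quantification. This vignette records the model, its assumptions, and
the numerical and design choices, so that what the test suite does and
does not demonstrate is explicit.

## Geometry and conventions

Images are square matrices spanning `[-fov, fov]^2` with `fov = 1`
(dimensionless; physical calibration is deferred to `slice_thickness`).
Column `j` maps to x (rightward), row `i` to y (upward, so row 1 is the
top); pixel centers sit at `(k - (n+1)/2) * 2*fov/n`. All geometry uses
pixel-center sampling with no anti-aliasing: membership of a pixel in an
ellipse or annulus is decided at its center, which keeps the rendered
geometry exact and testable at the cost of hard edges (see the EF
discussion below). The default grid is 64 x 64, the standard gated-SPECT
acquisition matrix, and gated series default to 8 frames per cardiac
cycle, the standard ECG gating.

View angles live in `[0, 180)` degrees (a parallel-beam view at
`phi + 180` duplicates the view at `phi`), degrees externally and
radians internally. The detector has `D` uniform bins symmetric about
zero spanning the field of view, so with the default `D = grid_size`
the bin spacing equals the pixel spacing. Objects are assumed to lie
inside the inscribed circle of the field of view; mass outside the
detector span would be truncated.

## Forward projection and the central-slice check

`project()` computes line integrals by sampling the image with bilinear
interpolation at pixel-spacing steps along each ray and scaling by the
step, so a unit disc of radius r projects to a central value near the
chord length 2r and the per-view mass equals the image integral to
discretization accuracy. This ray-driven scheme was chosen over
rotate-and-sum because it needs no intermediate resampled image and
supports a detector coarser than the rendering grid (used by the gated
study below).

`central_slice_residual()` verifies the projection theorem numerically:
it compares the modulus of the 1D DFT of a projection (scaled by the bin
spacing to approximate the continuous transform) with the image's 2D DFT
interpolated along the slice through the origin at the view angle.
Frequencies are compared up to half Nyquist, where both estimates are
well conditioned; the residual is the maximum discrepancy relative to
the spectrum peak and is defined as 0 when both spectra vanish. On a
smooth Gaussian blob the residual stays below 0.05 at all angles; it is
interpolation- and leakage-dominated, so hard-edged phantoms (slowly
decaying spectra) are not suitable inputs for this diagnostic.

## Ramp filtering

Each view is filtered independently in the frequency domain: extend to
`pad_factor * D` samples, multiply the DFT by `|rho|` (cycles per unit
length), inverse transform, crop. The scaling approximates
`g(x_r) = \int |rho| P(rho) e^{2 pi i rho x_r} d rho`, so back
projection with the `pi/M` view weight reconstructs on the intensity
scale of the original image — no post hoc normalization is needed and
reference implementations can be compared directly.

Two numerical choices matter:

* **Padding** (`pad_factor`, default 2) suppresses circular-convolution
  wrap-around. The pad region is filled with a linear taper from the
  last sample back to the first rather than zeros. For physical
  projections, which vanish at the detector edges, this *is*
  zero-padding; its advantage is that a constant view remains constant
  after padding, so the zero DC bin annihilates it exactly, which makes
  the DC-annihilation property testable at machine precision instead of
  up to an edge artifact.
* **Windows and cutoff.** The classical derivation specifies a pure
  `|rho|` response, which is the default. Hamming
  (`0.54 + 0.46 cos(pi rho / rho_c)`) and Shepp-Logan
  (`sinc(rho / 2 rho_c)`) apodizations are exposed for noisy data, and
  `cutoff` (fraction of Nyquist, default 1) truncates the passband.
  Apodization trades resolution for noise suppression; none of the
  shipped tests require it.

## Back projection and the quarter-symmetry acceleration

`backproject()` evaluates, for every pixel and view, the positioning map
`x_r = x cos(phi) + y sin(phi)`, samples the filtered view there by
linear interpolation between detector bins (nearest-neighbour purity was
considered and rejected: linear interpolation matches standard
implementations and the equivalence tests), accumulates, and scales by
`pi/M`. Rays falling outside the detector contribute zero. The
instrumented `op_counter()` tallies one positioning operation per
(pixel, view), plus multiplications, additions, and index roundings for
the trigonometric products and interpolation; the counter separates
these classes because published cost models are ambiguous about whether
interpolation arithmetic is included.

`backproject_symmetric()` exploits three exact identities of the
positioning map on a centered square grid:

| view angle | base map | grid operation |
|---|---|---|
| `phi + 90` | `phi` | transpose of column-flipped map |
| `90 - phi` | `phi` | negated transpose |
| `180 - phi` | `phi` | column flip |

Maps are computed trigonometrically only for azimuths in `(0, 45]`; the
0 and 90 degree maps are the pixel coordinate grids themselves (x and y
need no positioning computation); every other view reuses a computed map
through the table above. For `M` uniform views with `M` divisible by 4
exactly `ceiling(M/4)` maps are computed, so the positioning counter
ratio against the standard kernel is exactly 1/4; the identities are
exact up to floating-point trigonometry, and the equivalence tests bound
the image difference at `1e-9` of the dynamic range. For view sets that
are not uniform multiples of 4 the provider still works — it computes
whatever base maps are needed and the result carries
`exact_quarter = FALSE` — rather than falling back to per-view
positioning.

The analytic model is kept strictly separate from the live counters:
`table3_counts()` gives the closed-form per-class counts (traditional
`3MN, 2MN^2, MN^2`; accelerated `3N ceil(M/4)/2, N^2 ceil(M/4),
N^2 ceil(M/4)/2`), whose ratio is exactly 1/8 per class when 4 divides
M, while the instrumented positioning ratio is 1/4. The two accountings
measure different things (arithmetic classes versus positioning-map
evaluations) and `counters_vs_model()` reports them side by side without
summing them. `A_of_N()` is taken as exactly `N log2 N` (unit constant):
the filtering cost formulas use `A` algebraically, and every ratio
reported downstream is independent of the constant.

## Phantoms

The generators emulate the study objects, not scanner physics:

* `make_ellipse_phantom()` renders additive ellipse sets
  (`shepp_logan_spec()` ships the standard ten-ellipse head phantom with
  high-contrast gray levels) for reconstruction benchmarking.
* `make_myocardial_phantom()` renders a short-axis left ventricle as a
  uniform annulus (default outer radius 0.6, inner 0.35 of the field of
  view, 100 counts) with optional angular defect sectors whose uptake is
  scaled into `[0, 1]` — a resting perfusion slice with transmural
  defects.
* `make_gated_series()` beats the cavity radius along a cosine schedule
  from the end-diastolic radius (frame 1) to the end-systolic radius and
  back. The cosine is the simplest smooth curve with one systolic
  minimum per cycle; real volume curves are asymmetric (rapid ejection,
  slower filling), which matters for none of the max/min-based
  parameters.
* `add_poisson_noise()` replaces pixels by Poisson draws with the pixel
  value as mean — emission counting statistics — fully determined by an
  integer seed.

What the phantoms do **not** model: attenuation, scatter, collimator
response, tracer kinetics, 3D geometry, or patient anatomy. Passing
tests therefore demonstrate the correctness of the reconstruction and
scoring arithmetic, not clinical performance on real scans.

## Cardiac quantification

`segment_mean_counts()` divides the annular region of interest into
equal polar sectors (default 17, the conventional segment count; the
generator's sector geometry is configurable because segment models vary)
and `grade_perfusion()` grades relative uptake `u = counts/reference`
through configurable bands. The clinical scale names four grades without
numeric thresholds, so the defaults — `u >= 0.70` grade 0, `[0.50,
0.70)` grade 1, `[0.30, 0.50)` grade 2, below grade 3 — are a documented
convention, half-open so every uptake maps to one grade.
`grade_wall_thickening()` uses the published bands with two resolutions:
the grade-2 band "10% to 9%" is read as `[9, 10)` (the inverted order is
a typographical slip), and the gap between ">25" and "10–24" is closed
by assigning `[10, 25)` to grade 1 and `[25, Inf)` to grade 0.

`compute_function_params()` measures the cavity on each frame inside a
circular search region (by default halfway between the end-diastolic
inner radius and the outer radius, keeping the blurred epicardial rim
outside). The default measurement integrates the count *deficit*
`1 - v/ref` (clamped to `[0, 1]`, `ref` estimated as the median of
pixels above half the frame maximum) over the region: on binary phantom
renderings this equals threshold counting, while on reconstructions the
partially blurred rim pixels contribute fractionally, making the area
estimate sub-pixel accurate. A plain threshold count (default 0.5 of the
frame maximum) is available as `method = "threshold"`. Volumes are
`area x slice_thickness` proxies; absolute EDV/ESV/CO therefore depend
on calibration, and only ratio quantities (EF) are asserted in tests.
The deficit measure assumes uniform uptake in the region-of-interest
myocardium; a perfusion defect inside the ROI would inflate the cavity
estimate, so gated function phantoms are generated without defects.

For the end-to-end EF study the phantom is rendered at 256 x 256 —
emulating continuous anatomy — and *acquired* at 64 detector bins and
90 views, then reconstructed at 64 x 64. Rendering at the acquisition
matrix instead would quantize the cavity boundary at the object level
(a 0.25-radius cavity is only 8 pixels at grid 64) and dominate the EF
error with rendering artifacts unrelated to the reconstruction under
test. With the fine-rendered object, recovered EF stays within about
1 percentage point of the analytic value `1 - (r_ES/r_ED)^2` across
ED/ES radius pairs spanning EF 44-89%.

## Degenerate inputs and error handling

Zero images project to zero sinograms and reconstruct to zero; the
central-slice residual of a zero image is defined as 0. A gated series
with equal ED and ES radii has identical frames and EF exactly 0;
all-zero frames raise an undefined-EF error rather than returning 0/0.
Grading rejects nonpositive references and out-of-range grades;
`A_of_N()` rejects lengths that are not powers of two. File readers
validate rectangularity and numeric content and report the offending row
and column. The 16-bit raster path uses TIFF; PNG output is 8-bit with
the scale recorded in a JSON sidecar, and CSV is the lossless format.

## Problem sizes in the shipped tests

The suite runs on 64 x 64 grids (32 for pipeline round trips), view
counts from 4 to 180, 20-case equivalence sweeps, and five ED/ES radius
pairs with 8 gates each — sizes at which every property is measurable in
seconds while remaining at the study's native matrix scale. The
independent reconstruction reference in the oracle tests is
scikit-image's `iradon`, called through the system `python` on an
identical sinogram (converted to pixel-unit line integrals; geometric
conventions verified empirically in the test helper).

## Known limitations

* Parallel-beam 2D geometry only; dual-head orbit parameters are
  metadata, not a distinct geometry.
* No attenuation/scatter/resolution modeling, no iterative
  reconstruction.
* The operation-count model and the live counters are deliberately not
  reconciled into a single total: filtering costs and back projection
  costs are reported separately, as their composition is
  implementation-dependent.
* Absolute volumes are proxies; only EF-like ratios are validated.
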
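# ectfbp

Filtered back projection (FBP) reconstruction and gated cardiac
quantification for emission computed tomography (ECT), in pure R.

Gated myocardial perfusion SPECT measures the uptake of a radiotracer in
the left-ventricular wall from gamma-camera projections. Reconstructing
the tracer distribution, grading segmental perfusion, and deriving gated
function parameters (EDV, ESV, SV, EF, CO) are the computational core of
that examination. `ectfbp` implements this chain end to end on synthetic
myocardial phantoms, so every stage can be tested quantitatively without
scanner data: phantom generation, forward projection (discrete Radon
transform), ramp filtering, standard / unfiltered / symmetry-accelerated
back projection with instrumented operation counters, an analytic
operation-count model, and the cardiac scoring layer.

## The algorithms

**Forward projection.** For a view angle φ the detector coordinate of a
point is x_r = x cos φ + y sin φ. The sinogram row p_φ(x_r) is the line
integral of the image along rays of constant x_r, computed by bilinear
sampling at pixel-spacing steps.

**Central slice theorem.** The 1D Fourier transform of p_φ equals the
slice of the image's 2D Fourier transform through the origin at angle φ
(frequencies w₁ = 2πρ cos φ, w₂ = 2πρ sin φ). `central_slice_residual()`
checks this numerically against an independent 2D-FFT oracle.

**Filtered back projection.** Three steps: (1) filter each view with the
ramp response |ρ| (optionally Hamming/Shepp-Logan windowed, truncated at
a Nyquist-fraction cutoff), giving g(x_r, φ) = p ∗ h; (2) for each view
smear g back over the image along x_r = r cos(θ − φ); (3) integrate over
views on [0, π) with weight π/M. Unfiltered back projection is kept as
the star-artifact reference.

**Quarter-symmetry acceleration.** Because
x_r(x, y; φ+90°) = x_r(y, −x; φ), x_r(x, y; 90°−φ) = x_r(y, x; φ), and
x_r(x, y; 180°−φ) = x_r(−x, y; φ) on a centered grid, positioning maps
need trigonometric evaluation for only ⌈M/4⌉ azimuths; the rest are grid
reflections/transposes. `backproject_symmetric()` produces images
identical to `backproject()` while its positioning counter reads
⌈M/4⌉ · grid², a ratio of 1/4. The analytic model (`table3_counts()`)
puts the per-class operation ratio new/traditional at exactly 1/8 for
every M divisible by 4: traditional {3MN, 2MN², MN²} versus new
{3N⌈M/4⌉/2, N²⌈M/4⌉, N²⌈M/4⌉/2} for multiplications, additions, and
roundings.

**Cardiac layer.** Segmental relative uptake is graded 0–3 (normal →
perfusion defect), wall thickening percent is graded 0–3 (>25% normal;
[10, 25) reduced; [9, 10) substantially reduced; <9 akinetic), summed
scores tally `total = n₁ + 2n₂ + 3n₃`, and gated series yield
EDV = max frame volume, ESV = min, SV = EDV − ESV, EF = SV/EDV × 100,
CO = SV × HR / 1000.

## Worked example

A 64×64 annular myocardial phantom with one hypoperfused sector
(0°–60°, 30% of normal uptake), projected at 180 views, reconstructed
with the accelerated FBP, and scored over 6 sectors:

```r
library(ectfbp)
ph   <- make_myocardial_phantom(myocardial_spec(
          defects = data.frame(start_deg = 0, end_deg = 60, scale = 0.3)))
sino <- project(ph, uniform_angles(180))
rec  <- fbp_reconstruct(sino, accelerated = TRUE)
rec
#> <ect_recon> 64 x 64 from 180 views, filter ramp (quarter-symmetry positioning)
#> <op_counter> positioning 184320, multiplications 1.8432e+06, additions 921600, roundings 737280

seg <- segment_mean_counts(rec$image, n_segments = 6,
                           inner_radius = 0.35, outer_radius = 0.6)
round(seg, 1)
#> [1] 28.1 92.6 93.4 93.5 93.5 92.7
grade_perfusion(seg)
#> <segment_grades> 3 0 0 0 0 0
summed_score(grade_perfusion(seg))$total_score
#> [1] 3
```

The defect sector reads 28.1 counts against ~93 elsewhere — relative
uptake 0.30, grade 3 (perfusion defect); the five normal sectors grade
0, so the summed score is 3. Positioning operations: 184320 =
⌈180/4⌉ · 64², a quarter of the standard kernel's 180 · 64². The
analytic model gives the per-class ratio:

```r
unlist(complexity_ratio(360, 64))[1:3]
#> multiplications       additions       roundings
#>           0.125           0.125           0.125
```

A beating phantom (8 gates, cavity radius 0.40 → 0.20, area ratio 4:1)
yields the function parameters; volumes are area × slice-thickness
proxies, so the calibrated quantity is the ejection fraction:

```r
gated <- make_gated_series(myocardial_spec(), ed_inner_radius = 0.4,
                           es_inner_radius = 0.2)
compute_function_params(gated)
#> <cardiac_function> EDV 0.5 mL, ESV 0.1 mL, SV 0.4 mL, EF 76.3%, CO 0.02 L/min (HR 60 bpm)
```

(the analytic EF for a 4:1 cavity-area ratio is 75%).

## Command line

A thin CLI over the package functions is installed with the package:

```sh
CLI=$(Rscript -e 'cat(system.file("cli/ectfbp.R", package = "ectfbp"))')
Rscript "$CLI" phantom --kind myocardial --grid 64 --defect 0,60,0.3 --out out/
Rscript "$CLI" project --in out/phantom.csv --angles 180 --out out/sino.csv
Rscript "$CLI" reconstruct --sino out/sino.csv --accelerated --out out/rec.csv --counters out/ctr.json
Rscript "$CLI" complexity --M 360 --N 64 --out out/complexity.json
Rscript "$CLI" run --out out/full --seed 7
```

Exit codes: 0 ok, 2 usage, 3 data format, 4 numeric failure.
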
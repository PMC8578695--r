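test_that("perfusion grading maps relative uptake through the default bands", {
  g <- grade_perfusion(c(100, 80, 69.9, 50, 49.9, 30, 10), reference = 100)
  expect_identical(as.integer(g), c(0L, 0L, 1L, 1L, 2L, 2L, 3L))
  expect_identical(as.integer(grade_perfusion(1, reference = 1)), 0L)
  expect_identical(as.integer(grade_perfusion(0.1, reference = 1)), 3L)
  expect_error(grade_perfusion(c(1, 2), reference = 0), "reference")
  expect_error(grade_perfusion(c(-1, 2), reference = 1), "nonnegative")
})

test_that("perfusion grade never decreases as uptake falls", {
  u <- seq(1, 0, by = -0.01)
  g <- as.integer(grade_perfusion(u, reference = 1))
  expect_true(all(diff(g) >= 0))
  expect_identical(range(g), c(0L, 3L))
})

test_that("wall thickening grading follows the clinical bands", {
  expect_identical(grade_wall_thickening(30), 0L)
  expect_identical(grade_wall_thickening(15), 1L)
  expect_identical(grade_wall_thickening(5), 3L)
  # band edges: [25, inf) -> 0, [10, 25) -> 1, [9, 10) -> 2, below -> 3
  expect_identical(grade_wall_thickening(c(25, 24.9, 10, 9.9, 9, 8.9)),
                   c(0L, 1L, 1L, 2L, 2L, 3L))
  # monotone: higher thickening never gives a higher grade
  pct <- seq(-5, 40, by = 0.5)
  expect_true(all(diff(grade_wall_thickening(pct)) <= 0))
  expect_error(grade_wall_thickening(NaN), "finite")
})

test_that("summed score decomposes into per-grade tallies", {
  s <- summed_score(c(1, 2, 3, 0))
  expect_identical(s$total_score, 6L)
  expect_identical(s$abnormal_count, 3L)
  expect_identical(unname(s$per_grade_counts), c(1L, 1L, 1L))

  z <- summed_score(rep(0, 17))
  expect_identical(z$total_score, 0L)
  expect_identical(z$abnormal_count, 0L)

  set.seed(13)
  for (rep in 1:20) {
    g <- sample(0:3, size = sample(3:40, 1), replace = TRUE)
    s <- summed_score(g)
    n <- s$per_grade_counts
    expect_identical(s$total_score,
                     as.integer(1 * n[["1"]] + 2 * n[["2"]] + 3 * n[["3"]]))
    # permutation invariance and additivity over disjoint subsets
    expect_identical(summed_score(sample(g))$total_score, s$total_score)
    k <- length(g) %/% 2
    expect_identical(summed_score(g[seq_len(k)])$total_score +
                       summed_score(g[-seq_len(k)])$total_score,
                     s$total_score)
  }
})

test_that("function parameters obey the EDV/ESV/SV/EF/CO identities", {
  fp <- function_params(c(100, 90, 70, 50, 55, 70, 85, 95), heart_rate = 60)
  expect_identical(fp$EDV, 100)
  expect_identical(fp$ESV, 50)
  expect_identical(fp$SV, 50)
  expect_identical(fp$EF, 50)
  expect_identical(fp$CO, 3.0)
  expect_true(fp$ESV <= fp$EDV)

  flat <- function_params(rep(80, 8), heart_rate = 70)
  expect_identical(flat$EF, 0)
  expect_identical(flat$CO, 0)

  expect_error(function_params(rep(0, 8)), "undefined")
  expect_error(function_params(60), "at least 2")
})

test_that("segment means isolate an angular defect after reconstruction", {
  spec <- myocardial_spec(outer_radius = 0.6, inner_radius = 0.35,
                          base_counts = 100,
                          defects = data.frame(start_deg = 0, end_deg = 60,
                                               scale = 0.3))
  ph <- make_myocardial_phantom(spec)
  rec <- fbp_reconstruct(project(ph, uniform_angles(120)))$image
  # 6 sectors aligned with the defect: segment 1 covers [0, 60)
  seg <- segment_mean_counts(rec, n_segments = 6,
                             inner_radius = 0.35, outer_radius = 0.6)
  expect_identical(which.min(seg), 1L)
  expect_lt(seg[1], 0.5 * max(seg))
  g <- grade_perfusion(seg)
  expect_identical(as.integer(g)[1], 3L)
  expect_identical(as.integer(g)[-1], rep(0L, 5))
})

test_that("pipeline EF tracks analytic EF with perfect rank order", {
  spec <- myocardial_spec(outer_radius = 0.6, inner_radius = 0.35,
                          base_counts = 100)
  pairs <- list(c(0.40, 0.12), c(0.40, 0.20), c(0.40, 0.26),
                c(0.35, 0.25), c(0.30, 0.24))
  ef_true <- vapply(pairs, function(p) (1 - (p[2] / p[1])^2) * 100,
                    numeric(1))
  ef_meas <- vapply(pairs, function(p) {
    g <- make_gated_series(spec, 8, ed_inner_radius = p[1],
                           es_inner_radius = p[2])
    compute_function_params(g)$EF
  }, numeric(1))
  expect_identical(rank(ef_meas), rank(ef_true))
  expect_equal(stats::cor(ef_true, ef_meas, method = "spearman"), 1)
  expect_lt(max(abs(ef_true - ef_meas)), 5)
})

test_that("EF survives the full project-reconstruct pipeline within 2 points", {
  spec <- myocardial_spec(outer_radius = 0.6, inner_radius = 0.35,
                          base_counts = 100, grid_size = 256)
  p <- c(0.40, 0.20)  # cavity area ratio 4:1, analytic EF 75
  g <- make_gated_series(spec, 8, ed_inner_radius = p[1],
                         es_inner_radius = p[2])
  rg <- reconstruct_series(g, uniform_angles(90), n_detector_bins = 64)
  fp <- compute_function_params(rg)
  expect_lt(abs(fp$EF - 75), 2)
  expect_true(fp$ESV <= fp$EDV)
})
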
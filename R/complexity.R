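#' One-dimensional transform cost A(N)
#'
#' The cost of an N-point one-dimensional transform used as the unit of
#' account in the filtering cost model, taken as exactly `N log2 N`
#' (unit constant). All ratio results downstream are independent of the
#' constant. `N` must be a power of 2 so `log2 N` is integral.
#'
#' @param N transform length, power of 2.
#' @return `N * log2(N)`.
#' @examples
#' A_of_N(64)  # 384
#' @export
A_of_N <- function(N) {
  N <- as.integer(N)
  if (any(is.na(N)) || any(N < 2L) || any(bitwAnd(N, N - 1L) != 0L))
    stop("'N' must be a power of 2, >= 2", call. = FALSE)
  N * log2(N)
}

#' Per-view filtering operation counts
#'
#' Real-operation cost of filtering one view's projection data of
#' length N. The accelerated method filters via two length-2N
#' transforms plus 2N pointwise multiplications (multiplication
#' `2 A(2N) + 2N`, addition `2 A(2N)`); the traditional route costs
#' `5 A(2N) + 4N` multiplications and `5 A(2N)` additions.
#'
#' @param N projection length, power of 2.
#' @param method `"new"` or `"traditional"`.
#' @return list with `multiplications` and `additions`.
#' @examples
#' filter_op_counts(64, "new")          # 1920 mult, 1792 add
#' filter_op_counts(64, "traditional")  # 4736 mult, 4480 add
#' @export
filter_op_counts <- function(N, method = c("new", "traditional")) {
  method <- match.arg(method)
  a2n <- A_of_N(2L * as.integer(N))
  if (method == "new") {
    list(multiplications = 2 * a2n + 2 * N, additions = 2 * a2n)
  } else {
    list(multiplications = 5 * a2n + 4 * N, additions = 5 * a2n)
  }
}

#' Reconstruction operation counts (analytic model)
#'
#' The closed-form operation counts for reconstructing an N x N image
#' from M azimuths. Traditional back projection costs `3MN`
#' multiplications, `2MN^2` additions, and `MN^2` roundings; the
#' quarter-symmetry method needs positioning for only `ceiling(M/4)`
#' azimuths, giving `3N ceiling(M/4) / 2` multiplications,
#' `N^2 ceiling(M/4)` additions, and `N^2 ceiling(M/4) / 2` roundings.
#'
#' @param M number of azimuths (views), >= 1.
#' @param N grid dimension / transform length, >= 1.
#' @param method `"new"` or `"traditional"`.
#' @return list with `multiplications`, `additions`, `roundings`.
#' @examples
#' table3_counts(360, 64, "traditional")  # 69120, 2949120, 1474560
#' table3_counts(360, 64, "new")          # 8640, 368640, 184320
#' @export
table3_counts <- function(M, N, method = c("new", "traditional")) {
  method <- match.arg(method)
  if (M < 1 || N < 1) stop("'M' and 'N' must be >= 1", call. = FALSE)
  if (method == "traditional") {
    list(multiplications = 3 * M * N,
         additions = 2 * M * N^2,
         roundings = M * N^2)
  } else {
    q <- ceiling(M / 4)
    list(multiplications = 3 * N * q / 2,
         additions = N^2 * q,
         roundings = N^2 * q / 2)
  }
}

#' New/traditional operation-count ratios
#'
#' Ratio of the quarter-symmetry method's counts to the traditional
#' method's for each operation class. When M is divisible by 4 (so
#' `ceiling(M/4) = M/4` exactly) every class ratio equals exactly 1/8;
#' otherwise the ceiling makes the ratios slightly larger and the result
#' is flagged approximate.
#'
#' @inheritParams table3_counts
#' @return list with `multiplications`, `additions`, `roundings`
#'   ratios and logical `approximate`.
#' @examples
#' complexity_ratio(360, 64)  # 0.125 in every class
#' @export
complexity_ratio <- function(M, N) {
  new <- table3_counts(M, N, "new")
  trad <- table3_counts(M, N, "traditional")
  list(multiplications = new$multiplications / trad$multiplications,
       additions = new$additions / trad$additions,
       roundings = new$roundings / trad$roundings,
       approximate = (M %% 4 != 0))
}

#' Compare live back projection counters with the analytic model
#'
#' Places the instrumented positioning-operation ratio from an actual
#' pair of back projection runs (standard vs quarter-symmetry, identical
#' input) alongside the analytic model's per-class 1/8 ratios. The two
#' accountings measure different things — the live counter tallies
#' positioning-map evaluations (expected ratio 1/4), the model counts
#' arithmetic per operation class (ratio 1/8) — and are reported side by
#' side without being summed or reconciled.
#'
#' @param counter_standard,counter_symmetric [op_counter()] objects from
#'   [backproject()] and [backproject_symmetric()] runs on the same
#'   filtered sinogram.
#' @param M,N the view count and grid size of those runs.
#' @return list with `live` (positioning counts and their ratio) and
#'   `model` (the [complexity_ratio()] output).
#' @export
counters_vs_model <- function(counter_standard, counter_symmetric, M, N) {
  stopifnot(inherits(counter_standard, "op_counter"),
            inherits(counter_symmetric, "op_counter"))
  live_ratio <- if (counter_standard$positioning_ops > 0)
    counter_symmetric$positioning_ops / counter_standard$positioning_ops
  else NA_real_
  list(live = list(standard_positioning = counter_standard$positioning_ops,
                   symmetric_positioning = counter_symmetric$positioning_ops,
                   positioning_ratio = live_ratio),
       model = complexity_ratio(M, N))
}
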
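#' Verify a time grid is uniform and return its spacing
#'
#' The differentiation stencils assume equispaced samples; experimental
#' dissolution schedules rarely are, so this check guards every entry point.
#'
#' @param times Strictly increasing times, length >= 2.
#' @param rel_tol Maximum allowed relative deviation of successive gaps from
#'   their median (default 1e-6, enough to absorb floating-point jitter).
#' @return The common spacing `h` (days).
#' @export
check_uniform_grid <- function(times, rel_tol = 1e-6) {
  if (length(times) < 2L) stop("need at least 2 time points", call. = FALSE)
  gaps <- diff(times)
  if (any(gaps <= 0)) stop("`times` must be strictly increasing",
                           call. = FALSE)
  h <- stats::median(gaps)
  dev <- abs(gaps - h) / h
  if (max(dev) > rel_tol) {
    worst <- which.max(dev)
    stop(sprintf(
      "non-uniform grid: interval %d (t = %g to %g) has spacing %g vs %g",
      worst, times[worst], times[worst + 1L], gaps[worst], h), call. = FALSE)
  }
  h
}

#' Resample a release series onto a uniform grid
#'
#' Monotone shape-preserving piecewise-cubic (Fritsch--Carlson) interpolation
#' onto an equispaced grid spanning the original time range. The interpolant
#' passes through every input point and preserves monotonicity, so a
#' nondecreasing cumulative-release series stays nondecreasing.
#'
#' @param series A [release_series()] with at least 4 points.
#' @param h Target spacing, days; must not exceed the series time span.
#' @return A [release_series()] on the uniform grid.
#' @export
resample_uniform <- function(series, h) {
  stopifnot(inherits(series, "release_series"))
  if (nrow(series) < 4L) {
    stop("need at least 4 points to resample", call. = FALSE)
  }
  if (h <= 0) stop("`h` must be positive", call. = FALSE)
  t1 <- series$time_days[1L]
  t2 <- series$time_days[nrow(series)]
  if (h > (t2 - t1)) {
    stop("`h` exceeds the time span of the series", call. = FALSE)
  }
  f <- stats::splinefun(series$time_days, series$release_pct,
                        method = "monoH.FC")
  n_step <- floor((t2 - t1) / h + 1e-9)
  grid <- t1 + h * seq(0L, n_step)
  release_series(grid, f(grid), t0 = attr(series, "t0"))
}

#' Two-point forward-difference derivative, order O(h)
#'
#' `dy_i = (y[i+1] - y[i]) / h` for `i = 1 .. n-1` (anchored at the left
#' node). Exact for affine sequences. Nodes without a full stencil are
#' dropped rather than patched with lower-order one-sided formulas.
#'
#' @param values Samples on a uniform grid, length >= 2.
#' @param h Grid spacing, days.
#' @return A list of class `derivative_estimate` with fields `node_indices`
#'   (1-based indices into `values`), `values` (derivative estimates),
#'   `step_h`, `order_tag = "O(h)"`.
#' @export
forward_diff <- function(values, h) {
  n <- length(values)
  if (n < 2L) stop("forward difference needs at least 2 values",
                   call. = FALSE)
  if (h <= 0) stop("`h` must be positive", call. = FALSE)
  idx <- seq_len(n - 1L)
  structure(
    list(node_indices = idx, values = (values[idx + 1L] - values[idx]) / h,
         step_h = h, order_tag = "O(h)"),
    class = "derivative_estimate"
  )
}

#' Five-point central-difference derivative, order O(h^4)
#'
#' `dy_i = (-y[i+2] + 8 y[i+1] - 8 y[i-1] + y[i-2]) / (12 h)` for interior
#' nodes `i = 3 .. n-2` (1-based). Exact for polynomials of degree <= 4.
#'
#' @param values Samples on a uniform grid, length >= 5.
#' @param h Grid spacing, days.
#' @return A `derivative_estimate` with `order_tag = "O(h4)"`.
#' @export
central_diff4 <- function(values, h) {
  n <- length(values)
  if (n < 5L) stop("central O(h^4) difference needs at least 5 values",
                   call. = FALSE)
  if (h <= 0) stop("`h` must be positive", call. = FALSE)
  idx <- seq.int(3L, n - 2L)
  est <- (-values[idx + 2L] + 8 * values[idx + 1L] -
            8 * values[idx - 1L] + values[idx - 2L]) / (12 * h)
  structure(
    list(node_indices = idx, values = est, step_h = h, order_tag = "O(h4)"),
    class = "derivative_estimate"
  )
}
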
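#' First-order exterior-transfer release model
#'
#' Constructs the closed-form release model for a depot whose exterior bath
#' concentration `C3(t)` obeys the first-order transfer law
#' `dC3/dt + a C3 = a C2_edge` with `a = K32 / V3`, giving
#' `C3(t) = C2_edge * (1 - exp(-a (t - t0)))`. `C2_edge` is the drug
#' concentration at the outer edge of the polymer matrix (the plateau of the
#' release curve, in % of the nominal dose), `K32` the matrix-to-bath transfer
#' coefficient, and `V3` the bath volume.
#'
#' The transfer coefficient follows the dissolution literature's numeric
#' convention `K32 = rate_a * V3` with `V3` in mL, so that `K32 / V3` is the
#' first-order rate in day^-1. Exactly one of `rate_a` or `K32` must be given.
#'
#' @param C2_edge Plateau concentration at the matrix edge, % of dose (> 0).
#' @param rate_a Exterior first-order rate constant, day^-1 (> 0).
#' @param K32 Transfer coefficient, `rate_a * V3`; alternative to `rate_a`.
#' @param V3 Exterior medium volume, mL (default 80).
#' @param t0 Origin (injection/lag) time, days (default 0).
#' @return An object of class `first_order_model`.
#' @examples
#' m <- first_order_model(C2_edge = 103.5, rate_a = 0.7081)
#' evaluate_release_curve(m, c(0, 1, 7))
#' @export
first_order_model <- function(C2_edge, rate_a = NULL, K32 = NULL, V3 = 80,
                              t0 = 0) {
  if (is.null(rate_a) == is.null(K32)) {
    stop("supply exactly one of `rate_a` or `K32`", call. = FALSE)
  }
  if (!is.numeric(V3) || length(V3) != 1L || !is.finite(V3) || V3 <= 0) {
    stop("`V3` must be a single positive volume in mL", call. = FALSE)
  }
  if (is.null(rate_a)) rate_a <- K32 / V3
  if (!is.numeric(rate_a) || length(rate_a) != 1L || !is.finite(rate_a) ||
      rate_a <= 0) {
    stop("invalid model: rate constant must be a single positive number",
         call. = FALSE)
  }
  if (!is.numeric(C2_edge) || length(C2_edge) != 1L || !is.finite(C2_edge) ||
      C2_edge <= 0) {
    stop("invalid model: `C2_edge` must be a single positive percentage",
         call. = FALSE)
  }
  structure(
    list(C2_edge = C2_edge, rate_a = rate_a, K32 = rate_a * V3, V3 = V3,
         t0 = t0),
    class = "first_order_model"
  )
}

#' @export
print.first_order_model <- function(x, ...) {
  cat("First-order exterior-transfer release model\n")
  cat(sprintf("  C2_edge : %.4g %% of dose (plateau)\n", x$C2_edge))
  cat(sprintf("  rate a  : %.4g / day  (K32 = %.4g, V3 = %g mL)\n",
              x$rate_a, x$K32, x$V3))
  cat(sprintf("  t0      : %g day\n", x$t0))
  invisible(x)
}

#' Sampled cumulative-release trajectory
#'
#' A `release_series` pairs a strictly increasing time grid (days) with
#' cumulative release values (% of dose) and the origin time `t0`.
#'
#' @param times Strictly increasing sample times, days; `times[1] >= t0`.
#' @param values Cumulative release, % of dose; finite.
#' @param t0 Origin time, days.
#' @return A data frame of class `release_series` with columns `time_days`
#'   and `release_pct`, and attribute `t0`.
#' @export
release_series <- function(times, values, t0 = 0) {
  times <- as.numeric(times)
  values <- as.numeric(values)
  if (length(times) != length(values)) {
    stop("`times` and `values` must have equal length", call. = FALSE)
  }
  if (length(times) == 0L) stop("empty release series", call. = FALSE)
  if (any(!is.finite(times)) || any(!is.finite(values))) {
    stop("times and values must be finite", call. = FALSE)
  }
  if (any(diff(times) <= 0)) {
    stop("`times` must be strictly increasing", call. = FALSE)
  }
  if (times[1L] < t0 - 1e-12) {
    stop("first sample time precedes the origin time `t0`", call. = FALSE)
  }
  structure(
    data.frame(time_days = times, release_pct = values),
    t0 = t0,
    class = c("release_series", "data.frame")
  )
}

#' Evaluate the release curve at given times
#'
#' Evaluates `C3(t) = C2_edge * (1 - exp(-rate_a * (t - t0)))` on a strictly
#' increasing time grid. The curve starts at 0 at `t0`, is nondecreasing and
#' concave, and approaches the plateau `C2_edge`.
#'
#' @param model A [first_order_model()].
#' @param times Strictly increasing evaluation times, days, all `>= t0`.
#' @return A [release_series()].
#' @export
evaluate_release_curve <- function(model, times) {
  stopifnot(inherits(model, "first_order_model"))
  times <- as.numeric(times)
  if (any(times < model$t0 - 1e-12)) {
    stop("evaluation times must not precede the model origin `t0`",
         call. = FALSE)
  }
  vals <- model$C2_edge * (1 - exp(-model$rate_a * (times - model$t0)))
  release_series(times, vals, t0 = model$t0)
}

#' Fraction of the plateau released by time t
#'
#' Returns `1 - exp(-rate_a * (t - t0))`, the released fraction of the
#' eventual plateau `C2_edge`, in `[0, 1)` for finite `t`.
#'
#' @param model A [first_order_model()].
#' @param t Time, days, `>= t0`. Vectorised.
#' @return Numeric fraction(s) of the plateau.
#' @examples
#' m <- first_order_model(C2_edge = 100, K32 = 40, V3 = 80)
#' fraction_released_at(m, 7) # 1 - exp(-3.5)
#' @export
fraction_released_at <- function(model, t) {
  stopifnot(inherits(model, "first_order_model"))
  if (any(t < model$t0 - 1e-12)) {
    stop("`t` must not precede the model origin `t0`", call. = FALSE)
  }
  1 - exp(-model$rate_a * (t - model$t0))
}

#' Release-profile sweep over transfer coefficient and plateau grids
#'
#' Evaluates one release curve per `(K32, C2)` combination on a shared time
#' grid, for exploring how the matrix-to-bath transport rate and the
#' matrix-edge concentration shape the profile. Rows are ordered by
#' `(C2, K32)`.
#'
#' @param K32_values Positive transfer coefficients, `rate = K32 / V3` day^-1.
#' @param C2_values Positive plateau levels, % of dose.
#' @param time_grid Strictly increasing evaluation times, days.
#' @param V3 Exterior medium volume, mL.
#' @param t0 Origin time, days.
#' @return A long-format data frame with columns `K32_per_day`, `C2_pct`,
#'   `time_days`, `release_pct`.
#' @examples
#' sw <- sweep_profiles(c(30, 65), c(70, 105), seq(0, 7, by = 0.5))
#' @export
sweep_profiles <- function(K32_values, C2_values, time_grid, V3 = 80, t0 = 0) {
  if (length(K32_values) == 0L || length(C2_values) == 0L) {
    return(data.frame(K32_per_day = numeric(), C2_pct = numeric(),
                      time_days = numeric(), release_pct = numeric()))
  }
  if (any(K32_values <= 0) || any(C2_values <= 0)) {
    stop("sweep grids must be positive", call. = FALSE)
  }
  if (any(diff(time_grid) <= 0)) {
    stop("`time_grid` must be strictly increasing", call. = FALSE)
  }
  out <- vector("list", length(C2_values) * length(K32_values))
  i <- 1L
  for (C2 in sort(C2_values)) {
    for (K32 in sort(K32_values)) {
      m <- first_order_model(C2_edge = C2, K32 = K32, V3 = V3, t0 = t0)
      s <- evaluate_release_curve(m, time_grid)
      out[[i]] <- data.frame(K32_per_day = K32, C2_pct = C2,
                             time_days = s$time_days,
                             release_pct = s$release_pct)
      i <- i + 1L
    }
  }
  do.call(rbind, c(out, list(make.row.names = FALSE)))
}

#' Published fitted release parameters for the levofloxacin-zein formulations
#'
#' Reference fitted parameters for the four levofloxacin HCl zein-based ISG
#' formulations (20% and 25% w/w zein in DMSO or glycerol formal), each
#' estimated with both differentiation schemes at a bath volume of 80 mL.
#' `rate_a = K32 / V3` is the exponent coefficient of the fitted release
#' equation `C3(t) = C2_edge (1 - e^{-rate_a t})`.
#'
#' @return A data frame with columns `formulation`, `method` (`"O(h)"` or
#'   `"O(h4)"`), `K32` (day^-1 convention), `C2_edge` (%), `rate_a` (day^-1),
#'   `V3` (mL).
#' @export
reference_release_parameters <- function() {
  df <- data.frame(
    formulation = rep(c("Lv20ZD", "Lv25ZD", "Lv20ZG", "Lv25ZG"), each = 2L),
    method = rep(c("O(h)", "O(h4)"), 4L),
    K32 = c(56.65, 52.91, 51.57, 64.76, 47.58, 32.55, 34.47, 50.23),
    C2_edge = c(103.50, 105.50, 88.97, 88.60, 98.35, 104.50, 74.01, 71.58),
    rate_a = c(0.7081, 0.6614, 0.6446, 0.8095, 0.5948, 0.4069, 0.4309, 0.6279),
    stringsAsFactors = FALSE
  )
  df$V3 <- 80
  df
}

#' Write a sweep table as delimited text
#'
#' @param sweep Output of [sweep_profiles()].
#' @param path Destination file; comma-delimited with header.
#' @return `path`, invisibly.
#' @export
write_sweep_table <- function(sweep, path) {
  utils::write.csv(sweep, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
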
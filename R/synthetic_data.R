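#' Cup-method release protocol
#'
#' Describes the in vitro cup dissolution assay: a formulation depot sits in a
#' small cup immersed in `V3` mL of stirred buffer; at each scheduled time an
#' aliquot of `Vs` mL is withdrawn for assay and replaced with fresh buffer,
#' so later samples must be corrected for drug removed earlier.
#'
#' @param V3 Medium volume, mL (default 80).
#' @param Vs Aliquot volume withdrawn per sample, mL (default 5); `0 < Vs < V3`
#'   except that `Vs = 0` is allowed as the no-withdrawal limit.
#' @param dose_mg Nominal drug dose in the depot, mg (default 4, i.e. 0.4 g of
#'   formulation at 1% w/w drug).
#' @param schedule Strictly increasing sampling times, days. Default
#'   `c(0.5, 1:7)`, the conventional 12 h-to-7 day span.
#' @return An object of class `cup_protocol`.
#' @export
cup_protocol <- function(V3 = 80, Vs = 5, dose_mg = 4,
                         schedule = c(0.5, 1, 2, 3, 4, 5, 6, 7)) {
  if (!is.numeric(V3) || V3 <= 0) stop("`V3` must be positive", call. = FALSE)
  if (!is.numeric(Vs) || Vs < 0 || Vs >= V3) {
    stop("`Vs` must satisfy 0 <= Vs < V3", call. = FALSE)
  }
  if (!is.numeric(dose_mg) || dose_mg <= 0) {
    stop("`dose_mg` must be positive", call. = FALSE)
  }
  if (length(schedule) < 1L || any(diff(schedule) <= 0)) {
    stop("`schedule` must be strictly increasing", call. = FALSE)
  }
  structure(list(V3 = V3, Vs = Vs, dose_mg = dose_mg, schedule = schedule),
            class = "cup_protocol")
}

#' Measurement-noise specification
#'
#' Stand-in for spectrophotometric assay error, applied to the measured medium
#' concentrations (not to cumulative percentages), so that errors propagate
#' through the sampling-volume correction the way real assay noise would.
#'
#' @param kind One of `"none"`, `"additive-normal"` (adds `N(0, sd^2)` in
#'   concentration units) or `"multiplicative-normal"` (multiplies by
#'   `1 + N(0, sd^2)`, `sd` a relative fraction).
#' @param sd Standard deviation (>= 0).
#' @param seed Integer RNG seed; required for stochastic kinds.
#' @return An object of class `noise_spec`.
#' @export
noise_spec <- function(kind = c("none", "additive-normal",
                                "multiplicative-normal"),
                       sd = 0, seed = NULL) {
  kind <- match.arg(kind)
  if (!is.numeric(sd) || sd < 0) stop("`sd` must be >= 0", call. = FALSE)
  if (kind != "none" && is.null(seed)) {
    stop("a `seed` is required for stochastic noise kinds", call. = FALSE)
  }
  structure(list(kind = kind, sd = sd, seed = seed), class = "noise_spec")
}

#' Convert cumulative released amounts to per-sample medium concentrations
#'
#' Inverts the bookkeeping of the cup assay: given the true cumulative amount
#' `A_n` (mg) released by sampling time `n`, the concentration measured in the
#' n-th aliquot is
#' `c_n = (A_n - Vs * sum_{i<n} c_i) / V3`,
#' because each earlier aliquot removed `Vs * c_i` mg from the medium.
#'
#' @param cumulative_mg Nondecreasing cumulative released amounts, mg, one per
#'   scheduled sample.
#' @param protocol A [cup_protocol()].
#' @return Numeric vector of medium concentrations, mg/mL.
#' @export
apply_cup_sampling <- function(cumulative_mg, protocol) {
  stopifnot(inherits(protocol, "cup_protocol"))
  A <- as.numeric(cumulative_mg)
  if (any(!is.finite(A))) stop("cumulative amounts must be finite",
                               call. = FALSE)
  if (any(diff(A) < -1e-12 * max(abs(A), 1))) {
    stop("cumulative released amounts must be nondecreasing", call. = FALSE)
  }
  n <- length(A)
  conc <- numeric(n)
  removed <- 0
  for (i in seq_len(n)) {
    conc[i] <- (A[i] - removed) / protocol$V3
    removed <- removed + protocol$Vs * conc[i]
  }
  conc
}

#' Reconstruct cumulative release (% of dose) from aliquot concentrations
#'
#' Exact inverse of [apply_cup_sampling()]:
#' `A_n = c_n * V3 + Vs * sum_{i<n} c_i`, reported as `100 * A_n / dose_mg`.
#' This is the standard cumulative-release correction for
#' constant-volume-replacement dissolution sampling.
#'
#' @param concs Per-sample medium concentrations, mg/mL.
#' @param protocol A [cup_protocol()] whose schedule matches `concs`.
#' @return A [release_series()] in % of dose on the protocol schedule.
#' @export
reconstruct_cumulative <- function(concs, protocol) {
  stopifnot(inherits(protocol, "cup_protocol"))
  concs <- as.numeric(concs)
  if (length(concs) != length(protocol$schedule)) {
    stop("`concs` must match the protocol schedule length", call. = FALSE)
  }
  prior <- c(0, cumsum(concs))[seq_along(concs)]
  A <- concs * protocol$V3 + protocol$Vs * prior
  release_series(protocol$schedule, 100 * A / protocol$dose_mg, t0 = 0)
}

#' Corrupt concentrations with assay noise
#'
#' `kind = "none"` returns the input unchanged. Values are deliberately NOT
#' clipped at zero: small true concentrations can yield negative measurements,
#' as they do in a real spectrophotometric assay near the detection limit.
#'
#' @param concs Concentrations, mg/mL.
#' @param noise A [noise_spec()].
#' @return Concentrations with noise applied; identical output for identical
#'   seed.
#' @export
corrupt_with_noise <- function(concs, noise) {
  stopifnot(inherits(noise, "noise_spec"))
  if (noise$kind == "none" || noise$sd == 0) return(concs)
  old <- globalenv()$.Random.seed
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(noise$seed)
  eps <- stats::rnorm(length(concs), mean = 0, sd = noise$sd)
  switch(noise$kind,
         "additive-normal" = concs + eps,
         "multiplicative-normal" = concs * (1 + eps))
}

#' Generate a synthetic cup-method release dataset with known ground truth
#'
#' Evaluates the first-order release model on the protocol schedule (the
#' truth), converts it to released mass, pushes it through the aliquot
#' sampling model, optionally corrupts the aliquot concentrations with assay
#' noise, and reconstructs the observed cumulative-% series exactly as an
#' experimenter would.
#'
#' @param model A [first_order_model()]; its `C2_edge` is interpreted as % of
#'   `protocol$dose_mg`.
#' @param protocol A [cup_protocol()].
#' @param noise A [noise_spec()] (default: no noise).
#' @return A list with elements `truth` and `observed` (both
#'   [release_series()]) and `meta` (generator parameters and seed).
#' @examples
#' m <- first_order_model(C2_edge = 103.5, rate_a = 0.7081)
#' d <- make_dataset(m, cup_protocol())
#' d$observed
#' @export
make_dataset <- function(model, protocol = cup_protocol(),
                         noise = noise_spec("none")) {
  stopifnot(inherits(model, "first_order_model"),
            inherits(protocol, "cup_protocol"),
            inherits(noise, "noise_spec"))
  if (protocol$schedule[1L] < model$t0) {
    stop("protocol schedule starts before the model origin `t0`",
         call. = FALSE)
  }
  truth <- evaluate_release_curve(model, protocol$schedule)
  truth_mg <- truth$release_pct / 100 * protocol$dose_mg
  concs <- apply_cup_sampling(truth_mg, protocol)
  observed <- reconstruct_cumulative(corrupt_with_noise(concs, noise),
                                     protocol)
  meta <- list(
    C2_edge = model$C2_edge, rate_a = model$rate_a, K32 = model$K32,
    V3_model = model$V3, t0 = model$t0,
    V3 = protocol$V3, Vs = protocol$Vs, dose_mg = protocol$dose_mg,
    noise_kind = noise$kind, noise_sd = noise$sd,
    seed = if (is.null(noise$seed)) NA_integer_ else noise$seed
  )
  list(truth = truth, observed = observed, meta = meta)
}

#' Write a release series (and optional metadata side-car) as delimited text
#'
#' @param series A [release_series()].
#' @param path Destination CSV (`time_days`, `release_pct`).
#' @param meta Optional named list written as `key = value` lines to
#'   `paste0(path, ".meta")`.
#' @return `path`, invisibly.
#' @export
write_release_series <- function(series, path, meta = NULL) {
  utils::write.csv(as.data.frame(series), path, row.names = FALSE,
                   quote = FALSE)
  if (!is.null(meta)) {
    lines <- vapply(names(meta),
                    function(k) sprintf("%s = %s", k, format(meta[[k]])),
                    character(1))
    writeLines(lines, paste0(path, ".meta"))
  }
  invisible(path)
}

#' Read a release series written by [write_release_series()]
#'
#' @param path CSV file with columns `time_days` and `release_pct`.
#' @param t0 Origin time, days.
#' @return A [release_series()].
#' @export
read_release_series <- function(path, t0 = 0) {
  df <- utils::read.csv(path)
  need <- c("time_days", "release_pct")
  if (!all(need %in% names(df))) {
    stop(sprintf("'%s' lacks required columns time_days, release_pct", path),
         call. = FALSE)
  }
  release_series(df$time_days, df$release_pct, t0 = t0)
}
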
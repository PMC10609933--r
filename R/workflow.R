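#' Read a declarative run configuration
#'
#' Configurations are flat YAML key-value files, one section per command
#' (e.g. `generate:`, `fit:`, `sweep:`, `sphere:`), plus optional top-level
#' `seed` and `out_dir`. Command functions accept the parsed list directly,
#' so programmatic use never needs a file.
#'
#' @param path YAML file.
#' @return A named list.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop(sprintf("config file '%s' not found", path),
                               call. = FALSE)
  yaml::read_yaml(path)
}

.provenance <- function(config, seed) {
  list(tool = paste0("isgrelease ",
                     as.character(utils::packageVersion("isgrelease"))),
       config_hash = rlang::hash(config),
       seed = if (is.null(seed)) NA_integer_ else seed)
}

.cfg <- function(config, key, default) {
  if (!is.null(config[[key]])) config[[key]] else default
}

#' Generate a synthetic cup-method dataset from a configuration
#'
#' Writes `truth.csv` and `observed.csv` (plus `.meta` side-cars embedding
#' generator parameters, seed and config hash) under `out_dir`.
#'
#' Recognised config keys (all optional unless noted): `C2_edge` (required),
#' one of `rate_a`/`K32` (required), `V3`, `Vs`, `dose_mg`, `t0`, `schedule`,
#' `noise_kind`, `noise_sd`, `seed`.
#'
#' @param config Named list (e.g. the `generate` section of
#'   [read_run_config()]).
#' @param out_dir Output directory; created if absent.
#' @return Named character vector of the files written, invisibly.
#' @export
cmd_generate <- function(config, out_dir = ".") {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  model <- first_order_model(
    C2_edge = config$C2_edge, rate_a = config$rate_a, K32 = config$K32,
    V3 = .cfg(config, "V3", 80), t0 = .cfg(config, "t0", 0))
  protocol <- cup_protocol(
    V3 = .cfg(config, "V3", 80), Vs = .cfg(config, "Vs", 5),
    dose_mg = .cfg(config, "dose_mg", 4),
    schedule = .cfg(config, "schedule", c(0.5, 1, 2, 3, 4, 5, 6, 7)))
  kind <- .cfg(config, "noise_kind", "none")
  noise <- noise_spec(kind, sd = .cfg(config, "noise_sd", 0),
                      seed = config$seed)
  d <- make_dataset(model, protocol, noise)
  meta <- c(d$meta, .provenance(config, config$seed))
  paths <- c(truth = file.path(out_dir, "truth.csv"),
             observed = file.path(out_dir, "observed.csv"))
  write_release_series(d$truth, paths[["truth"]], meta = meta)
  write_release_series(d$observed, paths[["observed"]], meta = meta)
  invisible(paths)
}

#' Fit the first-order release model to a series file
#'
#' Reads a release CSV (`time_days`, `release_pct`), runs [fit_release()],
#' writes a key-value fit report, and logs the estimates to standard error.
#'
#' Config keys: `input` (required path), `method` (`"forward"`/`"O(h)"` or
#' `"central4"`/`"O(h4)"`, default forward), `V3`, `resample_h`, `label`.
#'
#' @inheritParams cmd_generate
#' @return Path of the report file, invisibly.
#' @export
cmd_fit <- function(config, out_dir = ".") {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  series <- read_release_series(config$input)
  fit <- fit_release(series,
                     method = .cfg(config, "method", "forward"),
                     V3 = .cfg(config, "V3", 80),
                     resample_h = config$resample_h)
  message(sprintf("fit [%s]: K32 = %.4f, C2 = %.4f, rel_err = %.4g, r2 = %.6f",
                  fit$method, fit$model$K32, fit$model$C2_edge,
                  fit$rel_err, fit$r_squared))
  path <- file.path(out_dir, "fit_report.txt")
  write_fit_report(fit, path, label = .cfg(config, "label", "unnamed"),
                   extra = .provenance(config, config$seed))
  invisible(path)
}

#' Run a release-profile sweep from a configuration
#'
#' Config keys: `K32_values` (default `c(30, 65)`), `C2_values` (default
#' `c(70, 105)`), `time_grid` (default 0..7 d step 0.05), `V3`, `t0`. The
#' defaults cover the conventional exploration grid: slow vs fast matrix
#' transport crossed with partial vs complete release.
#'
#' @inheritParams cmd_generate
#' @return Path of the sweep table, invisibly.
#' @export
cmd_sweep <- function(config, out_dir = ".") {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  sw <- sweep_profiles(
    K32_values = .cfg(config, "K32_values", c(30, 65)),
    C2_values = .cfg(config, "C2_values", c(70, 105)),
    time_grid = .cfg(config, "time_grid", seq(0, 7, by = 0.05)),
    V3 = .cfg(config, "V3", 80), t0 = .cfg(config, "t0", 0))
  if (nrow(sw) == 0L) stop("empty sweep grid", call. = FALSE)
  path <- file.path(out_dir, "sweep.csv")
  write_sweep_table(sw, path)
  invisible(path)
}

#' Run the spherical three-phase simulator from a configuration
#'
#' Config keys mirror [sphere_spec()] arguments; additionally `dose_mass`
#' for the exterior-series normalisation. Writes `sphere_fields.csv` and
#' `sphere_release.csv` and logs the relative mass-budget drift.
#'
#' @inheritParams cmd_generate
#' @return Named character vector of files written, invisibly.
#' @export
cmd_simulate_sphere <- function(config, out_dir = ".") {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  spec <- sphere_spec(
    r1 = config$r1, r2 = config$r2, D1 = config$D1, D2 = config$D2,
    epsilon = config$epsilon, K32 = config$K32, V3 = .cfg(config, "V3", 80),
    C1_init = config$C1_init, C3_init = .cfg(config, "C3_init", 0),
    t0 = .cfg(config, "t0", 0), n_r = .cfg(config, "n_r", 40),
    t_grid = .cfg(config, "t_grid", seq(0, 7, by = 0.05)),
    surface = .cfg(config, "surface", "bath"))
  sim <- simulate_sphere(spec)
  drift <- if (sim$mass[1L] > 0) {
    max(abs(sim$mass - sim$mass[1L])) / sim$mass[1L]
  } else max(abs(sim$mass))
  message(sprintf("sphere simulation: mass-budget drift %.3g relative",
                  drift))
  paths <- c(fields = file.path(out_dir, "sphere_fields.csv"),
             series = file.path(out_dir, "sphere_release.csv"))
  write_sphere_fields(sim, paths[["fields"]])
  write_release_series(exterior_release_series(sim, config$dose_mass),
                       paths[["series"]],
                       meta = .provenance(config, config$seed))
  invisible(paths)
}

#' Command-line dispatcher
#'
#' Thin shell interface over the command functions:
#' `isgrelease <generate|fit|sweep|simulate-sphere> --config <yaml>
#' [--seed <int>] [--out-dir <dir>]`. The config section named after the
#' command supplies the parameters; `--seed` overrides any configured seed.
#'
#' @param args Character vector of command-line arguments (default
#'   `commandArgs(trailingOnly = TRUE)`).
#' @return Exit status, invisibly (0 on success).
#' @export
isg_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  if (length(args) < 1L) {
    message("usage: isgrelease <generate|fit|sweep|simulate-sphere> ",
            "--config <yaml> [--seed <int>] [--out-dir <dir>]")
    return(invisible(1L))
  }
  cmd <- args[1L]
  rest <- args[-1L]
  getopt <- function(flag, default = NULL) {
    i <- which(rest == flag)
    if (length(i) == 1L && i < length(rest)) rest[i + 1L] else default
  }
  cfg_path <- getopt("--config")
  out_dir <- getopt("--out-dir", ".")
  seed <- getopt("--seed")
  status <- tryCatch({
    full <- if (is.null(cfg_path)) list() else read_run_config(cfg_path)
    section <- switch(cmd, "simulate-sphere" = "sphere", cmd)
    config <- if (!is.null(full[[section]])) full[[section]] else full
    if (!is.null(seed)) config$seed <- as.integer(seed)
    if (is.null(config$seed) && !is.null(full$seed)) config$seed <- full$seed
    switch(cmd,
           "generate" = cmd_generate(config, out_dir),
           "fit" = cmd_fit(config, out_dir),
           "sweep" = cmd_sweep(config, out_dir),
           "simulate-sphere" = cmd_simulate_sphere(config, out_dir),
           stop(sprintf("unknown command '%s'", cmd), call. = FALSE))
    0L
  }, error = function(e) {
    message("error: ", conditionMessage(e))
    1L
  })
  invisible(status)
}
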
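test_that("cmd_generate writes deterministic datasets with provenance", {
  out <- withr::local_tempdir()
  cfg <- list(C2_edge = 103.5, rate_a = 0.7081)
  paths <- cmd_generate(cfg, out)
  truth <- read_release_series(paths[["truth"]])
  obs <- read_release_series(paths[["observed"]])
  expect_equal(obs$release_pct, truth$release_pct) # noise-free: identical
  expect_true(file.exists(paste0(paths[["observed"]], ".meta")))
  meta <- readLines(paste0(paths[["observed"]], ".meta"))
  expect_true(any(grepl("config_hash", meta)))

  # same config and seed twice: byte-identical observed files
  out2 <- withr::local_tempdir()
  out3 <- withr::local_tempdir()
  cfgn <- list(C2_edge = 103.5, rate_a = 0.7081,
               noise_kind = "multiplicative-normal", noise_sd = 0.02,
               seed = 42L)
  p2 <- cmd_generate(cfgn, out2)
  p3 <- cmd_generate(cfgn, out3)
  expect_identical(readLines(p2[["observed"]]), readLines(p3[["observed"]]))
  expect_false(identical(readLines(p2[["observed"]]),
                         readLines(p2[["truth"]])))
})

test_that("generated plateaus approach the configured matrix-edge level", {
  out <- withr::local_tempdir()
  row <- ref_row("Lv25ZG", "O(h)")
  paths <- cmd_generate(list(C2_edge = row$C2_edge, K32 = row$K32), out)
  truth <- read_release_series(paths[["truth"]])
  expect_gt(tail(truth$release_pct, 1), 0.95 * row$C2_edge)
  expect_lt(tail(truth$release_pct, 1), row$C2_edge)
})

test_that("generate then fit recovers the published row end to end", {
  out <- withr::local_tempdir()
  row <- ref_row("Lv20ZD", "O(h)")
  paths <- cmd_generate(list(C2_edge = row$C2_edge, rate_a = row$rate_a,
                             schedule = seq(0.001, 7, by = 0.001)), out)
  report <- suppressMessages(
    cmd_fit(list(input = paths[["truth"]], method = "forward",
                 label = "Lv20ZD"), out))
  kv <- readLines(report)
  get <- function(key) {
    as.numeric(sub(".* = ", "", kv[grepl(paste0("^", key, " ="), kv)]))
  }
  expect_lt(abs(get("K32_per_day") - row$K32) / row$K32, 0.005)
  expect_lt(abs(get("C2_pct") - row$C2_edge) / row$C2_edge, 0.001)

  # degenerate input exits with an informative error
  zero <- file.path(out, "zero.csv")
  write_release_series(release_series(1:8, rep(0, 8)), zero)
  expect_error(suppressMessages(cmd_fit(list(input = zero), out)),
               "degenerate")
  short <- file.path(out, "short.csv")
  write_release_series(exact_series(100, 0.5, h = 1, span = 3), short)
  expect_error(suppressMessages(
    cmd_fit(list(input = short, method = "central4"), out)), "at least 5")
})

test_that("cmd_sweep covers the default exploration grid", {
  out <- withr::local_tempdir()
  path <- cmd_sweep(list(), out)
  sw <- utils::read.csv(path)
  expect_equal(nrow(unique(sw[, c("K32_per_day", "C2_pct")])), 4)
  # a K32 = 40 profile stays more than 3% below its plateau at day 7
  path2 <- cmd_sweep(list(K32_values = 40, C2_values = 100,
                          time_grid = c(0, 7)), out)
  sw2 <- utils::read.csv(path2)
  day7 <- sw2$release_pct[sw2$time_days == 7]
  expect_lt(day7, 100 - 3)
  expect_error(cmd_sweep(list(K32_values = numeric(0)), out), "empty|positive")
})

test_that("cmd_simulate_sphere writes fields, series and mass diagnostics", {
  out <- withr::local_tempdir()
  cfg <- list(r1 = 0.3, r2 = 1, D1 = 0.5, D2 = 0.2, epsilon = 0.4,
              K32 = 0, C1_init = 1, C3_init = 1, n_r = 12,
              t_grid = seq(0, 1, by = 0.25))
  paths <- suppressMessages(cmd_simulate_sphere(cfg, out))
  series <- read_release_series(paths[["series"]])
  expect_equal(diff(range(series$release_pct)), 0, tolerance = 1e-8)
  fields <- utils::read.csv(paths[["fields"]])
  expect_setequal(unique(fields$phase), c("interior", "matrix", "exterior"))

  cfg0 <- utils::modifyList(cfg, list(C1_init = 0, C3_init = 0))
  p0 <- suppressMessages(cmd_simulate_sphere(cfg0, out))
  expect_equal(max(abs(read_release_series(p0[["series"]])$release_pct)), 0)
})

test_that("the CLI dispatcher parses flags and reports failures", {
  out <- withr::local_tempdir()
  cfg_file <- file.path(out, "run.yaml")
  yaml::write_yaml(list(generate = list(C2_edge = 100, rate_a = 0.5)),
                   cfg_file)
  status <- isg_cli(c("generate", "--config", cfg_file, "--out-dir", out))
  expect_identical(status, 0L)
  expect_true(file.exists(file.path(out, "observed.csv")))
  expect_identical(suppressMessages(isg_cli("no-such-command")), 1L)
  expect_identical(suppressMessages(
    isg_cli(c("fit", "--config", file.path(out, "missing.yaml")))), 1L)
})
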
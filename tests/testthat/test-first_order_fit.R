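test_that("fit_linear_rate recovers (a, b) from exact derivative pairs", {
  t <- c(0, 0.5, 1, 2, 4, 7)
  y <- 100 * (1 - exp(-0.5 * t))
  dy <- 50 - 0.5 * y # analytic: dy = b - a y holds exactly
  est <- fit_linear_rate(y, dy)
  expect_equal(est$a_hat, 0.5, tolerance = 1e-10)
  expect_equal(est$b_hat, 50, tolerance = 1e-10)
  expect_equal(est$n_used, length(y))

  # two exact points determine the line
  est2 <- fit_linear_rate(y[c(1, 4)], dy[c(1, 4)])
  expect_equal(est2$a_hat, 0.5, tolerance = 1e-10)

  expect_error(fit_linear_rate(rep(3, 5), rep(1, 5)), "degenerate")
})

test_that("to_model applies the K32 and plateau identification", {
  m <- to_model(a_hat = 0.7081, b_hat = 0.7081 * 103.5, V3 = 80)
  expect_equal(m$K32, 56.648, tolerance = 1e-10)
  expect_equal(round(m$K32, 1), 56.6) # published rounding: 56.65
  expect_equal(m$C2_edge, 103.5, tolerance = 1e-10)
  expect_error(to_model(a_hat = -0.1, b_hat = 1), "non-physical")
  expect_error(to_model(a_hat = 1, b_hat = 0), "positive")
})

test_that("relative error and r-squared follow their definitions", {
  expect_equal(relative_error(c(3, 4), c(3, 4)), 0)
  expect_equal(relative_error(c(3, 4), c(0, 0)), 1)
  expect_equal(relative_error(c(1, 0), c(0, 1)), sqrt(2), tolerance = 1e-12)
  expect_error(relative_error(c(0, 0), c(1, 1)), "undefined")

  y <- c(1, 2, 3)
  expect_equal(r_squared(y, y), 1)
  expect_equal(r_squared(y, rep(mean(y), 3)), 0)
  expect_equal(r_squared(y, c(1, 2, 4)), 0.5)
  expect_error(r_squared(c(2, 2), c(1, 2)), "constant")
})

test_that("noise-free pipelines recover the generator to stencil accuracy", {
  # O(h^4): bias ~ a^4 h^4 / 30, far below 1e-6 relative at h = 0.01
  s <- exact_series(100, 0.5, h = 0.01)
  f <- fit_release(s, "O(h4)")
  expect_equal(f$model$K32, 40, tolerance = 1e-6)
  expect_equal(f$model$C2_edge, 100, tolerance = 1e-6)
  expect_lt(f$rel_err, 1e-6)
  expect_gt(f$r_squared, 1 - 1e-10)
})

test_that("the forward estimator obeys its closed-form bias law", {
  # on exact exponential data the O(h) rate estimate is (1 - e^{-a h})/h
  # at ANY h, and the plateau b/a is exact for both stencils: the bias
  # factors out of the ratio
  a <- 0.7081; C <- 103.5
  for (h in c(0.2, 0.05, 0.01)) {
    s <- exact_series(C, a, h = h)
    ff <- fit_release(s, "O(h)")
    expect_equal(ff$a_hat, (1 - exp(-a * h)) / h, tolerance = 1e-8)
    expect_equal(ff$model$C2_edge, C, tolerance = 1e-8)
    fc <- fit_release(s, "O(h4)")
    expect_equal(fc$model$C2_edge, C, tolerance = 1e-8)
  }
})

test_that("rate-estimate convergence is linear for O(h), quartic for O(h^4)", {
  a <- 0.5; C <- 100
  hs <- c(0.1, 0.05, 0.025, 0.0125)
  err <- sapply(hs, function(h) {
    s <- exact_series(C, a, h = h)
    c(abs(fit_release(s, "O(h)")$a_hat - a),
      abs(fit_release(s, "O(h4)")$a_hat - a))
  })
  slope_f <- coef(lm(log(err[1, ]) ~ log(hs)))[2]
  slope_c <- coef(lm(log(err[2, ]) ~ log(hs)))[2]
  expect_lt(abs(slope_f - 1), 0.2)
  expect_lt(abs(slope_c - 4), 0.2)
})

test_that("all eight published fits are recovered from their own equations", {
  for (i in seq_len(nrow(ref_params))) {
    row <- ref_params[i, ]
    h <- h_for_method(row$method)
    s <- exact_series(row$C2_edge, row$rate_a, h = h)
    f <- fit_release(s, row$method, V3 = row$V3)
    expect_lt(abs(f$model$K32 - row$K32) / row$K32, 0.005)
    expect_lt(abs(f$model$C2_edge - row$C2_edge) / row$C2_edge, 0.001)
  }
})

test_that("irregular schedules require (and use) resampling", {
  m <- first_order_model(C2_edge = 103.5, rate_a = 0.7081)
  sparse <- evaluate_release_curve(m, c(0.5, 1, 2, 3, 4, 5, 6, 7))
  expect_error(fit_release(sparse, "O(h)"), "resample_h")
  f <- fit_release(sparse, "forward", resample_h = 0.05)
  # interpolation error on 8 points dominates; recovery is approximate
  expect_lt(abs(f$model$K32 - m$K32) / m$K32, 0.05)
  expect_lt(abs(f$model$C2_edge - m$C2_edge) / m$C2_edge, 0.01)
  expect_gt(f$r_squared, 0.999)
})

test_that("degenerate and insufficient inputs fail loudly", {
  z <- release_series(seq(0, 7, by = 1), rep(0, 8))
  expect_error(fit_release(z, "O(h)"), "degenerate")
  four <- exact_series(100, 0.5, h = 1, span = 3)
  expect_error(fit_release(four, "O(h4)"), "at least 5")
})

test_that("noisy assay replicates average to the true rate", {
  m <- first_order_model(C2_edge = 88.6, rate_a = 0.8095)
  proto <- cup_protocol(schedule = seq(0.01, 7, by = 0.01))
  a_hats <- vapply(seq_len(200), function(i) {
    d <- make_dataset(m, proto,
                      noise_spec("multiplicative-normal", sd = 0.02,
                                 seed = 1000 + i))
    fit_release(d$observed, "O(h4)")$a_hat
  }, numeric(1))
  se <- sd(a_hats) / sqrt(length(a_hats))
  expect_lt(abs(mean(a_hats) - m$rate_a), 3 * se)
})

test_that("fit reports serialize the estimates", {
  f <- fit_release(exact_series(100, 0.5, h = 0.01), "O(h4)")
  path <- withr::local_tempfile(fileext = ".txt")
  write_fit_report(f, path, label = "demo")
  lines <- readLines(path)
  k32 <- as.numeric(sub("K32_per_day = ", "",
                        lines[grepl("^K32_per_day", lines)]))
  expect_equal(k32, 40, tolerance = 1e-6)
  expect_true(any(grepl("^formulation = demo$", lines)))
})
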
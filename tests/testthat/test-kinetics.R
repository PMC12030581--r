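test_that("model functions match closed-form values and reject bad input", {
  expect_equal(kp_release(0, k = 0.3, n = 0.7), 0)
  expect_equal(kp_release(0.5, k = 1, n = 1), 0.5)
  expect_equal(kp_release(4, k = 0.1, n = 0.5), 0.2)
  expect_equal(weibull_release(0, tau = 5, beta = 2), 0)
  expect_equal(weibull_release(24, tau = 24, beta = 1), 1 - exp(-1))
  expect_lt(weibull_release(60, tau = 2, beta = 1), 1)  # 30 tau, still < 1
  expect_equal(weibull_release(60, tau = 2, beta = 1), 1 - exp(-30))
  expect_error(kp_release(-1, 0.1, 0.5), "time")
  expect_error(weibull_release(1, -2, 1), "finite and > 0")
})

test_that("kp_release is increasing and weibull_release monotone within [0,1)", {
  t <- seq(0, 500, length.out = 200)
  for (p in list(c(0.05, 0.4), c(0.01, 1.2), c(0.2, 0.8))) {
    y <- kp_release(t, p[1], p[2])
    expect_true(all(diff(y) > 0))
  }
  for (p in list(c(12, 0.6), c(100, 1.5), c(3, 1))) {
    y <- weibull_release(t, p[1], p[2])
    expect_true(all(diff(y) >= 0))
    expect_true(all(y >= 0 & y <= 1))     # analytic sup is 1, never exceeded
    expect_lt(weibull_release(5 * p[1], p[1], p[2]), 1)
  }
})

test_that("time rescaling with matching parameter rescaling leaves curves unchanged", {
  t <- c(0.5, 1, 2, 4, 8, 16)
  c_scale <- 3.7
  expect_equal(weibull_release(c_scale * t, tau = c_scale * 6, beta = 0.8),
               weibull_release(t, tau = 6, beta = 0.8))
  expect_equal(kp_release(c_scale * t, k = 0.1 * c_scale^-0.6, n = 0.6),
               kp_release(t, k = 0.1, n = 0.6))
})

test_that("noise-free parameter recovery is exact to 1e-6 for both models", {
  t <- exp(seq(log(0.5), log(72), length.out = 20))
  kp_truth <- list(c(0.05, 0.6), c(0.12, 0.45), c(0.02, 0.9))
  for (p in kp_truth) {
    curve <- data.frame(time_h = t, release_pct = 100 * kp_release(t, p[1], p[2]))
    f <- fit_kp(curve)
    expect_true(f$converged)
    expect_equal(unname(f$params), p, tolerance = 1e-6)
    expect_lt(f$mse, 1e-10)
    expect_gt(f$r2, 1 - 1e-10)
  }
  wb_truth <- list(c(24, 0.8), c(6, 1.3), c(48, 0.6))
  for (p in wb_truth) {
    curve <- data.frame(time_h = t, release_pct = 100 * weibull_release(t, p[1], p[2]))
    f <- fit_weibull(curve)
    expect_equal(unname(f$params), p, tolerance = 1e-6)
    expect_lt(f$mse, 1e-10)
  }
})

test_that("log-log linearization of a noise-free power-law curve recovers the exponent", {
  t <- exp(seq(log(1), log(64), length.out = 15))
  y <- 100 * kp_release(t, 0.05, 0.6)
  slope <- unname(coef(lm(log(y / 100) ~ log(t)))[2])
  expect_equal(slope, 0.6, tolerance = 1e-10)
})

test_that("first-order curves are identified as beta = 1 and multi-starts agree", {
  t <- seq(1, 30, length.out = 15)
  curve <- data.frame(time_h = t, release_pct = 100 * weibull_release(t, 8, 1))
  f <- fit_weibull(curve)
  expect_equal(unname(f$params["beta"]), 1, tolerance = 1e-4)
  expect_identical(f$mechanism, "first_order")

  # multi-start consistency: different start counts reach the same optimum
  fits <- lapply(c(2L, 4L, 6L, 8L, 5L), function(ns)
    fit_weibull(curve, n_starts = ns))
  taus <- vapply(fits, function(f) unname(f$params["tau"]), numeric(1))
  expect_lt(max(taus) - min(taus), 1e-6)
})

test_that("degenerate curves are reported honestly", {
  flat <- data.frame(time_h = c(1, 2, 3, 4), release_pct = rep(50, 4))
  f <- fit_kp(flat)
  expect_true(is.na(f$r2) || f$r2 <= 0 || !f$converged)
  zero <- data.frame(time_h = 1:4, release_pct = rep(0, 4))
  expect_error(fit_kp(zero), "all-zero")
  expect_error(fit_kp(flat[1:2, ]), "at least 3")
})

test_that("mechanism rules follow the exponent and shape thresholds", {
  expect_identical(classify_mechanism("kp", 0.3), "fickian")
  expect_identical(classify_mechanism("kp", 0.5), "fickian")
  expect_identical(classify_mechanism("kp", 0.75), "anomalous")
  expect_identical(classify_mechanism("kp", 1.0), "case_II")
  expect_identical(classify_mechanism("kp", 1.005), "case_II")
  expect_identical(classify_mechanism("kp", 1.3), "super_case_II")
  expect_identical(classify_mechanism("weibull", 0.5), "diffusion_controlled")
  expect_identical(classify_mechanism("weibull", 1.0), "first_order")
  expect_identical(classify_mechanism("weibull", 1.4), "complex")
  expect_error(classify_mechanism("kp", -0.2), "positive")
})

test_that("fitter's reported MSE equals the evaluation metric on its own predictions", {
  t <- exp(seq(log(1), log(48), length.out = 12))
  curve <- data.frame(time_h = t,
                      release_pct = 100 * weibull_release(t, 10, 0.9) +
                        c(1, -2, 0.5, -1, 2, 0, 1, -0.5, 0.3, -1.2, 0.8, 0))
  f <- fit_weibull(curve)
  yhat <- 100 * weibull_release(t, f$params["tau"], f$params["beta"])
  expect_equal(f$mse, metric_mse(curve$release_pct, yhat), tolerance = 1e-12)
  expect_equal(f$r2, metric_r2(curve$release_pct, yhat), tolerance = 1e-12)
})

test_that("fit_dataset fits every sample under both models", {
  gen <- generate_dataset(generator_config(n_samples = 4, noise_sd = 1,
                                           seed = 8))
  fits <- fit_dataset(gen$dataset, model = "both")
  expect_equal(nrow(fits), 8L)
  expect_setequal(unique(fits$model), c("kp", "weibull"))
  expect_true(all(fits$mse >= 0))
  expect_true(all(fits$r2 <= 1))
})
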
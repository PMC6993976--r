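# Serum decay fitting, half-life conversion and the exposure-time transform.

test_that("an exact log10-linear series is recovered perfectly", {
  t <- seq(0.5, 10, by = 0.5)
  conc <- 10^(3 - 0.0301 * t)
  fit <- fit_serum_decay(t, conc)
  expect_equal(fit$slope_log10, -0.0301, tolerance = 1e-12)
  expect_equal(fit$intercept_log10, 3, tolerance = 1e-12)
  expect_equal(fit$half_life, 10, tolerance = 1e-12)  # 0.301 / 0.0301
  expect_equal(fit$r_squared, 1, tolerance = 1e-9)
})

test_that("half-life is recovered for exact exponentials, limited only by the rounded constant", {
  for (T_half in c(2, 5, 10, 20)) {
    t <- 1:8
    conc <- 800 * 2^(-t / T_half)
    fit <- fit_serum_decay(t, conc)
    expect_equal(fit$half_life, T_half, tolerance = 1e-3)
    # the k/half-life pair is consistent up to the rounding of 0.301
    expect_equal(fit$half_life * fit$k, log(2), tolerance = 1e-3)
    # the high-precision path removes even that
    expect_equal(fit_serum_decay(t, conc, precise = TRUE)$half_life, T_half,
                 tolerance = 1e-12)
  }
})

test_that("half-life estimation is accurate under lognormal serum noise", {
  # Monte-Carlo oracle: k = 0.14/min, sigma_log10 = 0.05, n = 20
  k <- 0.14
  t <- seq(0.5, 10, length.out = 20)
  true_hl <- log(2) / k
  set.seed(11)
  hits <- vapply(1:500, function(i) {
    conc <- 10^(log10(900) - (k / log(10)) * t + rnorm(20, 0, 0.05))
    fit <- fit_serum_decay(t, conc)
    abs(fit$half_life - true_hl) / true_hl < 0.15
  }, logical(1))
  expect_gte(mean(hits), 0.95)
})

test_that("non-positive concentrations are excluded with a warning; tiny samples error", {
  t <- 1:6
  conc <- c(100, 80, 0, 50, -2, 30)
  expect_warning(fit <- fit_serum_decay(t, conc), "non-positive")
  expect_equal(fit$n_points, 4)
  expect_error(suppressWarnings(fit_serum_decay(1:3, c(10, 0, 0))), ">= 3")
})

test_that("fit window restricts the points used", {
  t <- 1:10
  conc <- c(5000, 2000, 10^(3 - 0.05 * (3:10)))  # nonlinear early phase
  fit <- fit_serum_decay(t, conc, window = c(3, 10))
  expect_equal(fit$n_points, 8)
  expect_equal(fit$slope_log10, -0.05, tolerance = 1e-10)
})

test_that("exposure time has the correct limits and closed form", {
  expect_equal(exposure_time(0, 10), 10)            # constant serum
  expect_equal(exposure_time(0, c(1, 5, 10)), c(1, 5, 10))
  # 5-min half-life at t = 10: (e^{kt}-1)/k, cross-checked by quadrature
  k <- log(2) / 5
  cf <- exposure_time(k, 10)
  quad <- integrate(function(x) exp(-k * x), 0, 10, rel.tol = 1e-12)$value /
    exp(-k * 10)
  expect_equal(cf, quad, tolerance = 1e-9)
  expect_equal(cf, 21.64, tolerance = 1e-3)
  # continuity at k -> 0
  expect_equal(exposure_time(1e-12, 10), 10, tolerance = 1e-9)
})

test_that("exposure time exceeds clock time for a decaying curve", {
  for (k in c(0.01, 0.1, 0.5, 1)) {
    t <- c(0.5, 3, 10)
    expect_true(all(exposure_time(k, t) >= t))
  }
})

test_that("analytic and trapezoid paths agree on fitted curves", {
  t <- seq(0.5, 10, length.out = 12)
  for (k in c(0.03, 0.14, 0.3)) {
    fit <- fit_serum_decay(t, 700 * exp(-k * t))
    tt <- seq(0.5, 10, length.out = 7)
    a <- exposure_time(fit, tt, method = "analytic")
    e <- exposure_time(fit, tt, method = "empirical")
    expect_equal(e, a, tolerance = 1e-6)
  }
})

test_that("exposure time rejects non-positive times", {
  expect_error(exposure_time(0.1, 0))
  expect_error(exposure_time(0.1, -1))
})

test_that("a fast early mixing phase biases full-range fits but not windowed ones", {
  cfg <- tiny_config(n_per_group = 12)
  cfg$biexponential <- TRUE
  cfg <- validate_sim_config(cfg)
  dat <- simulate_study(cfg)
  s <- dat$serum[dat$serum$genotype == "E3", ]
  conc <- s$serum_tracer_cpm / s$aliquot_ul
  full <- fit_serum_decay(s$time_min, conc)
  late <- fit_serum_decay(s$time_min, conc, window = c(4, 10))
  k_slow <- 0.14
  expect_gt(full$k, k_slow * 1.05)           # early phase steepens the fit
  expect_equal(late$k, k_slow, tolerance = 0.02)
})
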
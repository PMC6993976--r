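# The Patlak estimator and its model-object methods.

test_that("collinear points give the exact slope/intercept and r = 1", {
  fit <- patlak_fit(c(1, 2, 3, 4), c(8, 9, 10, 11))
  expect_equal(fit$ki, 1)
  expect_equal(fit$vi, 7)
  expect_equal(fit$r, 1)
  expect_true(fit$transport_significant)
  expect_true(fit$vi_measurable)
  expect_equal(unname(coef(fit)), c(1, 7))
  expect_equal(predict(fit, c(0, 10)), c(7, 17))
})

test_that("fits require 3 points and non-degenerate exposure times", {
  expect_error(patlak_fit(c(1, 2), c(1, 2)), ">= 3")
  expect_error(patlak_fit(c(2, 2, 2), c(1, 2, 3)), "identical")
  # window filtering can reduce below the minimum
  expect_error(patlak_fit(1:10, 1:10, window = c(4, 5)), ">= 3")
})

test_that("noiseless simulated groups recover ki and vi to machine accuracy", {
  cfg <- tiny_config()
  dat <- simulate_study(cfg)
  res <- run_pipeline(dat)
  for (i in seq_len(nrow(res$regional_ki))) {
    g <- res$regional_ki$group[i]; r <- res$regional_ki$region[i]
    expect_equal(res$regional_ki$ki[i], cfg$ki_true[r, g], tolerance = 1e-9)
    expect_equal(res$regional_vi$vi[i], cfg$vi_true[r, g], tolerance = 1e-9)
  }
})

test_that("a flat noiseless line is reported as ns with nm binding", {
  expt <- c(1, 3, 5, 7)
  fit <- patlak_fit(expt, rep(4.2, 4))
  expect_false(fit$transport_significant)
  expect_false(fit$vi_measurable)
  expect_equal(fit$ki, 0, tolerance = 1e-12)
  expect_equal(fit$vi, 4.2, tolerance = 1e-12)
})

test_that("a significantly negative slope is not reported as transport", {
  fit <- patlak_fit(c(1, 2, 3, 4, 5), c(10, 8, 6, 4, 2))
  expect_lt(fit$p_slope, 0.05)
  expect_false(fit$transport_significant)
})

test_that("slope-test size is nominal under the regression model", {
  # homoscedastic Gaussian responses around a flat line: the exact setting of
  # the t test on the slope
  set.seed(64)
  x <- exposure_time(0.139, seq(0.5, 10, length.out = 10))
  reject <- vapply(1:2000, function(i) {
    patlak_fit(x, 5 + rnorm(10))$p_slope < 0.05
  }, logical(1))
  expect_gte(mean(reject), 0.035)
  expect_lte(mean(reject), 0.065)
})

test_that("slope-test type-I error stays close to nominal under counting noise", {
  # groups simulated with ki = 0 and Poisson counting noise; the counting
  # variance grows along the line, which makes the OLS test mildly
  # anti-conservative, so the band is wider than the nominal one above
  cfg <- tiny_config(noise_model = "poisson_counts", n_per_group = 10,
                     ki = c(0, 0), vi = c(5, 5), vv = c(6, 6))
  reject <- logical(2000)
  flagged <- logical(2000)
  for (i in 1:2000) {
    dat <- simulate_study(cfg, seed = i)
    s <- dat$serum[dat$serum$genotype == "E3", ]
    r <- dat$regions[dat$regions$region == "Frontal Cortex" &
                       dat$regions$id %in% s$id, ]
    sf <- fit_serum_decay(s$time_min, s$serum_tracer_cpm / s$aliquot_ul)
    expt <- exposure_time(sf, s$time_min)
    j <- match(r$id, s$id)
    d <- delta_bs(
      brain_serum_ratio(r$tracer_cpm, r$weight_g, s$serum_tracer_cpm[j],
                        s$aliquot_ul[j]),
      brain_serum_ratio(r$marker_cpm, r$weight_g, s$serum_marker_cpm[j],
                        s$aliquot_ul[j])
    )
    fit <- patlak_fit(expt[j], d)
    reject[i] <- fit$p_slope < 0.05
    flagged[i] <- fit$transport_significant
  }
  expect_gte(mean(reject), 0.03)
  expect_lte(mean(reject), 0.09)
  # the transport flag additionally requires a positive slope, so under the
  # null it fires at roughly half the two-sided rate
  expect_lt(mean(flagged), mean(reject))
})

test_that("patlak model methods are coherent", {
  set.seed(2)
  x <- seq(1, 20, length.out = 12)
  y <- 3 + 0.8 * x + rnorm(12, 0, 0.5)
  fit <- patlak_fit(x, y, animal_id = sprintf("m%02d", 1:12))
  expect_s3_class(fit, "patlak_fit")
  expect_equal(residuals(fit) + predict(fit), y, ignore_attr = TRUE)
  sm <- summary(fit)
  expect_equal(sm$coefficients["Ki", "Estimate"], fit$ki)
  sims <- simulate(fit, nsim = 3, seed = 1)
  expect_equal(dim(sims), c(12, 3))
  expect_output(print(fit), "Ki")
})
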
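# Forward simulator: determinism, self-consistency of the noiseless forward
# model, noise scaling, and design guards.

test_that("identical config and seed give bit-identical datasets", {
  cfg <- tiny_config(noise_model = "poisson_counts", dose_cv = 0.05, seed = 42)
  d1 <- simulate_study(cfg)
  d2 <- simulate_study(cfg)
  expect_identical(d1$serum, d2$serum)
  expect_identical(d1$regions, d2$regions)
  d3 <- simulate_study(cfg, seed = 43)
  expect_false(identical(d1$regions$tracer_cpm, d3$regions$tracer_cpm))
})

test_that("default design produces the full study layout", {
  cfg <- default_study_config(seed = 3)
  dat <- simulate_study(cfg)
  expect_equal(nrow(dat$serum), 40)             # 4 groups x 10 mice
  expect_equal(sort(unique(dat$regions$region)), sort(brain_regions()))
  expect_equal(nrow(dat$regions), 40 * 11)
  expect_true(all(dat$serum$aliquot_ul == 50))
  expect_true(all(dat$serum$time_min >= 0.5 & dat$serum$time_min <= 10))
  expect_true(all(table(dat$regions$id) == 11))
  expect_no_error(validate_study(dat, canonical = TRUE))
})

test_that("zero kinetic parameters give zero brain counts", {
  cfg <- tiny_config(ki = c(0, 0), vi = c(0, 0), vv = c(0, 0))
  dat <- simulate_study(cfg)
  expect_true(all(dat$regions$tracer_cpm == 0))
  expect_true(all(dat$regions$marker_cpm == 0))
  expect_true(all(dat$serum$serum_tracer_cpm > 0))
})

test_that("noiseless marker B/S equals vv and delta B/S lies on the Patlak line", {
  cfg <- tiny_config()
  dat <- simulate_study(cfg)
  s <- dat$serum
  key <- paste(s$genotype, s$sex, sep = ".")
  k <- unname(cfg$k_clear_tracer[key])
  i <- match(dat$regions$id, s$id)
  bs_mk <- brain_serum_ratio(dat$regions$marker_cpm, dat$regions$weight_g,
                             s$serum_marker_cpm[i], s$aliquot_ul[i])
  bs_tr <- brain_serum_ratio(dat$regions$tracer_cpm, dat$regions$weight_g,
                             s$serum_tracer_cpm[i], s$aliquot_ul[i])
  vv <- cfg$vv_true[cbind(dat$regions$region, key[i])]
  expect_equal(bs_mk, vv, tolerance = 1e-9)
  # oracle for the exposure integral: closed form of the mono-exponential
  expt <- (exp(k[i] * s$time_min[i]) - 1) / k[i]
  ki <- cfg$ki_true[cbind(dat$regions$region, key[i])]
  vi <- cfg$vi_true[cbind(dat$regions$region, key[i])]
  expect_equal(delta_bs(bs_tr, bs_mk), ki * expt + vi, tolerance = 1e-9)
})

test_that("Poisson serum-count CV matches 1/sqrt(expected) across seeds", {
  cfg <- tiny_config(noise_model = "poisson_counts", n_per_group = 3)
  draws <- vapply(1:500, function(s) {
    simulate_study(cfg, seed = s)$serum$serum_tracer_cpm[3]
  }, numeric(1))
  lambda <- mean(draws)
  expect_gt(lambda, 50)  # guards the fixture itself
  cv_emp <- sd(draws) / mean(draws)
  expect_equal(cv_emp, 1 / sqrt(lambda), tolerance = 0.2)
})

test_that("designs whose serum counts could hit zero are rejected", {
  cfg <- tiny_config(noise_model = "poisson_counts")
  cfg$c0_tracer <- 0.002  # ~0.1 expected counts in the aliquot at t = 0
  expect_error(simulate_study(cfg), "unusable design")
  cfg$noise_model <- "none"  # deterministic model has no zero-count risk
  expect_no_error(simulate_study(validate_sim_config(cfg)))
})

test_that("config invariants are enforced", {
  expect_error(tiny_config(ki = c(-1, 1)), "ki_true")
  expect_error(tiny_config(vv = c(-1, 1)), "vv_true")
  cfg <- tiny_config()
  cfg$time_schedule <- c(0, 5)
  expect_error(validate_sim_config(cfg), "strictly positive")
  cfg <- tiny_config()
  cfg$region_weights$mean_g[1] <- -0.1
  expect_error(validate_sim_config(cfg), "weights must be positive")
  # negative vi is allowed only by explicit configuration
  expect_no_error(tiny_config(vi = c(-0.5, 1)))
})

test_that("lognormal noise is mean-preserving on brain counts", {
  cfg <- tiny_config(noise_model = "lognormal_cv", n_per_group = 3)
  cfg$noise_cv <- 0.1
  noiseless <- simulate_study(tiny_config(n_per_group = 3))
  draws <- vapply(1:400, function(s) {
    simulate_study(cfg, seed = s)$regions$tracer_cpm[1]
  }, numeric(1))
  expect_equal(mean(draws), noiseless$regions$tracer_cpm[1], tolerance = 0.02)
})

test_that("the default config carries the published group-level estimates", {
  cfg <- default_study_config()
  expect_equal(cfg$vv_true["Pons/Medulla", "E3.F"], 10.99)
  expect_equal(unname(cfg$ki_true["Striatum", ]), rep(0, 4))
  expect_equal(cfg$ki_true["Whole Brain", "E3.F"], 1.128)
  expect_equal(cfg$vi_true["Hypothalamus", "E3.M"], 8.45)
  # truth matrices cover all groups and every simulated region
  expect_true(all(cfg$region_weights$region %in% rownames(cfg$ki_true)))
})
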
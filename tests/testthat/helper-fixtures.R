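# Small in-code fixtures used across the suite.

# A reduced two-group study over three canonical regions; fast to simulate
# but structurally identical to the full design.
tiny_config <- function(noise_model = "none", dose_cv = 0, seed = 1L,
                        n_per_group = 6,
                        ki = c(1.2, 0.6), vi = c(4, 5), vv = c(6, 7),
                        k_clear = c(A = 0.14, B = 0.07)) {
  groups <- data.frame(genotype = c("E3", "E4"), sex = c("F", "M"),
                       stringsAsFactors = FALSE)
  regions <- c("Frontal Cortex", "Hypothalamus", "Cerebellum")
  mk <- function(vals) {
    matrix(rep(vals, each = length(regions)) * c(1, 0.8, 1.3),
           nrow = length(regions), ncol = 2,
           dimnames = list(regions, c("E3.F", "E4.M")))
  }
  simulation_config(
    groups = groups, n_per_group = n_per_group,
    time_schedule = seq(0.5, 10, length.out = n_per_group),
    c0_tracer = 1e6 / 1500, c0_marker = 5e5 / 1500,
    k_clear_tracer = c(E3.F = unname(k_clear[1]), E4.M = unname(k_clear[2])),
    k_clear_marker = 0.005,
    ki_true = mk(ki), vi_true = mk(vi), vv_true = mk(vv),
    region_weights = data.frame(
      region = regions, mean_g = c(0.045, 0.012, 0.06),
      sd_g = c(0.004, 0.001, 0.006), stringsAsFactors = FALSE
    ),
    noise_model = noise_model, dose_cv = dose_cv, seed = seed
  )
}

# One-group configuration at the full study design (n = 10, all 11 regions,
# times spread 0.5-10 min) used for stochastic-recovery checks.
one_group_default <- function(noise_model = "poisson_counts", dose_cv = 0.05,
                              seed = 1L) {
  cfg <- default_study_config(noise_model = noise_model, dose_cv = dose_cv,
                              seed = seed)
  cfg$groups <- cfg$groups[1, , drop = FALSE]  # E3 female
  validate_sim_config(cfg)
  cfg
}
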
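# Two-compartment forward model for a single-terminal-timepoint dual-tracer
# study. Serum concentration decays mono-exponentially; brain content in a
# region is the sum of an irreversible influx term (Ki * integral of Cp), a
# reversible binding term (Vi * Cp) and the residual vascular blood (Vv * Cp);
# the vascular marker only occupies the vascular space.

# ∫0^t exp(-k tau) dtau, stable at k -> 0.
.int_decay <- function(k, t) ifelse(k == 0, t, -expm1(-k * t) / k)

#' Simulate a dual-tracer BBB study
#'
#' Generates a complete study dataset from a [simulation_config()]: one
#' terminal observation per animal (serum aliquot counts for both isotopes)
#' plus per-region brain weights and counts for both isotopes. Terminal times
#' are assigned deterministically round-robin over the schedule within each
#' group. The forward model for the test tracer in region r at time t is
#'
#' `brain cpm/g = Ki * dose * c0 * (1 - exp(-k t)) / k + (Vi + Vv) * Cp(t)`
#'
#' with `Cp(t) = dose * c0 * exp(-k t)` the serum concentration, while the
#' vascular marker contributes `Vv * Cp_marker(t)` per gram. Counts are the
#' per-gram values times the region weight (serum counts: concentration times
#' aliquot volume), with the configured noise model applied last. Under
#' `noise_model = "none"` counting noise is off and region weights sit at
#' their means; with `dose_cv = 0` as well, the dataset is the exact
#' deterministic forward model and every downstream ratio recovers the
#' configured truth exactly.
#'
#' With Poisson noise, configurations whose expected serum counts are low
#' enough that more than 1% of draws would be zero are rejected: such a
#' design cannot yield valid brain/serum ratios.
#'
#' @param config a `sim_config`.
#' @param seed optional override of `config$seed`.
#' @return an object of class `study_dataset`: a list with data frames
#'   `serum` (one row per animal: `id`, `genotype`, `sex`, `time_min`,
#'   `serum_tracer_cpm`, `serum_marker_cpm`, `aliquot_ul`) and `regions`
#'   (`id`, `region`, `weight_g`, `tracer_cpm`, `marker_cpm`), the originating
#'   `config`, and a `provenance` list (seed, noise model, config hash).
#' @export
#' @examples
#' cfg <- default_study_config(noise_model = "none")
#' dat <- simulate_study(cfg)
#' nrow(dat$serum)    # 40 animals
#' nrow(dat$regions)  # 11 regions each
simulate_study <- function(config, seed = NULL) {
  config <- validate_sim_config(config)
  if (!is.null(seed)) config$seed <- as.integer(seed)

  g <- config$groups
  nper <- config$n_per_group
  sched <- rep_len(config$time_schedule, nper)
  serum <- do.call(rbind, lapply(seq_len(nrow(g)), function(i) {
    data.frame(
      id = sprintf("%s_%s_%02d", g$genotype[i], g$sex[i], seq_len(nper)),
      genotype = g$genotype[i], sex = g$sex[i], time_min = sched,
      stringsAsFactors = FALSE
    )
  }))
  n <- nrow(serum)
  key <- .group_key(serum$genotype, serum$sex)
  k_tr <- .lookup_rate(config$k_clear_tracer, key)
  k_mk <- .lookup_rate(config$k_clear_marker, key)
  rw <- config$region_weights
  nreg <- nrow(rw)

  .with_seed(config$seed, {
    # fixed draw order: dose factors, region weights, then count noise
    dose <- if (config$dose_cv > 0) rlnorm(n, 0, config$dose_cv) else rep(1, n)

    weight <- if (config$noise_model == "none") {
      rep(rw$mean_g, times = n)
    } else {
      # lognormal with matched mean/sd keeps weights strictly positive
      mu <- rep(rw$mean_g, times = n)
      sdg <- rep(rw$sd_g, times = n)
      s2 <- log(1 + (sdg / mu)^2)
      rlnorm(n * nreg, log(mu) - s2 / 2, sqrt(s2))
    }

    if (isTRUE(config$biexponential)) {
      # fast early mixing phase on the test tracer only
      f <- config$frac_fast; kf <- config$k_fast
      tm <- serum$time_min
      cp_tr <- dose * config$c0_tracer *
        (f * exp(-kf * tm) + (1 - f) * exp(-k_tr * tm))
      int_cp <- dose * config$c0_tracer *
        (f * .int_decay(kf, tm) + (1 - f) * .int_decay(k_tr, tm))
    } else {
      cp_tr <- dose * config$c0_tracer * exp(-k_tr * serum$time_min)
      int_cp <- dose * config$c0_tracer * .int_decay(k_tr, serum$time_min)
    }
    cp_mk <- dose * config$c0_marker * exp(-k_mk * serum$time_min)

    serum_tr_exp <- cp_tr * config$aliquot_volume
    serum_mk_exp <- cp_mk * config$aliquot_volume

    if (config$noise_model == "poisson_counts") {
      lam_min <- min(serum_tr_exp, serum_mk_exp)
      if (exp(-lam_min) > 0.01)
        stop("unusable design: expected serum counts as low as ",
             signif(lam_min, 3),
             " cpm would give zero-count aliquots in > 1% of draws",
             call. = FALSE)
    }

    # per-gram expectations, region-major within animal
    idx <- rep(seq_len(n), each = nreg)
    reg <- rep(rw$region, times = n)
    ki <- config$ki_true[cbind(reg, key[idx])]
    vi <- config$vi_true[cbind(reg, key[idx])]
    vv <- config$vv_true[cbind(reg, key[idx])]
    perg_tr <- ki * int_cp[idx] + (vi + vv) * cp_tr[idx]
    perg_mk <- vv * cp_mk[idx]
    brain_tr_exp <- perg_tr * weight
    brain_mk_exp <- perg_mk * weight

    noisy <- function(expected) {
      switch(config$noise_model,
        none = expected,
        poisson_counts = rpois(length(expected), expected),
        lognormal_cv = {
          s2 <- log(1 + config$noise_cv^2)
          expected * rlnorm(length(expected), -s2 / 2, sqrt(s2))
        }
      )
    }
    serum$serum_tracer_cpm <- as.numeric(noisy(serum_tr_exp))
    serum$serum_marker_cpm <- as.numeric(noisy(serum_mk_exp))
    serum$aliquot_ul <- config$aliquot_volume
    regions <- data.frame(
      id = serum$id[idx], region = reg, weight_g = weight,
      tracer_cpm = as.numeric(noisy(brain_tr_exp)),
      marker_cpm = as.numeric(noisy(brain_mk_exp)),
      stringsAsFactors = FALSE
    )

    structure(
      list(
        serum = serum, regions = regions, config = config,
        provenance = list(
          seed = config$seed, noise_model = config$noise_model,
          config_hash = .fnv1a(config[setdiff(names(config), "seed")]),
          package_version = as.character(utils::packageVersion("patlakr"))
        )
      ),
      class = "study_dataset"
    )
  })
}

#' @export
print.study_dataset <- function(x, ...) {
  cat("Dual-tracer BBB study dataset\n")
  cat("  animals: ", nrow(x$serum), " (",
      length(unique(.group_key(x$serum$genotype, x$serum$sex))), " groups)\n", sep = "")
  cat("  regions per animal: ", length(unique(x$regions$region)), "\n", sep = "")
  cat("  terminal times: ", min(x$serum$time_min), "-", max(x$serum$time_min),
      " min\n", sep = "")
  if (!is.null(x$provenance))
    cat("  noise model: ", x$provenance$noise_model,
        ", seed ", x$provenance$seed, "\n", sep = "")
  invisible(x)
}

# Shared structural validation used by the reader and the pipeline.
# Returns a character vector of problems (empty when valid).
.study_problems <- function(serum, regions, canonical_regions = NULL) {
  problems <- character()
  if (!nrow(serum)) return("no animals in dataset")
  if (anyDuplicated(serum$id))
    problems <- c(problems, paste0("duplicate animal id: ",
      paste(unique(serum$id[duplicated(serum$id)]), collapse = ", ")))
  if (any(!is.finite(serum$time_min)) || any(serum$time_min <= 0))
    problems <- c(problems, "terminal times must be positive")
  if (any(serum$aliquot_ul <= 0))
    problems <- c(problems, "aliquot volumes must be positive")
  orphan <- setdiff(regions$id, serum$id)
  if (length(orphan))
    problems <- c(problems, paste0("region rows for unknown animal id: ",
                                   paste(orphan, collapse = ", ")))
  dup <- duplicated(regions[c("id", "region")])
  if (any(dup))
    problems <- c(problems, paste0("duplicate (id, region) rows: ",
      paste(unique(paste(regions$id[dup], regions$region[dup])), collapse = "; ")))
  if (!is.null(canonical_regions)) {
    bad <- setdiff(unique(regions$region), canonical_regions)
    if (length(bad))
      problems <- c(problems, paste0("unknown region name(s): ",
                                     paste(bad, collapse = ", ")))
  }
  neg <- with(regions, !is.finite(weight_g) | weight_g <= 0)
  if (any(neg))
    problems <- c(problems, "non-positive region weights")
  if (any(regions$tracer_cpm < 0) || any(regions$marker_cpm < 0))
    problems <- c(problems, "negative brain counts")
  if (any(serum$serum_tracer_cpm < 0) || any(serum$serum_marker_cpm < 0))
    problems <- c(problems, "negative serum counts")
  # every animal should carry the same region set
  sets <- tapply(regions$region, regions$id, function(r) paste(sort(r), collapse = "|"))
  if (length(unique(sets)) > 1)
    problems <- c(problems, "animals do not share a common region set")
  problems
}

#' Validate a study dataset
#'
#' Runs the structural invariants of the study schema (unique animal ids,
#' positive times/weights/volumes, no orphan or duplicate region rows,
#' non-negative counts, a common region set across animals) and reports all
#' violations together.
#'
#' @param dataset a `study_dataset`.
#' @param canonical if `TRUE`, additionally require region names to come from
#'   [brain_regions()].
#' @return `dataset`, invisibly.
#' @export
validate_study <- function(dataset, canonical = FALSE) {
  stopifnot(inherits(dataset, "study_dataset"))
  problems <- .study_problems(
    dataset$serum, dataset$regions,
    if (canonical) brain_regions(include_whole_brain = TRUE)
  )
  if (length(problems))
    stop("invalid study dataset:\n  - ",
         paste(problems, collapse = "\n  - "), call. = FALSE)
  invisible(dataset)
}
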
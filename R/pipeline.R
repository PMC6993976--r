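# End-to-end analysis: serum clearance fits per group, exposure times, B/S
# and delta B/S per region (plus the whole-brain aggregate), Patlak fits per
# group x region, and the vascular-space summary table.

# Long point table: one row per animal x region with both B/S ratios, the
# corrected ratio and the animal's exposure time already attached.
.patlak_points <- function(serum, regions, expt_by_id, exclude_regions) {
  wb <- aggregate_whole_brain(regions, exclude = exclude_regions)
  allreg <- rbind(regions[names(wb)], wb)
  i <- match(allreg$id, serum$id)
  s <- serum[i, , drop = FALSE]
  bs_tr <- brain_serum_ratio(allreg$tracer_cpm, allreg$weight_g,
                             s$serum_tracer_cpm, s$aliquot_ul)
  bs_mk <- brain_serum_ratio(allreg$marker_cpm, allreg$weight_g,
                             s$serum_marker_cpm, s$aliquot_ul)
  data.frame(
    id = allreg$id, genotype = s$genotype, sex = s$sex,
    group = .group_key(s$genotype, s$sex), region = allreg$region,
    time_min = s$time_min, expt = expt_by_id[allreg$id],
    bs_tracer = bs_tr, bs_marker = bs_mk,
    delta_bs = delta_bs(bs_tr, bs_mk),
    stringsAsFactors = FALSE
  )
}

#' Vascular space summary (albumin marker)
#'
#' Per group x region summary of the vascular marker's brain/serum ratio:
#' mean, standard error and n, together with the p-value of a regression of
#' marker B/S on terminal time within the cell (`time_trend_p`). Collapsing
#' values across time into a single mean is only justified when the marker
#' ratio shows no time trend, so `collapse_valid` flags cells with
#' `time_trend_p >= 0.05`. Cells with fewer than 2 animals are reported with
#' an undefined SE and flagged.
#'
#' @param dataset a `study_dataset`.
#' @param group_by grouping columns among `"genotype"`, `"sex"` (default
#'   both); use `character(0)` to pool all animals.
#' @param exclude_regions regions excluded from the whole-brain aggregate.
#' @return data frame of class `vascular_space_summary` with columns `group`,
#'   `region`, `mean`, `se`, `n`, `time_trend_p`, `collapse_valid`.
#' @export
vascular_space_summary <- function(dataset, group_by = c("genotype", "sex"),
                                   exclude_regions = .OLFACTORY) {
  stopifnot(inherits(dataset, "study_dataset"))
  serum <- dataset$serum
  ok <- serum$serum_tracer_cpm > 0 & serum$serum_marker_cpm > 0
  serum <- serum[ok, , drop = FALSE]
  regions <- dataset$regions[dataset$regions$id %in% serum$id, , drop = FALSE]
  expt0 <- setNames(serum$time_min, serum$id)  # placeholder, unused here
  pts <- .patlak_points(serum, regions, expt0, exclude_regions)
  grp <- if (length(group_by)) {
    interaction(pts[group_by], sep = ".", drop = TRUE)
  } else factor(rep("all", nrow(pts)))
  cells <- split(pts, list(grp, pts$region), sep = "|", drop = TRUE)
  out <- do.call(rbind, lapply(cells, function(d) {
    n <- nrow(d)
    trend_p <- NA_real_
    if (n >= 3 && var(d$time_min) > 0) {
      # a marker B/S constant up to floating-point noise has no time trend;
      # testing the rounding residue would produce arbitrary p-values
      relvar <- var(d$bs_marker) / max(mean(d$bs_marker)^2, .Machine$double.xmin)
      if (relvar < 1e-18) {
        trend_p <- 1
      } else {
        sm <- suppressWarnings(summary(lm(bs_marker ~ time_min, data = d)))$coefficients
        if (nrow(sm) == 2) trend_p <- sm["time_min", "Pr(>|t|)"]
      }
    }
    data.frame(
      group = NA_character_,  # filled from the split keys below
      region = d$region[1],
      mean = mean(d$bs_marker),
      se = if (n >= 2) sd(d$bs_marker) / sqrt(n) else NA_real_,
      n = n,
      time_trend_p = trend_p,
      collapse_valid = if (is.na(trend_p)) NA else trend_p >= 0.05,
      stringsAsFactors = FALSE
    )
  }))
  # split() keys carry the group label; recover it directly
  key <- do.call(rbind, strsplit(names(cells), "|", fixed = TRUE))
  out$group <- key[, 1]
  rownames(out) <- NULL
  out <- out[order(out$group, match(out$region, brain_regions(TRUE))), ]
  rownames(out) <- NULL
  class(out) <- c("vascular_space_summary", "data.frame")
  out
}

#' @export
print.vascular_space_summary <- function(x, digits = 4, ...) {
  cat("Vascular space (marker B/S, uL/g), collapsed across time\n")
  df <- as.data.frame(x)
  df$mean <- signif(df$mean, digits); df$se <- signif(df$se, digits)
  df$time_trend_p <- signif(df$time_trend_p, 3)
  print(df, row.names = FALSE, ...)
  invisible(x)
}

#' Run the full BBB pharmacokinetic analysis
#'
#' Orchestrates the complete analysis of a dual-tracer study dataset:
#'
#' 1. validation and exclusion (with logging) of animals whose serum counts
#'    are non-positive — such animals cannot form ratios;
#' 2. log-linear serum decay fits of the test tracer per serum group
#'    (genotype x sex by default; `"sex"` collapses genotypes, `"pooled"`
#'    fits one curve), giving the clearance rate and half-life per group;
#' 3. exposure times per animal from its group's fitted curve (or from a
#'    user-supplied clearance rate via `known_k`);
#' 4. brain/serum ratios per region and isotope, the whole-brain aggregate,
#'    and the vascular-corrected delta B/S;
#' 5. Patlak fits per analysis group x region (plus sex-combined whole-brain
#'    fits), flagged "ns"/"nm" where transport is not detected;
#' 6. the vascular-space summary table.
#'
#' @param dataset a `study_dataset`.
#' @param alpha significance level for transport detection.
#' @param serum_grouping `"genotype_sex"`, `"sex"` or `"pooled"` — which
#'   animals share a serum curve for the exposure-time transform.
#' @param known_k optional clearance rate(s) (/min) overriding the fitted
#'   rates for the exposure-time transform: a scalar, or a vector named by
#'   serum group.
#' @param expt_method `"analytic"` or `"empirical"`, see [exposure_time()].
#' @param serum_window,patlak_window optional `c(lo, hi)` windows selecting
#'   the linear portion of the serum decay (time, min) and the Patlak
#'   relation (Expt, min). Defaults use all points; any windowing is logged.
#' @param exclude_regions regions excluded from the whole-brain sum.
#' @param combine_sexes also fit sex-combined (genotype-pooled) whole-brain
#'   Patlak lines.
#' @param half_life_precise use `log10(2)` rather than 0.301 in half-life
#'   conversion.
#' @return an object of class `bbb_results`: list with `clearance`,
#'   `vascular_space`, `regional_ki`, `regional_vi`, `whole_brain_pk` tables,
#'   the point table `points`, the fitted objects (`serum_fits`,
#'   `patlak_fits`), and a `log` of every exclusion and decision.
#' @export
run_pipeline <- function(dataset,
                         alpha = 0.05,
                         serum_grouping = c("genotype_sex", "sex", "pooled"),
                         known_k = NULL,
                         expt_method = c("analytic", "empirical"),
                         serum_window = NULL,
                         patlak_window = NULL,
                         exclude_regions = .OLFACTORY,
                         combine_sexes = TRUE,
                         half_life_precise = FALSE) {
  serum_grouping <- match.arg(serum_grouping)
  expt_method <- match.arg(expt_method)
  validate_study(dataset)
  log <- character()
  note <- function(...) log <<- c(log, paste0(...))

  serum <- dataset$serum
  bad <- serum$serum_tracer_cpm <= 0 | serum$serum_marker_cpm <= 0
  if (any(bad)) {
    note("excluded animal(s) with non-positive serum counts: ",
         paste(serum$id[bad], collapse = ", "))
    serum <- serum[!bad, , drop = FALSE]
  }
  if (nrow(serum) < 3) stop("too few usable animals after exclusions", call. = FALSE)
  regions <- dataset$regions[dataset$regions$id %in% serum$id, , drop = FALSE]

  skey <- switch(serum_grouping,
    genotype_sex = .group_key(serum$genotype, serum$sex),
    sex = serum$sex,
    pooled = rep("all", nrow(serum))
  )
  conc <- serum$serum_tracer_cpm / serum$aliquot_ul
  serum_fits <- lapply(split(seq_len(nrow(serum)), skey), function(i) {
    fit_serum_decay(serum$time_min[i], conc[i], window = serum_window,
                    precise = half_life_precise)
  })
  if (!is.null(serum_window))
    note("serum decay fitted on explicit window [",
         serum_window[1], ", ", serum_window[2], "] min")

  clearance <- do.call(rbind, lapply(names(serum_fits), function(g) {
    f <- serum_fits[[g]]
    data.frame(group = g, n = f$n_points, slope_log10 = f$slope_log10,
               intercept_log10 = f$intercept_log10, r_squared = f$r_squared,
               k_per_min = f$k, half_life_min = f$half_life,
               stringsAsFactors = FALSE)
  }))
  rownames(clearance) <- NULL

  k_for <- function(g) {
    if (is.null(known_k)) return(NULL)
    if (length(known_k) == 1 && is.null(names(known_k))) return(unname(known_k))
    if (!g %in% names(known_k))
      stop("known_k has no entry for serum group ", g, call. = FALSE)
    unname(known_k[g])
  }
  expt <- numeric(nrow(serum))
  for (g in unique(skey)) {
    i <- skey == g
    kk <- k_for(g)
    src <- if (is.null(kk)) serum_fits[[g]] else kk
    expt[i] <- exposure_time(src, serum$time_min[i], method = expt_method)
  }
  if (!is.null(known_k))
    note("exposure times computed from user-supplied clearance rate(s)")
  expt_by_id <- setNames(expt, serum$id)

  pts <- .patlak_points(serum, regions, expt_by_id, exclude_regions)
  if (!is.null(patlak_window))
    note("Patlak fits restricted to Expt window [",
         patlak_window[1], ", ", patlak_window[2], "] min")

  fit_cell <- function(d) {
    tryCatch(
      patlak_fit(d$expt, d$delta_bs, alpha = alpha, window = patlak_window,
                 animal_id = d$id),
      error = function(e) {
        note("Patlak fit failed (", d$group[1], ", ", d$region[1], "): ",
             conditionMessage(e))
        NULL
      }
    )
  }
  cells <- split(pts, list(pts$group, pts$region), sep = "|", drop = TRUE)
  patlak_fits <- lapply(cells, fit_cell)
  names(patlak_fits) <- names(cells)

  fit_row <- function(g, region, f) {
    if (is.null(f)) {
      return(data.frame(group = g, region = region, ki = NA_real_,
                        ki_se = NA_real_, vi = NA_real_, vi_se = NA_real_,
                        r = NA_real_, n = NA_integer_, p_slope = NA_real_,
                        transport = NA, ki_label = "nf", vi_label = "nf",
                        stringsAsFactors = FALSE))
    }
    data.frame(
      group = g, region = region, ki = f$ki, ki_se = f$ki_se,
      vi = f$vi, vi_se = f$vi_se, r = f$r, n = f$n, p_slope = f$p_slope,
      transport = f$transport_significant,
      ki_label = if (f$transport_significant) sprintf("%.3f", f$ki) else "ns",
      vi_label = if (f$vi_measurable) sprintf("%.2f", f$vi) else "nm",
      stringsAsFactors = FALSE
    )
  }
  keyparts <- do.call(rbind, strsplit(names(patlak_fits), "|", fixed = TRUE))
  pk <- do.call(rbind, lapply(seq_along(patlak_fits), function(i)
    fit_row(keyparts[i, 1], keyparts[i, 2], patlak_fits[[i]])))
  pk <- pk[order(pk$group, match(pk$region, brain_regions(TRUE))), ]
  rownames(pk) <- NULL

  dissected <- pk[pk$region != .WHOLE_BRAIN, , drop = FALSE]
  regional_ki <- dissected[c("group", "region", "ki", "ki_se", "r", "n",
                             "p_slope", "transport", "ki_label")]
  regional_vi <- dissected[c("group", "region", "vi", "vi_se", "n",
                             "transport", "vi_label")]

  wb <- pk[pk$region == .WHOLE_BRAIN, , drop = FALSE]
  if (combine_sexes) {
    wbpts <- pts[pts$region == .WHOLE_BRAIN, , drop = FALSE]
    for (s in unique(wbpts$sex)) {
      d <- wbpts[wbpts$sex == s, , drop = FALSE]
      f <- fit_cell(within(d, {group <- paste0(s, ".combined")}))
      patlak_fits[[paste0(s, ".combined|", .WHOLE_BRAIN)]] <- f
      wb <- rbind(wb, fit_row(paste0(s, ".combined"), .WHOLE_BRAIN, f))
    }
  }
  rownames(wb) <- NULL

  vs <- vascular_space_summary(dataset, exclude_regions = exclude_regions)

  structure(
    list(
      clearance = clearance,
      vascular_space = vs,
      regional_ki = regional_ki,
      regional_vi = regional_vi,
      whole_brain_pk = wb,
      points = pts,
      serum_fits = serum_fits,
      patlak_fits = patlak_fits,
      settings = list(alpha = alpha, serum_grouping = serum_grouping,
                      expt_method = expt_method, serum_window = serum_window,
                      patlak_window = patlak_window,
                      exclude_regions = exclude_regions,
                      known_k = known_k),
      log = log
    ),
    class = "bbb_results"
  )
}

#' @export
print.bbb_results <- function(x, ...) {
  cat("BBB pharmacokinetic analysis results\n")
  cat("  serum groups: ", paste(x$clearance$group, collapse = ", "), "\n", sep = "")
  cat("  clearance half-lives (min): ",
      paste(sprintf("%s %.3g", x$clearance$group, x$clearance$half_life_min),
            collapse = ", "), "\n", sep = "")
  nk <- sum(x$regional_ki$transport, na.rm = TRUE)
  cat("  regional Patlak fits: ", nrow(x$regional_ki), " (",
      nk, " with detectable transport)\n", sep = "")
  cat("  whole-brain fits: ", nrow(x$whole_brain_pk), "\n", sep = "")
  if (length(x$log)) cat("  log:\n", paste("   -", x$log, collapse = "\n"), "\n")
  invisible(x)
}
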
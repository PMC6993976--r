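# The Patlak (multiple-time regression) estimator. In a study where each
# animal contributes one terminal observation, every animal supplies one
# point (Expt, delta B/S); the slope of the least-squares line is the
# unidirectional influx constant Ki (uL/g-min) and the intercept the
# reversible vascular binding Vi (uL/g).

#' Patlak multiple-time regression fit
#'
#' Ordinary least squares of the vascular-corrected brain/serum ratio on
#' exposure time. The slope estimates the unidirectional influx constant
#' `Ki` (uL/g-min) and the intercept the reversible vascular binding `Vi`
#' (uL/g), each with its standard error; the Pearson correlation `r` and the
#' two-sided p-value for a zero slope are reported alongside.
#'
#' Transport is declared present (`transport_significant`) when the slope is
#' significantly different from zero at level `alpha` *and* positive; a
#' significantly negative slope is an anomaly, not transport. Where transport
#' is not detected the intercept has no kinetic interpretation, so
#' `vi_measurable` always equals `transport_significant`: such fits are
#' reported as "ns" (non-significant transport) and "nm" (non-measurable
#' binding) in downstream tables. A fit needs at least 3 points and
#' non-constant exposure times.
#'
#' @param expt exposure times, min (see [exposure_time()]).
#' @param delta_bs vascular-corrected B/S ratios, uL/g (see [delta_bs()]);
#'   negative values are legitimate data.
#' @param alpha significance level for the slope test (default 0.05).
#' @param window optional `c(lo, hi)` restricting the fit to the linear
#'   portion of the Expt axis; default uses all points.
#' @param animal_id optional point labels carried through to methods.
#' @return an object of class `patlak_fit` with elements `ki`, `ki_se`, `vi`,
#'   `vi_se`, `r`, `n`, `p_slope`, `transport_significant`, `vi_measurable`,
#'   `alpha`, `window`, the point data, and the underlying `lm`.
#' @export
#' @examples
#' fit <- patlak_fit(c(1, 2, 3, 4), c(8, 9, 10, 11))
#' coef(fit)  # Ki = 1, Vi = 7
patlak_fit <- function(expt, delta_bs, alpha = 0.05, window = NULL,
                       animal_id = NULL) {
  stopifnot(length(expt) == length(delta_bs))
  keep <- is.finite(expt) & is.finite(delta_bs)
  if (!is.null(window)) {
    stopifnot(length(window) == 2)
    keep <- keep & expt >= window[1] & expt <= window[2]
  }
  x <- expt[keep]; y <- delta_bs[keep]
  ids <- if (!is.null(animal_id)) animal_id[keep]
  if (length(x) < 3)
    stop("Patlak fit needs >= 3 points, got ", length(x), call. = FALSE)
  if (var(x) == 0)
    stop("all exposure times identical: slope undefined", call. = FALSE)

  fit <- lm(y ~ x)
  # noiseless data triggers summary.lm's perfect-fit note; the 0-residual
  # case is well-defined here (SE = 0)
  sm <- suppressWarnings(summary(fit))$coefficients
  ki <- unname(sm["x", "Estimate"])
  p_slope <- unname(sm["x", "Pr(>|t|)"])
  # a perfectly flat, noiseless line yields 0/0 test statistics
  sig <- isTRUE(is.finite(p_slope) && p_slope < alpha && ki > 0)
  structure(
    list(
      ki = ki, ki_se = unname(sm["x", "Std. Error"]),
      vi = unname(sm["(Intercept)", "Estimate"]),
      vi_se = unname(sm["(Intercept)", "Std. Error"]),
      # r is undefined for a constant response (flat line)
      r = if (var(y) == 0) NA_real_ else cor(x, y),
      n = length(x), p_slope = p_slope,
      transport_significant = sig, vi_measurable = sig,
      alpha = alpha, window = window,
      data = data.frame(expt = x, delta_bs = y,
                        animal_id = if (is.null(ids)) NA_character_ else ids,
                        stringsAsFactors = FALSE),
      lm = fit
    ),
    class = "patlak_fit"
  )
}

#' @export
print.patlak_fit <- function(x, ...) {
  cat("Patlak multiple-time regression (", x$n, " points)\n", sep = "")
  cat(sprintf("  Ki = %.4g +/- %.3g uL/g-min   Vi = %.4g +/- %.3g uL/g\n",
              x$ki, x$ki_se, x$vi, x$vi_se))
  cat(sprintf("  r = %.3f, p(slope) = %.4g: %s\n", x$r, x$p_slope,
              if (x$transport_significant) "transport detected"
              else "ns (no detectable transport; Vi nm)"))
  invisible(x)
}

#' @export
summary.patlak_fit <- function(object, ...) {
  out <- list(
    coefficients = rbind(
      Ki = c(Estimate = object$ki, `Std. Error` = object$ki_se),
      Vi = c(Estimate = object$vi, `Std. Error` = object$vi_se)
    ),
    r = object$r, n = object$n, p_slope = object$p_slope,
    transport_significant = object$transport_significant,
    vi_measurable = object$vi_measurable, alpha = object$alpha
  )
  class(out) <- "summary.patlak_fit"
  out
}

#' @export
print.summary.patlak_fit <- function(x, ...) {
  cat("Patlak fit summary\n")
  print(signif(x$coefficients, 4))
  cat(sprintf("n = %d, r = %.3f, p(slope) = %.4g (alpha = %g)\n",
              x$n, x$r, x$p_slope, x$alpha))
  cat("transport:", if (x$transport_significant) "significant" else "ns",
      " Vi:", if (x$vi_measurable) "measurable" else "nm", "\n")
  invisible(x)
}

#' @export
coef.patlak_fit <- function(object, ...) {
  c(Ki = object$ki, Vi = object$vi)
}

#' @export
residuals.patlak_fit <- function(object, ...) residuals(object$lm)

#' Predicted delta B/S along the Patlak line
#'
#' @param object a `patlak_fit`.
#' @param expt exposure times (min); default the fitted points.
#' @param ... unused.
#' @return predicted delta B/S values, uL/g.
#' @export
predict.patlak_fit <- function(object, expt = object$data$expt, ...) {
  object$vi + object$ki * expt
}

#' Simulate delta B/S responses from a fitted Patlak line
#'
#' Draws Gaussian responses around the fitted line at the observed exposure
#' times, using the residual standard deviation of the fit.
#'
#' @param object a `patlak_fit`.
#' @param nsim number of response vectors.
#' @param seed optional seed.
#' @param ... unused.
#' @return data frame with `nsim` columns of simulated responses.
#' @export
simulate.patlak_fit <- function(object, nsim = 1, seed = NULL, ...) {
  simulate(object$lm, nsim = nsim, seed = seed)
}

#' Plot a Patlak fit
#'
#' Scatter of delta B/S against exposure time with the fitted line.
#'
#' @param x a `patlak_fit`.
#' @param ... passed to [plot()].
#' @export
plot.patlak_fit <- function(x, ...) {
  dots <- list(...)
  args <- c(list(x = x$data$expt, y = x$data$delta_bs,
                 xlab = "Exposure time (min)",
                 ylab = expression(Delta * "B/S (" * mu * "L/g)")), dots)
  if (is.null(dots$main))
    args$main <- sprintf("Ki = %.3g uL/g-min, Vi = %.3g uL/g", x$ki, x$vi)
  do.call(plot, args)
  abline(x$vi, x$ki, col = "firebrick", lwd = 2)
  invisible(x)
}
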
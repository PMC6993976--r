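# Group-comparison statistics: equality of regression lines by the
# extra-sum-of-squares F test (the test performed by common linear-regression
# comparison software), classical balanced two-way ANOVA, and Sidak-adjusted
# post hoc comparisons of cell means.

#' Compare regression lines across groups
#'
#' Tests whether k >= 2 groups of (x, y) points share a regression line,
#' by the extra-sum-of-squares (Zar-style) F tests:
#'
#' * **slope homogeneity** — common slope (separate intercepts) vs fully
#'   separate lines: `F = ((RSS_cs - RSS_sep)/(k-1)) / (RSS_sep/(n-2k))`;
#' * **elevation** — single line vs common slope with separate intercepts:
#'   `F = ((RSS_common - RSS_cs)/(k-1)) / (RSS_cs/(n-k-1))`.
#'
#' The elevation (intercept) test is only interpretable when slope
#' homogeneity is not rejected; both are always returned, with degrees of
#' freedom and two-sided p-values. For k = 2 the slope test is identical to
#' the textbook two-slope t test squared.
#'
#' @param groups named list, one element per group, each a list or data frame
#'   with numeric `x` and `y` of equal length (>= 3 points, non-constant x).
#' @param alpha significance level used only for the printed verdict.
#' @return object of class `regline_comparison`: list with `slope_test` and
#'   `elevation_test` (each `F`, `df`, `p`), the per-group slopes, `k`, `n`.
#' @export
#' @examples
#' g <- list(a = list(x = 1:5, y = c(1, 3, 2, 5, 4)),
#'           b = list(x = 1:5, y = c(2, 2, 4, 4, 6)))
#' compare_regression_lines(g)
compare_regression_lines <- function(groups, alpha = 0.05) {
  k <- length(groups)
  if (k < 2) stop("need at least two groups", call. = FALSE)
  if (is.null(names(groups)) || any(!nzchar(names(groups))))
    names(groups) <- paste0("group", seq_len(k))
  for (g in names(groups)) {
    d <- groups[[g]]
    if (length(d$x) != length(d$y) || length(d$x) < 3)
      stop("group '", g, "' needs >= 3 (x, y) points", call. = FALSE)
    if (var(d$x) == 0)
      stop("group '", g, "' has constant x: regression undefined", call. = FALSE)
  }
  x <- unlist(lapply(groups, `[[`, "x"), use.names = FALSE)
  y <- unlist(lapply(groups, `[[`, "y"), use.names = FALSE)
  g <- factor(rep(names(groups), vapply(groups, function(d) length(d$x), 1L)),
              levels = names(groups))
  n <- length(x)

  rss <- function(fit) sum(residuals(fit)^2)
  sep_fits <- lapply(levels(g), function(l) lm(y[g == l] ~ x[g == l]))
  rss_sep <- sum(vapply(sep_fits, rss, numeric(1)))
  rss_cs <- rss(lm(y ~ g + x))       # common slope, separate intercepts
  rss_common <- rss(lm(y ~ x))       # single line

  df_slope <- c(k - 1, n - 2 * k)
  f_slope <- max(0, (rss_cs - rss_sep) / df_slope[1] / (rss_sep / df_slope[2]))
  df_elev <- c(k - 1, n - k - 1)
  f_elev <- max(0, (rss_common - rss_cs) / df_elev[1] / (rss_cs / df_elev[2]))

  slopes <- vapply(sep_fits, function(f) unname(coef(f)[2]), numeric(1))
  structure(
    list(
      slope_test = list(F = f_slope, df = df_slope,
                        p = pf(f_slope, df_slope[1], df_slope[2], lower.tail = FALSE)),
      elevation_test = list(F = f_elev, df = df_elev,
                            p = pf(f_elev, df_elev[1], df_elev[2], lower.tail = FALSE)),
      slopes = setNames(slopes, names(groups)),
      k = k, n = n, alpha = alpha,
      rss = c(separate = rss_sep, common_slope = rss_cs, common = rss_common)
    ),
    class = "regline_comparison"
  )
}

#' @export
print.regline_comparison <- function(x, ...) {
  st <- x$slope_test; et <- x$elevation_test
  cat("Comparison of regression lines (", x$k, " groups, n = ", x$n, ")\n", sep = "")
  cat(sprintf("  slopes: %s\n",
              paste(sprintf("%s = %.4g", names(x$slopes), x$slopes), collapse = ", ")))
  cat(sprintf("  slope homogeneity: F(%d, %d) = %.4g, p = %.4g\n",
              st$df[1], st$df[2], st$F, st$p))
  if (st$p >= x$alpha) {
    cat(sprintf("  elevation (common slope): F(%d, %d) = %.4g, p = %.4g\n",
                et$df[1], et$df[2], et$F, et$p))
  } else {
    cat("  slopes differ; elevation test not interpretable (reported anyway)\n")
    cat(sprintf("    elevation: F(%d, %d) = %.4g, p = %.4g\n",
                et$df[1], et$df[2], et$F, et$p))
  }
  invisible(x)
}

#' Balanced two-way analysis of variance
#'
#' Classical sums-of-squares decomposition for a balanced two-factor design
#' with replication: main effects, interaction and residual rows with SS, df,
#' MS, F and p. Unbalanced designs (unequal cell sizes) and empty cells are
#' an error — this is deliberately the textbook balanced decomposition, where
#' `SS_A + SS_B + SS_AB + SS_resid = SS_total`.
#'
#' When the response is constant, all sums of squares are zero and F ratios
#' are undefined; they are reported as `NaN` with a `degenerate` attribute.
#'
#' @param response numeric response, one value per observation.
#' @param a,b factors (or coercible) of the same length as `response`.
#' @return data frame of class `anova_table` with rows `A`, `B`, `A:B`,
#'   `Residuals` and columns `term`, `ss`, `df`, `ms`, `F`, `p`.
#' @export
#' @examples
#' y <- c(1, 3, 2, 4, 5, 7, 6, 8)
#' a <- rep(c("lo", "hi"), each = 4)
#' b <- rep(rep(c("u", "v"), each = 2), 2)
#' two_way_anova(y, a, b)
two_way_anova <- function(response, a, b) {
  stopifnot(length(response) == length(a), length(response) == length(b))
  a <- factor(a); b <- factor(b)
  if (nlevels(a) < 2 || nlevels(b) < 2)
    stop("both factors need >= 2 levels", call. = FALSE)
  counts <- table(a, b)
  if (any(counts == 0))
    stop("empty cell(s) in the design: ",
         paste(which(counts == 0, arr.ind = TRUE), collapse = ", "), call. = FALSE)
  if (length(unique(c(counts))) != 1)
    stop("unbalanced design (unequal cell sizes) is out of scope for the ",
         "classical decomposition", call. = FALSE)

  fit <- aov(response ~ a * b)
  tab <- summary(fit)[[1]]
  rn <- trimws(rownames(tab))
  pick <- function(term) which(rn == term)
  rows <- c(A = pick("a"), B = pick("b"), `A:B` = pick("a:b"),
            Residuals = pick("Residuals"))
  out <- data.frame(
    term = names(rows),
    ss = tab[rows, "Sum Sq"],
    df = tab[rows, "Df"],
    ms = tab[rows, "Sum Sq"] / tab[rows, "Df"],
    F = c(tab[rows[1:3], "F value"], NA),
    p = c(tab[rows[1:3], "Pr(>F)"], NA),
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  # var() is exactly zero for a constant response; aov's sums of squares may
  # carry rounding residue
  degenerate <- var(response) == 0
  if (degenerate) {
    out$ss[] <- 0
    out$ms[] <- 0
    out$F[1:3] <- NaN
    out$p[1:3] <- NaN
  }
  structure(out, class = c("anova_table", "data.frame"),
            degenerate = degenerate, residual_ms = out$ms[out$term == "Residuals"],
            residual_df = out$df[out$term == "Residuals"])
}

#' @export
print.anova_table <- function(x, ...) {
  cat("Two-way ANOVA (balanced)\n")
  df <- as.data.frame(x)
  for (col in c("ss", "ms", "F", "p")) df[[col]] <- signif(df[[col]], 5)
  print(df, row.names = FALSE)
  if (isTRUE(attr(x, "degenerate")))
    cat("note: constant response; F ratios undefined\n")
  invisible(x)
}

#' Sidak-adjusted pairwise comparisons of cell means
#'
#' Post hoc t tests on the cell means of a balanced two-factor design, using
#' the residual mean square of the two-way ANOVA as the pooled error
#' variance, with the Sidak multiplicity adjustment
#' `p_adj = 1 - (1 - p)^m` over the `m` comparisons performed.
#'
#' @param response,a,b as in [two_way_anova()].
#' @param comparisons list of length-2 character vectors naming the cell
#'   pairs to compare; cells are labelled `"<a>:<b>"`. Default: all pairwise
#'   cell comparisons.
#' @return data frame with columns `cell1`, `cell2`, `diff`, `t`, `df`, `p`,
#'   `p_adj`, plus an `m` attribute.
#' @export
sidak_posthoc <- function(response, a, b, comparisons = NULL) {
  a <- factor(a); b <- factor(b)
  tab <- two_way_anova(response, a, b)
  ms <- attr(tab, "residual_ms")
  dfres <- attr(tab, "residual_df")
  # zero within-cell variance leaves only rounding residue in the residual MS
  if (!is.finite(ms) || ms <= 1e-10 * max(sum(tab$ss), .Machine$double.eps))
    stop("residual mean square is zero: post hoc comparisons undefined",
         call. = FALSE)
  cell <- interaction(a, b, sep = ":", drop = TRUE)
  means <- tapply(response, cell, mean)
  ns <- tapply(response, cell, length)
  if (is.null(comparisons)) {
    cn <- names(means)
    comparisons <- utils::combn(cn, 2, simplify = FALSE)
  }
  m <- length(comparisons)
  out <- do.call(rbind, lapply(comparisons, function(pr) {
    if (!all(pr %in% names(means)))
      stop("unknown cell in comparison: ", paste(pr, collapse = " vs "),
           call. = FALSE)
    d <- means[[pr[1]]] - means[[pr[2]]]
    se <- sqrt(ms * (1 / ns[[pr[1]]] + 1 / ns[[pr[2]]]))
    tt <- d / se
    p <- 2 * pt(abs(tt), dfres, lower.tail = FALSE)
    data.frame(cell1 = pr[1], cell2 = pr[2], diff = d, t = tt, df = dfres,
               p = p, p_adj = 1 - (1 - p)^m, stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  attr(out, "m") <- m
  out
}
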
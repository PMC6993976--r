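# Statistical layer: regression-line comparison, two-way ANOVA, Sidak.

# Brute-force extra-sum-of-squares oracle assembled from explicit residual
# sums, independent of the implementation.
ess_oracle <- function(groups) {
  rss_line <- function(x, y) {
    b <- cov(x, y) / var(x); a <- mean(y) - b * mean(x)
    sum((y - a - b * x)^2)
  }
  x <- unlist(lapply(groups, `[[`, "x")); y <- unlist(lapply(groups, `[[`, "y"))
  g <- rep(seq_along(groups), vapply(groups, function(d) length(d$x), 1L))
  k <- length(groups); n <- length(x)
  rss_sep <- sum(vapply(seq_len(k), function(i)
    rss_line(x[g == i], y[g == i]), numeric(1)))
  # common slope, separate intercepts: pooled within-group slope
  bw <- sum(vapply(seq_len(k), function(i) {
    xi <- x[g == i]; yi <- y[g == i]
    sum((xi - mean(xi)) * (yi - mean(yi)))
  }, numeric(1))) / sum(vapply(seq_len(k), function(i) {
    xi <- x[g == i]; sum((xi - mean(xi))^2)
  }, numeric(1)))
  rss_cs <- sum(vapply(seq_len(k), function(i) {
    xi <- x[g == i]; yi <- y[g == i]
    ai <- mean(yi) - bw * mean(xi)
    sum((yi - ai - bw * xi)^2)
  }, numeric(1)))
  f <- ((rss_cs - rss_sep) / (k - 1)) / (rss_sep / (n - 2 * k))
  list(F = f, rss_sep = rss_sep, rss_cs = rss_cs)
}

test_that("identical groups give F ~ 0 and p ~ 1", {
  d <- list(x = 1:5, y = c(2, 4, 5, 4, 7))
  cmp <- compare_regression_lines(list(a = d, b = d))
  expect_lt(cmp$slope_test$F, 1e-10)
  expect_gt(cmp$slope_test$p, 0.999)
  expect_lt(cmp$elevation_test$F, 1e-10)
})

test_that("slope F matches the brute-force extra-sum-of-squares oracle", {
  fixed <- list(
    a = list(x = c(1, 2, 3, 4, 5), y = c(2, 3, 5, 4, 6)),
    b = list(x = c(1, 2, 3, 4, 5), y = c(1, 4, 4, 7, 8))
  )
  cmp <- compare_regression_lines(fixed)
  oracle <- ess_oracle(fixed)
  expect_equal(cmp$slope_test$F, oracle$F, tolerance = 1e-9)
  expect_equal(cmp$slope_test$df, c(1, 6))

  set.seed(77)
  for (rep in 1:20) {
    k <- sample(2:4, 1)
    gs <- lapply(seq_len(k), function(i) {
      n <- sample(4:9, 1)
      x <- sort(runif(n, 0, 10))
      list(x = x, y = 1 + i * 0.3 * x + rnorm(n))
    })
    names(gs) <- paste0("g", seq_len(k))
    cmp <- compare_regression_lines(gs)
    expect_equal(cmp$slope_test$F, ess_oracle(gs)$F, tolerance = 1e-9)
  }
})

test_that("for two groups the slope F equals the two-slope t statistic squared", {
  set.seed(3)
  g <- list(
    a = list(x = 1:7, y = 2 + 0.5 * (1:7) + rnorm(7, 0, 0.4)),
    b = list(x = 1:8, y = 1 + 0.9 * (1:8) + rnorm(8, 0, 0.4))
  )
  cmp <- compare_regression_lines(g)
  # textbook two-slope t test on pooled residual variance
  s_line <- function(d) {
    fit <- lm(d$y ~ d$x)
    list(b = unname(coef(fit)[2]), rss = sum(residuals(fit)^2),
         sxx = sum((d$x - mean(d$x))^2), n = length(d$x))
  }
  A <- s_line(g$a); B <- s_line(g$b)
  sp2 <- (A$rss + B$rss) / (A$n + B$n - 4)
  tstat <- (A$b - B$b) / sqrt(sp2 / A$sxx + sp2 / B$sxx)
  expect_equal(cmp$slope_test$F, tstat^2, tolerance = 1e-9)
})

test_that("slope-equality test holds its size under a common line", {
  set.seed(19)
  reject <- vapply(1:2000, function(i) {
    x <- 1:6
    g <- list(a = list(x = x, y = 1 + 0.5 * x + rnorm(6)),
              b = list(x = x, y = 1 + 0.5 * x + rnorm(6)))
    compare_regression_lines(g)$slope_test$p < 0.05
  }, logical(1))
  expect_gte(mean(reject), 0.035)
  expect_lte(mean(reject), 0.065)
})

test_that("degenerate groups are rejected by name", {
  g <- list(good = list(x = 1:4, y = 1:4),
            flat = list(x = rep(2, 4), y = 1:4))
  expect_error(compare_regression_lines(g), "flat")
  expect_error(compare_regression_lines(g["good"]), "two groups")
})

test_that("two-way ANOVA reproduces the hand-computed decomposition", {
  y <- c(1, 3, 2, 4, 5, 7, 6, 8)
  a <- rep(c("a1", "a2"), each = 4)
  b <- rep(rep(c("b1", "b2"), each = 2), 2)
  tab <- two_way_anova(y, a, b)
  expect_equal(tab$ss, c(32, 2, 0, 8))
  expect_equal(tab$df, c(1, 1, 1, 4))
  expect_equal(tab$F[1:3], c(16, 1, 0))
})

test_that("ANOVA conserves sums of squares on random balanced designs", {
  set.seed(101)
  for (rep in 1:30) {
    nrep <- sample(2:5, 1)
    a <- rep(c("x", "y"), each = 2 * nrep)
    b <- rep(rep(c("u", "v"), each = nrep), 2)
    y <- rnorm(length(a), mean = 2 * (a == "x") + 0.5 * (b == "u"))
    tab <- two_way_anova(y, a, b)
    expect_equal(sum(tab$ss), sum((y - mean(y))^2), tolerance = 1e-9)
    # permutation invariance
    p <- sample(seq_along(y))
    tab2 <- two_way_anova(y[p], a[p], b[p])
    expect_equal(tab2$ss, tab$ss, tolerance = 1e-9)
  }
})

test_that("constant responses give NaN F ratios with a degeneracy flag", {
  tab <- two_way_anova(rep(3, 8), rep(c("a", "b"), each = 4),
                       rep(c("u", "v"), 4))
  expect_true(attr(tab, "degenerate"))
  expect_true(all(is.nan(tab$F[1:3])))
})

test_that("unbalanced designs and empty cells are refused", {
  expect_error(two_way_anova(1:7, c("a", "a", "a", "a", "b", "b", "b"),
                             c("u", "u", "v", "v", "u", "u", "v")),
               "unbalanced")
  expect_error(two_way_anova(1:4, c("a", "a", "b", "b"), c("u", "u", "u", "u")),
               "2 levels")
})

test_that("Sidak adjustment has the closed form and is monotone", {
  y <- c(1.2, 1.9, 1.4, 2.2, 3.3, 2.8, 4.1, 3.6)
  a <- rep(c("a1", "a2"), each = 4)
  b <- rep(rep(c("b1", "b2"), each = 2), 2)
  one <- sidak_posthoc(y, a, b, comparisons = list(c("a1:b1", "a2:b1")))
  expect_equal(one$p_adj, one$p)  # m = 1 leaves p unchanged
  all6 <- sidak_posthoc(y, a, b)
  expect_equal(nrow(all6), 6)
  expect_equal(all6$p_adj, 1 - (1 - all6$p)^6, tolerance = 1e-12)
  # monotone in p and in m
  o <- order(all6$p)
  expect_true(all(diff(all6$p_adj[o]) >= -1e-12))
  # monotone in m: adjusting over 6 comparisons never shrinks below raw p
  expect_true(all(all6$p_adj >= all6$p - 1e-12))
})

test_that("Sidak family-wise error stays controlled under the null", {
  set.seed(23)
  fwer <- vapply(1:2000, function(i) {
    y <- rnorm(12)
    a <- rep(c("a1", "a2"), each = 6)
    b <- rep(rep(c("b1", "b2"), each = 3), 2)
    any(sidak_posthoc(y, a, b)$p_adj < 0.05)
  }, logical(1))
  expect_lte(mean(fwer), 0.065)
})

test_that("zero residual variance blocks post hoc comparisons", {
  y <- c(1, 1, 2, 2, 3, 3, 4, 4)  # zero within-cell variance
  a <- rep(c("a1", "a2"), each = 4)
  b <- rep(rep(c("b1", "b2"), each = 2), 2)
  expect_error(sidak_posthoc(y, a, b), "residual mean square")
})
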
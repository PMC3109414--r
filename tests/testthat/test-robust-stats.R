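# MM regression ---------------------------------------------------------

test_that("MM regression reproduces an exact line and resists gross outliers", {
  x <- seq(-5, 5, length.out = 40)
  fit <- mm_regression(x, 3 + 2 * x)
  expect_equal(unname(fit$coefficients["slope"]), 2, tolerance = 1e-12)
  expect_equal(unname(fit$coefficients["intercept"]), 3, tolerance = 1e-10)
  expect_true(all(fit$weights == 1))

  # 30% of responses destroyed at high leverage: MM stays near the truth,
  # ordinary least squares is carried away
  set.seed(401)
  n <- 200; xx <- runif(n, -3, 3); yy <- xx + rnorm(n)
  bad <- order(xx, decreasing = TRUE)[1:60]
  yy[bad] <- -20
  mm_slope <- mm_regression(xx, yy)$coefficients["slope"]
  ls_slope <- stats::coef(stats::lm(yy ~ xx))[2]
  expect_lt(abs(mm_slope - 1), 0.1)
  expect_gt(abs(ls_slope - 1), 0.5)
})

test_that("MM regression is efficient on clean data and matches an independent MM fit", {
  skip_if_not_installed("MASS")
  set.seed(77)
  n <- 500; x <- rnorm(n); y <- 1 + 0.5 * x + rnorm(n)
  mm <- mm_regression(x, y)
  ls <- stats::lm(y ~ x)
  ls_se <- summary(ls)$coefficients[2, 2]
  expect_lt(abs(mm$coefficients["slope"] - stats::coef(ls)[2]), 2 * ls_se)

  set.seed(7)
  n <- 150; x <- rnorm(n); y <- 1 + 0.8 * x + rnorm(n, 0, 0.6)
  y[sample(n, 20)] <- y[sample(n, 20)] + 15
  mine <- mm_regression(x, y)
  ref <- MASS::rlm(y ~ x, method = "MM")
  expect_equal(unname(mine$coefficients["slope"]),
               unname(stats::coef(ref)[2]), tolerance = 5e-3)
  expect_true(all(mine$weights >= 0 & mine$weights <= 1))
  expect_equal(unname(mine$t["slope"]),
               unname(mine$coefficients["slope"] / mine$se["slope"]))
})

test_that("MM slope stays bounded under heavy contamination (breakdown)", {
  for (frac in c(0.10, 0.20, 0.30, 0.45)) {
    devs <- vapply(1:5, function(r) {
      set.seed(round(1000 * frac) + r)
      n <- 200; x <- runif(n, -3, 3); y <- 2 * x + rnorm(n, 0, 0.5)
      bad <- sample(n, round(frac * n))
      y[bad] <- 50
      abs(mm_regression(x, y)$coefficients["slope"] - 2)
    }, numeric(1))
    expect_lt(max(devs), 0.5)
  }
})

test_that("MM regression rejects degenerate designs", {
  expect_error(mm_regression(rep(1, 10), rnorm(10)), "constant")
  expect_error(mm_regression(1:2, 1:2), "at least 3")
})

# lowess ----------------------------------------------------------------

test_that("lowess reproduces a line exactly and downweights an outlier", {
  x <- seq(0, 10, length.out = 60)
  y <- 2 + 0.5 * x
  expect_lt(max(abs(lowess_fit(x, y) - y)), 1e-8)

  y2 <- y; y2[30] <- y2[30] + 50
  rob <- lowess_fit(x, y2)
  nonrob <- lowess_fit(x, y2, iterations = 0)
  expect_lt(abs(rob[30] - y[30]), 50 / 10)
  expect_lt(abs(rob[30] - y[30]), abs(nonrob[30] - y[30]))
})

test_that("lowess with span 1 respects symmetry and reduces to least squares", {
  x <- seq(-3, 3, length.out = 41)
  y <- x^2
  fit <- lowess_fit(x, y, span = 1)
  expect_equal(fit, rev(fit), tolerance = 1e-8)

  # zero robustifying iterations, full span, exactly linear data: the
  # weighted local fits all reproduce the least-squares line
  yl <- 1 + 2 * x
  fit0 <- lowess_fit(x, yl, span = 1, iterations = 0)
  ls <- stats::fitted(stats::lm(yl ~ x))
  expect_equal(fit0, unname(ls), tolerance = 1e-8)
})

test_that("lowess validates span and sample size", {
  expect_error(lowess_fit(1:4, 1:4), "at least 5")
  expect_error(lowess_fit(1:20, rnorm(20), span = 0.01), "span too small")
  expect_error(lowess_fit(1:20, rnorm(20), span = 1.5), "span")
})

# Spearman --------------------------------------------------------------

test_that("Spearman's rho matches the rank definition and base R on ties", {
  expect_equal(spearman_rho(1:10, (1:10)^3), 1)
  expect_equal(spearman_rho(1:10, -(1:10)^3), -1)
  expect_equal(spearman_rho(c(1, 2, 3, 4), c(1, 3, 2, 4)), 0.8)
  set.seed(31)
  for (i in 1:10) {
    x <- sample(1:5, 30, replace = TRUE)   # heavy ties
    y <- sample(1:6, 30, replace = TRUE)
    expect_equal(spearman_rho(x, y),
                 stats::cor(x, y, method = "spearman"), tolerance = 1e-12)
  }
  expect_error(spearman_rho(rep(1, 5), 1:5), "constant")
})

test_that("Spearman's rho is invariant under strictly monotone transforms", {
  set.seed(17)
  for (i in 1:20) {
    x <- rnorm(25); y <- rnorm(25)
    base_rho <- spearman_rho(x, y)
    expect_equal(spearman_rho(exp(x), y), base_rho)
    expect_equal(spearman_rho(x, y^3 + 5 * y), base_rho)
  }
})

# Mann-Whitney ----------------------------------------------------------

test_that("Mann-Whitney U statistic and exact tail match hand enumeration", {
  res <- mann_whitney(c(1, 2), c(3, 4))
  expect_equal(res$statistic, 0)
  # all 6 assignments: |U - 2| >= 2 for U in {0, 4} -> two-sided p = 2/6
  expect_equal(res$p_value, 2 / 6)
  expect_identical(res$method, "exact")

  same <- mann_whitney(c(5, 6, 7), c(5, 6, 7))
  expect_gt(same$p_value, 0.9)
})

test_that("exact Mann-Whitney agrees with base R and with the approximation", {
  set.seed(101)
  for (i in 1:10) {
    na <- sample(2:6, 1); nb <- sample(2:6, 1)
    a <- rnorm(na); b <- rnorm(nb)       # continuous: no ties
    mine <- mann_whitney(a, b)
    ref <- stats::wilcox.test(a, b, exact = TRUE)
    expect_equal(mine$p_value, ref$p.value, tolerance = 1e-12)
  }
  set.seed(202)
  a <- rnorm(15); b <- rnorm(15, 0.3)
  exact <- mann_whitney(a, b, exact_cap = 30)
  approx <- mann_whitney(a, b, exact_cap = 12)
  expect_identical(approx$method, "normal-approximation")
  expect_lt(abs(exact$p_value - approx$p_value), 0.02)
  expect_error(mann_whitney(numeric(0), 1:3), "non-empty")
})

# variance ratio --------------------------------------------------------

test_that("variance-ratio test orients to the larger variance and matches var.test", {
  x <- c(1, 2, 3, 4, 5)
  same <- variance_ratio_test(x, x)
  expect_equal(same$statistic, 1)
  expect_equal(same$p_value, 1)

  set.seed(9)
  a <- rnorm(2000); b <- 2 * rnorm(2000)
  vr <- variance_ratio_test(a, b)
  expect_equal(vr$statistic, 4, tolerance = 0.3)
  sw <- variance_ratio_test(b, a)
  expect_equal(vr$statistic, sw$statistic)
  expect_equal(vr$p_value, sw$p_value)

  for (i in 1:5) {
    a <- rnorm(20 + i); b <- rnorm(15, 0, 1.5)
    expect_equal(variance_ratio_test(a, b)$p_value,
                 stats::var.test(a, b)$p.value, tolerance = 1e-12)
  }
  zero <- variance_ratio_test(rep(1, 5), rnorm(5))
  expect_true(zero$infinite)
  expect_equal(zero$statistic, Inf)
})

# categorical -----------------------------------------------------------

test_that("chi-square and Fisher exact match enumeration and base R", {
  flat <- categorical_tests(matrix(c(10, 10, 10, 10), 2))
  expect_equal(flat$chisq, 0)
  expect_equal(flat$fisher_p, 1)

  tab <- matrix(c(1, 9, 9, 1), 2)
  mine <- categorical_tests(tab)
  expect_equal(mine$fisher_p, stats::fisher.test(tab)$p.value,
               tolerance = 1e-9)
  expect_equal(mine$chisq,
               unname(stats::chisq.test(tab, correct = FALSE)$statistic))

  swapped <- categorical_tests(tab[2:1, ])
  expect_equal(mine$fisher_p, swapped$fisher_p)

  expect_error(categorical_tests(matrix(c(0, 0, 3, 4), 2, byrow = TRUE)),
               "degenerate")
})
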
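test_that("CAMCOG sampler hits the target group sizes, support and medians", {
  s <- sample_camcog(95, 97, seed = 1)
  expect_equal(nrow(s), 192)
  expect_equal(as.vector(table(s$group)), c(95, 97))
  expect_true(all(s$camcog == round(s$camcog)))
  expect_true(all(s$camcog >= 0 & s$camcog <= 107))

  empty <- sample_camcog(0, 0, seed = 3)
  expect_equal(nrow(empty), 0)

  big <- sample_camcog(5000, 0, seed = 7)
  expect_lt(abs(stats::median(big$camcog) - 99), 2)
  q <- stats::quantile(big$camcog, c(0.25, 0.75))
  expect_lt(abs(q[1] - 81), 5)
  expect_lt(abs(q[2] - 106), 2)

  ad <- sample_camcog(0, 5000, seed = 7)
  expect_lt(abs(stats::median(ad$camcog) - 57), 4)

  expect_error(sample_camcog(-1, 5, seed = 1), "non-negative")
})

test_that("piecewise mean is anchored, continuous and collapses for equal slopes", {
  cfg <- scenario_config("bm", theta = 90, slope_above = -2, slope_below = 3,
                         level_at_theta = 500, sd_above = 1, sd_below = 1)
  expect_equal(piecewise_mean(90, cfg), 500)
  # peak-shaped config: falling above, rising below -> maximum at theta
  expect_gt(piecewise_mean(90, cfg), piecewise_mean(70, cfg))
  expect_gt(piecewise_mean(90, cfg), piecewise_mean(105, cfg))
  # continuity at theta
  expect_equal(piecewise_mean(90 + 1e-9, cfg), piecewise_mean(90, cfg),
               tolerance = 1e-6)

  line <- scenario_config("bm", 90, 2, 2, 500, 1, 1)
  x <- c(0, 30, 60, 90, 107)
  expect_equal(piecewise_mean(x, line), 500 + 2 * (x - 90))
})

test_that("scenario validation names the offending field", {
  expect_error(scenario_config("b", 120, 1, 1, 10, 1, 1), "theta")
  expect_error(scenario_config("b", 90, 1, 1, 10, -1, 1), "sd_above")
  expect_error(scenario_config("b", 90, 1, 1, 10, 1, 1,
                               contamination_rate = 0.7),
               "contamination_rate")
})

test_that("default scenarios carry the published change-points and slope signs", {
  cfgs <- default_scenarios()
  expect_named(cfgs, c("abeta40", "abeta42", "tau", "ptau"))
  expect_equal(vapply(cfgs, `[[`, numeric(1), "theta"),
               c(abeta40 = 90, abeta42 = 90, tau = 94, ptau = 93))
  # biphasic Abeta1-40, falling Abeta1-42 above with near-flat below,
  # steeper-above Tau and phospho-Tau
  expect_gt(cfgs$abeta40$slope_above, 0)
  expect_lt(cfgs$abeta40$slope_below, 0)
  expect_lt(cfgs$abeta42$slope_above, 0)
  expect_lt(abs(cfgs$abeta42$slope_below), abs(cfgs$abeta42$slope_above) / 10)
  expect_gt(cfgs$tau$slope_above, cfgs$tau$slope_below)
  expect_gt(cfgs$tau$slope_below, 0)
})

test_that("generated cohorts are reproducible and follow the configured law", {
  cfgs <- default_scenarios()
  t1 <- generate_cohort(cfgs, 95, 97, seed = 3)
  t2 <- generate_cohort(cfgs, 95, 97, seed = 3)
  expect_identical(t1, t2)
  expect_true(all(t1$camcog >= 0 & t1$camcog <= 107))
  expect_true(all(vapply(biomarker_names(t1),
                         function(b) all(t1[[b]] >= 0, na.rm = TRUE),
                         logical(1))))

  # near-noiseless limit converges on the broken-stick mean
  tiny <- scenario_config("bm", 90, 5, -2, 400, 1e-6, 1e-6)
  t3 <- generate_cohort(list(bm = tiny), 50, 50, seed = 4)
  expect_lt(max(abs(t3$bm - piecewise_mean(t3$camcog, tiny))), 1e-4)
})

test_that("side variances and slopes of generated data match the configuration", {
  cfg <- scenario_config("bm", 90, 93, -15, 4200, 1964, 1362)
  tab <- generate_cohort(list(bm = cfg), 1000, 1000, seed = 3)
  mu <- piecewise_mean(tab$camcog, cfg)
  res <- tab$bm - mu
  above <- tab$camcog > 90
  ratio <- stats::var(res[above]) / stats::var(res[!above])
  expect_lt(abs(ratio / (1964 / 1362)^2 - 1), 0.15)

  # side-wise least-squares slopes at large n recover the configured slopes
  big <- generate_cohort(list(bm = cfg), 3000, 3000, seed = 8)
  for (side in c(TRUE, FALSE)) {
    sel <- (big$camcog > 90) == side
    fit <- stats::lm(big$bm[sel] ~ big$camcog[sel])
    est <- stats::coef(fit)[2]
    se <- summary(fit)$coefficients[2, 2]
    truth <- if (side) cfg$slope_above else cfg$slope_below
    expect_lt(abs(est - truth), 3 * se)
  }
})

test_that("contamination inflates the configured fraction of residuals", {
  cfg <- scenario_config("bm", 90, 0, 0, 100, 1, 1,
                         contamination_rate = 0.2, contamination_scale = 10)
  tab <- generate_cohort(list(bm = cfg), 2500, 2500, seed = 12)
  res <- tab$bm - piecewise_mean(tab$camcog, cfg)
  # |residual| > 4 SD essentially only from the contaminated component
  frac_gross <- mean(abs(res) > 4)
  expect_gt(frac_gross, 0.10)
  expect_lt(frac_gross, 0.25)
})

test_that("cohort tables and scenario configs round-trip through disk", {
  cfgs <- default_scenarios()
  tab <- generate_cohort(cfgs, 20, 20, seed = 6, missing_rate = 0.1)
  csv <- withr::local_tempfile(fileext = ".csv")
  write_cohort(tab, csv)
  back <- read_cohort(csv)
  expect_equal(back$camcog, tab$camcog)
  expect_equal(back$abeta40, tab$abeta40, tolerance = 1e-10)
  expect_identical(levels(back$group), levels(tab$group))

  yml <- withr::local_tempfile(fileext = ".yaml")
  write_scenarios(cfgs, yml)
  cfgs2 <- read_scenarios(yml)
  expect_equal(cfgs2$tau$theta, cfgs$tau$theta)
  expect_equal(cfgs2$abeta40$slope_below, cfgs$abeta40$slope_below)
  expect_equal(cfgs2$ptau$covariate_coeffs, cfgs$ptau$covariate_coeffs)
})
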
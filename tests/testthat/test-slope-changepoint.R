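test_that("tie splitting permutes only within tie groups, deterministically", {
  camcog <- c(10, 30, 20, 50, 40)           # all distinct
  y <- c(1, 2, 3, 4, 5)
  for (seed in 1:5) {
    ts <- tie_split_ranks(camcog, y, seed)
    expect_equal(ts$camcog_sorted, sort(camcog))
    expect_equal(ts$order, order(camcog))
  }

  set.seed(88)
  camcog2 <- sample(rep(c(5, 9, 9, 9, 13, 13), 2))
  y2 <- rnorm(12)
  t1 <- tie_split_ranks(camcog2, y2, 42)
  t2 <- tie_split_ranks(camcog2, y2, 42)
  expect_identical(t1$order, t2$order)
  expect_true(all(sort(t1$order) == 1:12))
  # scores never swap across tie groups; the (camcog, y) multiset survives
  expect_equal(t1$camcog_sorted, sort(camcog2))
  expect_setequal(paste(t1$camcog_sorted, t1$series),
                  paste(camcog2, y2))
})

test_that("all tie orderings occur uniformly over seeds", {
  camcog <- rep(1, 4)
  y <- c(10, 20, 30, 40)
  draws <- vapply(1:24000, function(s) {
    paste(tie_split_ranks(camcog, y, s)$series, collapse = "-")
  }, character(1))
  counts <- table(draws)
  expect_equal(length(counts), 24)
  chisq <- sum((counts - 1000)^2 / 1000)
  # 24 cells, df 23: far tail only if the splits were non-uniform
  expect_lt(chisq, stats::qchisq(0.999, 23))
})

test_that("segmentation finds a constructed slope break and nothing on a line", {
  up_down <- c(seq(0, 1, length.out = 50), seq(1, 0, length.out = 50)[-1])
  cp <- segment_series(up_down, 8, 10)
  expect_equal(length(cp), 1)
  expect_lte(abs(cp - 50), 1)

  expect_length(segment_series(0.5 * (1:100), 8, 10), 0)
  set.seed(13)
  expect_length(segment_series(rnorm(100), 8, 180), 0)
  expect_error(segment_series(rnorm(20), 11, 10), "half the series")
  expect_error(segment_series(rnorm(20), 2, 10), "at least 3")
})

test_that("escalation stops at the first single change-point and degrades gracefully", {
  up_down <- c(seq(0, 1, length.out = 40), seq(1, 0, length.out = 40)[-1])
  sch <- data.frame(window = c(8, 12), tolerance = c(10, 20))
  e <- escalate_until_single(up_down, sch)
  expect_identical(e$status, "single")
  expect_equal(e$window, 8)
  expect_lte(abs(e$index - 40), 1)

  # two breaks of unequal angle: the stronger survives the coarsening
  two <- c(seq(0, 2, length.out = 40),
           seq(2, 1.55, length.out = 21)[-1],
           seq(1.55, -3, length.out = 40)[-1])
  esc <- escalate_until_single(two, data.frame(window = c(6, 6, 6, 8, 10),
                                               tolerance = c(5, 10, 20, 35, 60)))
  expect_true(esc$status %in% c("single", "absorbed"))
  expect_lt(abs(esc$index - 60), 6)

  # pure noise against a conservative schedule: a flag, not an exception
  set.seed(3)
  none <- escalate_until_single(rnorm(60) * 0.01 + 5,
                                data.frame(window = 10, tolerance = 179))
  expect_identical(none$status, "none")
  expect_true(is.na(none$index))
})

test_that("the resampled slope change-point is reproducible and collapses without ties", {
  cfgs <- default_scenarios()
  tab <- make_cohort(seed = 5)
  r1 <- slope_changepoint(tab$camcog, tab$tau, repetitions = 20,
                          master_seed = 9)
  r2 <- slope_changepoint(tab$camcog, tab$tau, repetitions = 20,
                          master_seed = 9)
  expect_identical(r1$estimates, r2$estimates)
  expect_equal(r1$median, stats::median(r1$estimates, na.rm = TRUE))

  one <- slope_changepoint(tab$camcog, tab$tau, repetitions = 1,
                           master_seed = 4)
  expect_equal(one$median, one$estimates[1])

  # tie-free scores: every repetition sees the same series
  set.seed(10)
  camcog <- sample(1:500, 120) / 5
  y <- 3 * pmax(camcog - 50, 0) + rnorm(120, 0, 2)
  res <- slope_changepoint(camcog, y, repetitions = 10, master_seed = 2)
  expect_equal(length(unique(res$estimates)), 1)
})

test_that("a trend-free biomarker raises the analysis-failed flag", {
  set.seed(41)
  camcog <- sample(0:107, 150, replace = TRUE)
  y <- rep(7, 150)                          # constant: no slope anywhere
  expect_warning(
    res <- slope_changepoint(camcog, y, repetitions = 10, master_seed = 1),
    "failed")
  expect_true(res$failed)
  expect_true(is.na(res$median))
})

test_that("the change-point distribution tightens as the slope contrast grows", {
  iqr_at <- function(contrast) {
    cfg <- scenario_config("bm", 90, contrast, 0, 500, 40, 40)
    tab <- generate_cohort(list(bm = cfg), 60, 60, seed = 31)
    res <- slope_changepoint(tab$camcog, tab$bm, repetitions = 40,
                             master_seed = 6)
    stats::IQR(res$estimates, na.rm = TRUE)
  }
  spreads <- vapply(c(2, 8, 32), iqr_at, numeric(1))
  expect_lt(spreads[3], spreads[1])
})
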
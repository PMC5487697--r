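test_that("interval_weights implements midpoint intervals with half-gap ends", {
  expect_equal(interval_weights(c(0, 7, 14, 21)), c(7, 7, 7, 7))
  expect_equal(interval_weights(10), 1)
  expect_equal(interval_weights(c(0, 10, 40)), c(10, 20, 30))
  expect_error(interval_weights(c(0, 10, 10)), "strictly increasing")
})

test_that("interval_weights are positive and sum to the period length", {
  set.seed(21)
  for (i in 1:30) {
    times <- sort(runif(sample(2:30, 1), 0, 365))
    w <- interval_weights(times)
    expect_true(all(w > 0))
    g <- diff(times)
    period <- max(times) - min(times) + (g[1] + g[length(g)]) / 2
    expect_equal(sum(w), period, tolerance = 1e-12)
  }
})

test_that("time_integrated_mean handles constant, equal-spaced and irregular series", {
  expect_equal(time_integrated_mean(c(5, 5, 5), c(3, 11, 40)), 5)
  expect_equal(time_integrated_mean(c(1, 2, 3), c(0, 7, 14)), 2)
  expect_equal(time_integrated_mean(c(1, 1, 4), c(0, 10, 40)), 2.5)
  expect_error(time_integrated_mean(numeric(0), numeric(0)), "empty")
})

test_that("time_integrated_mean equals the step-function integration oracle", {
  set.seed(31)
  for (i in 1:50) {
    n <- sample(1:40, 1)
    times <- sort(runif(n, 0, 365))
    if (n > 1) while (any(diff(times) <= 0)) times <- sort(runif(n, 0, 365))
    values <- rnorm(n, 10, 4)
    got <- time_integrated_mean(values, times)
    want <- step_function_mean(values, times)
    expect_equal(got, want, tolerance = 1e-10)
    expect_gte(got, min(values))
    expect_lte(got, max(values))
  }
})

test_that("time_integrated_mean is invariant to time shift and rescale", {
  values <- c(2, 9, 4, 7)
  times <- c(0, 6, 20, 33)
  base <- time_integrated_mean(values, times)
  expect_equal(time_integrated_mean(values, times + 123.4), base)
  expect_equal(time_integrated_mean(values, times * 7.7), base)
  # equal spacing reproduces the arithmetic mean exactly
  expect_identical(time_integrated_mean(values, c(0, 7, 14, 21)), mean(values))
})

test_that("area_summary computes between-station statistics with n-1 SD", {
  d <- make_grid(rep(4, 8), c("a", "b"), c(0, 7, 14, 21))
  a <- area_summary(d)
  expect_equal(a$area_mean, 4)
  expect_equal(a$cv_percent, 0)

  d2 <- make_grid(c(rep(3, 4), rep(5, 4)), c("a", "b"), c(0, 7, 14, 21))
  a2 <- area_summary(d2)
  expect_equal(a2$area_mean, 4)
  expect_equal(a2$sd, sqrt(2), tolerance = 1e-12)
  expect_equal(a2$cv_percent, 100 * sqrt(2) / 4, tolerance = 1e-12)
  expect_equal(a2$n_stations, 2)
})

test_that("area_summary cv is scale invariant and guards its preconditions", {
  d <- make_grid(c(1, 4, 2, 6, 3, 9, 2, 5), c("a", "b"), c(0, 7, 14, 21))
  a1 <- area_summary(d)
  d$value <- d$value * 37.5
  a2 <- area_summary(d)
  expect_equal(a1$cv_percent, a2$cv_percent, tolerance = 1e-12)

  expect_error(area_summary(d[d$station_id == "a", ]), "2 stations")
  # station with too few occasions is excluded with a warning
  d3 <- rbind(make_grid(c(1, 2, 3, 4, 5, 6, 7, 8), c("a", "b"), c(0, 7, 14, 21)),
              data.frame(station_id = "c", day = 0, value = 99))
  expect_warning(a3 <- area_summary(d3), "fewer than 4 occasions")
  expect_equal(a3$n_stations, 2)
})

test_that("variability_table matches hand-computed CVs on both axes", {
  const <- make_grid(rep(7, 6), c("a", "b"), c(1, 8, 15))
  expect_equal(variability_table(const, "over_time")$mean_cv, 0)
  expect_equal(variability_table(const, "over_stations")$mean_cv, 0)

  # identical stations: per-occasion CV is 0 even though values vary in time
  ident <- make_grid(c(1, 3, 1, 3), c("a", "b"), c(1, 8))
  expect_equal(variability_table(ident, "over_time")$mean_cv, 0)

  # station a = (2, 4), station b = (6, 8): hand CVs with n-1 denominator
  d <- make_grid(c(2, 4, 6, 8), c("a", "b"), c(1, 8))
  vt <- variability_table(d, "over_stations")
  expect_equal(unname(vt$cv_percent[c("a", "b")]),
               c(100 * sd(c(2, 4)) / 3, 100 * sd(c(6, 8)) / 7),
               tolerance = 1e-12)
  expect_equal(vt$mean_cv, 33.67175, tolerance = 1e-5)
  expect_equal(vt$cv_range, sort(unname(vt$cv_percent)))
})

test_that("log-transformed variability uses natural logs and geometric grand mean", {
  d <- make_grid(c(2, 4, 6, 8), c("a", "b"), c(1, 8))
  vt <- variability_table(d, "over_stations", "log")
  expect_equal(vt$grand_mean, exp(mean(log(c(2, 4, 6, 8)))), tolerance = 1e-12)
  expect_equal(unname(vt$cv_percent[["a"]]),
               100 * sd(log(c(2, 4))) / mean(log(c(2, 4))), tolerance = 1e-12)
  d$value[2] <- -1
  expect_error(variability_table(d, "over_time", "log"), "positive")
})

test_that("normality_check flags skewed data and passes normal data", {
  x <- c(1, 2, 3, 4, 100)
  nc <- normality_check(x)
  expect_gt(nc$W, 0)
  expect_lte(nc$W, 1)
  expect_error(normality_check(rep(1, 10)), "identical")
  expect_error(normality_check(c(1, 2)), "between 3 and 5000")

  set.seed(41)
  p_norm <- replicate(200, normality_check(rnorm(21))$p)
  expect_gte(mean(p_norm > 0.05), 0.90)
  p_skew <- replicate(200, normality_check(exp(rnorm(21, sd = 1.5)))$p)
  expect_gte(mean(p_skew < 0.05), 0.80)
})
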
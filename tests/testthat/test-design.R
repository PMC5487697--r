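cm <- cost_model(A = 1, B = 20, n = 3, m = 0.1, N_time = 12)

test_that("survey_cost evaluates the linear cost model", {
  expect_equal(survey_cost(cm, 0), 20)
  expect_equal(survey_cost(cm, 1.53846), 28, tolerance = 0.002)
  cm2 <- cost_model(A = 0, B = 0, n = 1, m = 1, N_time = 2)
  expect_equal(survey_cost(cm2, 3), 6)
})

test_that("stations_from_budget inverts the cost model", {
  expect_equal(stations_from_budget(cm, 28), 8 / (12 * (1 / 3 + 0.1)),
               tolerance = 1e-12)
  one <- cm$B + cm$N_time * (cm$A / cm$n + cm$sum_m)
  expect_equal(stations_from_budget(cm, one), 1)
  expect_error(stations_from_budget(cm, 19), "below fixed costs")
})

test_that("budget and station count round-trip to machine precision", {
  set.seed(51)
  for (i in 1:20) {
    model <- cost_model(A = runif(1, 0.5, 5), B = runif(1, 0, 50),
                        n = runif(1, 1, 6), m = runif(3, 0, 1),
                        N_time = sample(4:24, 1))
    N <- runif(1, 0.1, 40)
    expect_equal(stations_from_budget(model, survey_cost(model, N)), N,
                 tolerance = 1e-10)
    budget <- model$B + runif(1, 1, 100)
    expect_equal(survey_cost(model, stations_from_budget(model, budget)),
                 budget, tolerance = 1e-10)
  }
})

test_that("ci_percent follows t * CV / sqrt(N)", {
  expect_equal(ci_percent(6.21, 1), 12.48, tolerance = 0.005)
  expect_equal(ci_percent(0, 17), 0)
  expect_lte(ci_percent(12.36, 25), 5)
  expect_equal(ci_percent(12.36, 25), 2.01 * 12.36 / 5, tolerance = 1e-12)
  # halves when N quadruples
  expect_equal(ci_percent(8, 36), ci_percent(8, 9) / 2, tolerance = 1e-12)
  # exact mode uses the t quantile at df = ceil(N) - 1
  expect_equal(ci_percent(10, 21, "exact"),
               qt(0.975, 20) * 10 / sqrt(21), tolerance = 1e-12)
  expect_error(ci_percent(10, 1.5, "exact"), "N >= 2")
})

test_that("stations_for_precision returns the minimal sufficient station count", {
  expect_equal(stations_for_precision(12.36, 5), 25L)
  expect_equal(stations_for_precision(10.83, 5), 19L)
  expect_equal(stations_for_precision(1, 2.01), 1L)
  expect_equal(stations_for_precision(1, 50), 1L)
  # minimality and sufficiency on a grid of cases
  for (cv in c(0.5, 3, 7.3, 12.36)) {
    for (target in c(1, 5, 12)) {
      N <- stations_for_precision(cv, target)
      expect_lte(ci_percent(cv, N), target)
      if (N > 1) expect_gt(ci_percent(cv, N - 1), target)
    }
  }
  # quadruples (up to ceiling) when the target halves
  expect_equal(stations_for_precision(12.36, 2.5), 99L)  # ceil(4 * 24.686) - 1e-9
})

test_that("cost_for_precision prices a precision target", {
  expect_equal(cost_for_precision(cm, 12.36, 20), 28.02, tolerance = 0.005)
  expect_equal(round(cost_for_precision(cm, 12.36, 20)), 28)
  # direct evaluation oracle
  N <- (2.01 * 4.76 / 9.56)^2
  expect_equal(cost_for_precision(cm, 4.76, 9.56),
               12 * N * (1 / 3 + 0.1) + 20, tolerance = 1e-12)
  # cost tends to the fixed cost as the requirement is relaxed
  expect_equal(cost_for_precision(cm, 12.36, 1e9), cm$B, tolerance = 1e-6)
  # integer mode rounds stations up before pricing
  expect_equal(cost_for_precision(cm, 12.36, 20, continuous = FALSE),
               survey_cost(cm, 2))
})

test_that("budget_for_portfolio budgets for the worst variable", {
  cvs <- c(salinity = 6.21, temperature = 0.97, extinction = 12.36,
           oxygen = 0.55, cdom = 10.83, chlorophyll = 4.76)
  b <- budget_for_portfolio(cm, cvs, 20)
  expect_equal(b$budget, 28)
  expect_equal(b$worst_variable, "extinction")
  expect_equal(b$N_space, (2.01 * 12.36 / 20)^2, tolerance = 1e-12)
  expect_equal(unname(b$achieved_ci["extinction"]), 20, tolerance = 1e-12)
  expect_equal(unname(b$achieved_ci["oxygen"]),
               2.01 * 0.55 / sqrt(b$N_space), tolerance = 1e-12)
  expect_lt(unname(b$achieved_ci["oxygen"]), 0.9)
  # a single variable priced at N = 1 costs one station-year plus overhead
  b1 <- budget_for_portfolio(cm, c(x = 1), target_ci = 2.01)
  expect_equal(b1$budget_exact, cm$B + cm$N_time * (cm$A / cm$n + cm$sum_m),
               tolerance = 1e-12)
})

test_that("power_one_sample agrees with stats::power.t.test", {
  expect_equal(power_one_sample(10, 0), 0.05, tolerance = 1e-12)
  for (n in c(5, 10, 25)) {
    for (d in c(0.3, 0.8, 1.5)) {
      want <- stats::power.t.test(n = n, delta = d, sd = 1,
                                  type = "one.sample", strict = TRUE)$power
      expect_equal(power_one_sample(n, d), want, tolerance = 1e-8)
    }
  }
  expect_gte(power_one_sample(10, 5 / 4.76), 0.8)
  expect_lt(power_one_sample(9, 5 / 4.76), 0.8)
  expect_error(power_one_sample(1, 0.5), "n >= 2")
})

test_that("min_n_for_power is minimal and matches a brute-force scan", {
  expect_equal(min_n_for_power(20), 2L)  # floor of the search
  # n = 2 has little power even for large d (heavy-tailed df = 1 null)
  expect_equal(min_n_for_power(10), 3L)
  for (d in seq(0.1, 3.0, by = 0.1)) {
    n_grid <- 2:5000
    brute <- n_grid[which(power_one_sample(n_grid, d) >= 0.8)[1]]
    expect_equal(min_n_for_power(d), brute)
  }
})

test_that("power_curve is monotone and saturates for huge effects", {
  pc <- power_curve(5 / 10.83, 60)
  expect_true(all(diff(pc$power) > 0))
  expect_lt(pc$power[pc$n == 38], 0.8)
  expect_gte(pc$power[pc$n == 39], 0.8)
  sat <- power_curve(50, 5)
  expect_true(all(sat$power > 0.999))
})

test_that("design_table combines precision and power requirements per variable", {
  cvs <- c(chlorophyll = 4.76, oxygen = 0.55)
  tab <- design_table(cvs, target_ci = 5, deltas = c(5, 10))
  expect_equal(tab$ci_prefactor, 2.01 * c(4.76, 0.55), tolerance = 1e-12)
  expect_equal(tab$stations_for_target,
               stations_for_precision(c(4.76, 0.55), 5))
  expect_equal(tab$min_n_5_percent, c(10L, 3L))
  expect_equal(tab$min_n_10_percent, c(5L, 2L))
  # degenerate zero CV short-circuits to the smallest testable sample
  tab0 <- design_table(c(flat = 0))
  expect_equal(tab0$min_n_5_percent, 2L)
  expect_equal(tab0$stations_for_target, 1L)
})
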
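#' Linear cost model for a monitoring survey
#'
#' The annual cost of a survey with `N_time` cruises per year and `N_space`
#' stations per cruise is
#' `Cost = N_time * N_space * (A / n + sum(m)) + B`:
#' every station costs its share of a ship day plus the per-variable
#' sampling and analysis costs, and `B` collects the fixed labor, reporting
#' and overhead costs that do not scale with effort. Costs are in whatever
#' relative or absolute units the user supplies.
#'
#' @param A Cost per research-ship day.
#' @param B Fixed labor/overhead cost.
#' @param n Average number of stations worked per cruise day (> 0).
#' @param m Per-variable sampling + analysis costs; a vector, summed
#'   internally.
#' @param N_time Number of surveys per year (>= 1), typically chosen with
#'   [min_frequency()].
#' @return Object of class `cost_model`.
#' @examples
#' cm <- cost_model(A = 1, B = 20, n = 3, m = 0.1, N_time = 12)
#' survey_cost(cm, N_space = 5)
#' @export
cost_model <- function(A = 1, B = 20, n = 3, m = 0.1, N_time = 12) {
  stopifnot(A >= 0, B >= 0, n > 0, all(m >= 0), N_time >= 1)
  structure(list(A = A, B = B, n = n, m = m, sum_m = sum(m), N_time = N_time),
            class = "cost_model")
}

#' @export
print.cost_model <- function(x, ...) {
  cat(sprintf(
    "Cost model: A = %g (ship/day), B = %g (fixed), n = %g stations/day,\n",
    x$A, x$B, x$n))
  cat(sprintf("  sum(m) = %g per station, N_time = %g surveys/year\n",
              x$sum_m, x$N_time))
  cat(sprintf("  marginal cost per station-year: %g\n",
              x$N_time * (x$A / x$n + x$sum_m)))
  invisible(x)
}

#' Total survey cost for a given number of stations
#'
#' @param model A [cost_model()].
#' @param N_space Stations per survey (>= 0; may be fractional when
#'   exploring budget curves).
#' @return Cost in the model's units.
#' @export
survey_cost <- function(model, N_space) {
  stopifnot(inherits(model, "cost_model"), all(N_space >= 0))
  model$N_time * N_space * (model$A / model$n + model$sum_m) + model$B
}

#' Number of stations affordable under a budget
#'
#' Inverts the cost model:
#' `N_space = (budget - B) / (N_time * (A / n + sum(m)))`.
#' The fractional value is returned; rounding down to whole stations is the
#' caller's decision.
#'
#' @param model A [cost_model()].
#' @param budget Available budget; must exceed the fixed cost `B`.
#' @return Fractional number of stations per survey.
#' @export
stations_from_budget <- function(model, budget) {
  stopifnot(inherits(model, "cost_model"))
  if (any(budget <= model$B)) {
    stop(sprintf("budget below fixed costs (B = %g)", model$B))
  }
  (budget - model$B) / (model$N_time * (model$A / model$n + model$sum_m))
}

# two-sided 95% t multiplier: fixed calibration constant or exact quantile
t_multiplier <- function(N, t_mode = c("fixed", "exact"), t_value = 2.01,
                         alpha = 0.05) {
  t_mode <- match.arg(t_mode)
  if (t_mode == "fixed") return(t_value)
  if (any(N < 2)) stop("exact t multiplier requires N >= 2 (df >= 1)")
  stats::qt(1 - alpha / 2, ceiling(N) - 1)
}

# fractional N with ci_percent(cv, N) = target; exact mode needs a fixed
# point because the t quantile depends on the df implied by N
solve_N_continuous <- function(cv, target_ci, t_mode = c("fixed", "exact"),
                               t_value = 2.01) {
  t_mode <- match.arg(t_mode)
  N <- (t_value * cv / target_ci)^2
  if (t_mode == "exact") {
    for (i in 1:100) {
      N_new <- (t_multiplier(max(2, N), "exact") * cv / target_ci)^2
      if (abs(N_new - N) < 1e-12) break
      N <- N_new
    }
  }
  N
}

#' Precision of the area mean as a percent confidence half-width
#'
#' The 95% confidence half-width of a mean of `N` station values, expressed
#' as a percent of the mean, is `CI% = t * CV% / sqrt(N)`. In `"fixed"` mode
#' the multiplier is the calibration constant `t_value` (default 2.01, the
#' two-sided 95% Student t multiplier for about 20 stations, convenient for
#' planning because it makes CI% a pure power law in N); `"exact"` mode uses
#' the two-sided 97.5th t quantile with `ceiling(N) - 1` degrees of freedom.
#'
#' @param cv Between-station coefficient of variation, percent (>= 0).
#' @param N Number of stations (> 0; fractional allowed in `"fixed"` mode).
#' @param t_mode `"fixed"` or `"exact"`.
#' @param t_value Multiplier used in `"fixed"` mode.
#' @return CI half-width in percent of the mean.
#' @examples
#' ci_percent(6.21, 1)    # one station: 12.48%
#' ci_percent(12.36, 25)  # under 5%
#' @export
ci_percent <- function(cv, N, t_mode = c("fixed", "exact"), t_value = 2.01) {
  stopifnot(all(cv >= 0), all(N > 0))
  t_multiplier(N, t_mode, t_value) * cv / sqrt(N)
}

#' Stations needed to reach a target precision
#'
#' Smallest integer `N >= 1` with `ci_percent(cv, N) <= target_ci`; in
#' `"fixed"` mode this is `ceiling((t * cv / target_ci)^2)`.
#'
#' @inheritParams ci_percent
#' @param target_ci Required CI half-width, percent (> 0).
#' @return Integer number of stations.
#' @examples
#' stations_for_precision(12.36, 5)  # 25
#' stations_for_precision(10.83, 5)  # 19
#' @export
stations_for_precision <- function(cv, target_ci, t_mode = c("fixed", "exact"),
                                   t_value = 2.01) {
  t_mode <- match.arg(t_mode)
  stopifnot(all(target_ci > 0), all(cv >= 0))
  if (t_mode == "fixed") {
    return(pmax(1L, as.integer(ceiling((t_value * cv / target_ci)^2 - 1e-9))))
  }
  vapply(seq_along(cv), function(i) {
    N <- 1L
    repeat {
      ci <- if (N < 2) ci_percent(cv[i], N, "fixed", t_value)
            else ci_percent(cv[i], N, "exact")
      if (ci <= target_ci[min(i, length(target_ci))]) return(N)
      N <- N + 1L
    }
  }, integer(1))
}

#' Cost of reaching a target precision for one variable
#'
#' Solves `CI% = target` for the number of stations, then prices it with
#' [survey_cost()]. `continuous = TRUE` keeps the fractional station count
#' (smooth cost-precision curves); `continuous = FALSE` rounds up to whole
#' stations first.
#'
#' @inheritParams stations_for_precision
#' @param model A [cost_model()].
#' @param continuous Keep fractional stations? Default `TRUE`.
#' @return Cost in the model's units.
#' @examples
#' cm <- cost_model()
#' cost_for_precision(cm, cv = 12.36, target_ci = 20)  # ~28
#' @export
cost_for_precision <- function(model, cv, target_ci, continuous = TRUE,
                               t_mode = c("fixed", "exact"), t_value = 2.01) {
  t_mode <- match.arg(t_mode)
  N <- if (continuous) {
    solve_N_continuous(cv, target_ci, t_mode, t_value)
  } else {
    stations_for_precision(cv, target_ci, t_mode, t_value)
  }
  survey_cost(model, N)
}

#' Minimal budget for a precision target across a variable portfolio
#'
#' A survey measures all variables at every station, so the station count —
#' and hence the budget — is set by the variable with the largest CV%. The
#' budget is computed in continuous mode and rounded to the nearest whole
#' cost unit for reporting; the achieved precision of every variable at the
#' allocated (fractional) station count is returned alongside.
#'
#' @param model A [cost_model()].
#' @param cvs Named numeric vector of per-variable CV%.
#' @param target_ci Required CI half-width (percent) for every variable.
#' @inheritParams ci_percent
#' @return Object of class `portfolio_budget`: list with `budget` (rounded),
#'   `budget_exact`, `N_space` (fractional stations), `worst_variable`, and
#'   `achieved_ci` (named vector, percent).
#' @examples
#' cvs <- c(salinity = 6.21, temperature = 0.97, extinction = 12.36,
#'          oxygen = 0.55, cdom = 10.83, chlorophyll = 4.76)
#' budget_for_portfolio(cost_model(), cvs, target_ci = 20)
#' @export
budget_for_portfolio <- function(model, cvs, target_ci,
                                 t_mode = c("fixed", "exact"), t_value = 2.01) {
  t_mode <- match.arg(t_mode)
  stopifnot(length(cvs) >= 1, target_ci > 0)
  worst <- which.max(cvs)
  N <- solve_N_continuous(cvs[[worst]], target_ci, t_mode, t_value)
  tmult <- t_multiplier(max(2, N), t_mode, t_value)
  cost <- survey_cost(model, N)
  achieved <- if (N > 0) tmult * cvs / sqrt(N) else 0 * cvs
  structure(
    list(budget = round(cost), budget_exact = cost, N_space = unname(N),
         worst_variable = names(cvs)[worst] %||% worst,
         achieved_ci = achieved, target_ci = target_ci),
    class = "portfolio_budget"
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.portfolio_budget <- function(x, ...) {
  cat(sprintf(
    "Budget for CI%% <= %g on all variables: %g units (exact %.3f)\n",
    x$target_ci, x$budget, x$budget_exact))
  cat(sprintf("  binding variable: %s; stations per survey: %.3f\n",
              x$worst_variable, x$N_space))
  cat("  achieved CI% per variable:\n")
  print(round(x$achieved_ci, 2))
  invisible(x)
}

#' Power of the two-sided one-sample t test
#'
#' Power to detect a true shift of `d` standard deviations in the mean of
#' `n` station-level time-integrated averages, at two-sided significance
#' `alpha`. Computed from the noncentral t distribution with `n - 1` degrees
#' of freedom and noncentrality `d * sqrt(n)`. When the change is expressed
#' as a percent of the mean and spread as CV%, the standardized effect is
#' `d = delta_percent / cv_percent`.
#'
#' @param n Sample size (stations), >= 2. Vectorized.
#' @param d Standardized effect size (> 0 for a real change; `d = 0` returns
#'   `alpha`).
#' @param alpha Two-sided significance level. Default 0.05.
#' @return Power in `[0, 1]`.
#' @examples
#' power_one_sample(10, d = 5 / 4.76)  # > 0.8
#' @export
power_one_sample <- function(n, d, alpha = 0.05) {
  stopifnot(all(n >= 2), d >= 0, alpha > 0, alpha < 1)
  tc <- stats::qt(1 - alpha / 2, n - 1)
  ncp <- d * sqrt(n)
  stats::pt(tc, n - 1, ncp = ncp, lower.tail = FALSE) +
    stats::pt(-tc, n - 1, ncp = ncp)
}

#' Minimum sample size for a target power
#'
#' Smallest `n >= 2` whose one-sample two-sided t-test power reaches
#' `power`. Used to answer: how many stations are needed to detect a 5% (or
#' 10%) change in a variable's seasonal mean between two years?
#'
#' @param d Standardized effect size, > 0 (`delta_percent / cv_percent`).
#' @param power Target power. Default 0.8.
#' @param alpha Two-sided significance level. Default 0.05.
#' @return Integer sample size.
#' @examples
#' min_n_for_power(5 / 4.76)   # chlorophyll-like CV, 5% change: 10
#' min_n_for_power(10 / 12.36) # high-CV variable, 10% change: 15
#' @export
min_n_for_power <- function(d, power = 0.8, alpha = 0.05) {
  stopifnot(d > 0, power > 0, power < 1)
  n <- 2L
  while (power_one_sample(n, d, alpha) < power) {
    n <- n + 1L
    if (n > 1e6) stop("sample size search exceeded 1e6")  # unreachable for d > 0
  }
  n
}

#' Power as a function of sample size
#'
#' @inheritParams min_n_for_power
#' @param n_max Largest sample size to tabulate (>= 2).
#' @return Data frame with columns `n` and `power`, for `n = 2, ..., n_max`;
#'   strictly increasing in `n` for fixed `d > 0`.
#' @export
power_curve <- function(d, n_max, alpha = 0.05) {
  stopifnot(n_max >= 2)
  n <- 2:n_max
  data.frame(n = n, power = power_one_sample(n, d, alpha))
}

#' Per-variable design table: precision and power requirements
#'
#' Convenience summary combining the precision and power calculus for a set
#' of variables: CI% at a reference station count, stations needed for a
#' target CI%, and minimum sample sizes to detect each percent change in
#' `deltas` with the given power.
#'
#' @param cvs Named numeric vector of per-variable CV%.
#' @param n_ref Reference station count for the achieved-CI column.
#' @param target_ci Target precision (percent) for the station-count column.
#' @param deltas Percent changes to detect. Default `c(5, 10)`.
#' @param power Target power. Default 0.8.
#' @param alpha Two-sided significance level. Default 0.05.
#' @inheritParams ci_percent
#' @return Data frame with one row per variable.
#' @export
design_table <- function(cvs, n_ref = 1, target_ci = 5, deltas = c(5, 10),
                         power = 0.8, alpha = 0.05,
                         t_mode = c("fixed", "exact"), t_value = 2.01) {
  t_mode <- match.arg(t_mode)
  out <- data.frame(
    variable = names(cvs) %||% seq_along(cvs),
    cv_percent = unname(cvs),
    ci_prefactor = t_multiplier(max(2, n_ref), t_mode, t_value) * unname(cvs),
    stations_for_target = stations_for_precision(unname(cvs), target_ci,
                                                 t_mode, t_value),
    row.names = NULL
  )
  for (delta in deltas) {
    out[[sprintf("min_n_%g_percent", delta)]] <-
      vapply(unname(cvs), function(cv) {
        if (cv <= 0) return(2L)  # no spread: any change detectable at n = 2
        min_n_for_power(delta / cv, power, alpha)
      }, integer(1))
  }
  attr(out, "target_ci") <- target_ci
  out
}
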
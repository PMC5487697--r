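# Independent oracles used across the suite. These deliberately avoid the
# package's own weight arithmetic.

# Exact integral of the piecewise-constant midpoint step function divided by
# the period length: breakpoints at the midpoints between sampling times,
# period extended half a gap beyond the terminal samples.
step_function_mean <- function(values, times) {
  n <- length(times)
  if (n == 1) return(values)
  g <- diff(times)
  lo <- times[1] - g[1] / 2
  hi <- times[n] + g[n - 1] / 2
  breaks <- c(lo, (times[-1] + times[-n]) / 2, hi)
  sum(values * diff(breaks)) / (hi - lo)
}

# hand-rolled OLS slope/intercept (no lm): used to cross-check the
# log-linear extinction fit
ols_by_hand <- function(x, y) {
  slope <- sum((x - mean(x)) * (y - mean(y))) / sum((x - mean(x))^2)
  c(intercept = mean(y) - slope * mean(x), slope = slope)
}

# simulated rejection rate of the two-sided one-sample t test at effect d
simulated_rejection_rate <- function(n, d, n_rep = 10000, alpha = 0.05) {
  x <- matrix(rnorm(n_rep * n, mean = d, sd = 1), nrow = n_rep)
  m <- rowMeans(x)
  s <- sqrt(rowSums((x - m)^2) / (n - 1))
  tstat <- m / (s / sqrt(n))
  mean(abs(tstat) > qt(1 - alpha / 2, n - 1))
}

# small station x occasion data frame used by several tests
make_grid <- function(values, stations, days) {
  d <- expand.grid(station_id = stations, day = days,
                   stringsAsFactors = FALSE)
  d <- d[order(d$station_id, d$day), ]
  d$value <- values
  rownames(d) <- NULL
  d
}
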
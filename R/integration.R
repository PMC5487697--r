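#' Midpoint interval weights for an irregular time series
#'
#' Each observation represents the interval reaching halfway to its
#' neighbours; the period is extended by half the first and last gaps beyond
#' the terminal samples, so the weights of an equally spaced series are all
#' equal and the time-weighted mean reduces to the arithmetic mean. A single
#' observation receives weight 1.
#'
#' @param times Numeric vector of sampling times (e.g. day of year),
#'   strictly increasing, length >= 1.
#' @return Numeric vector of weights, same length as `times`, summing to the
#'   period length `t_N - t_1 + (g_1 + g_{N-1})/2` for N >= 2.
#' @examples
#' interval_weights(c(0, 7, 14, 21))  # 7 7 7 7
#' interval_weights(c(0, 10, 40))     # 10 20 30
#' @export
interval_weights <- function(times) {
  stopifnot(is.numeric(times), length(times) >= 1)
  if (length(times) == 1) return(1)
  if (any(diff(times) <= 0)) stop("`times` must be strictly increasing")
  n <- length(times)
  g <- diff(times)
  w <- numeric(n)
  w[1] <- g[1]
  w[n] <- g[n - 1]
  if (n > 2) w[2:(n - 1)] <- (times[3:n] - times[1:(n - 2)]) / 2
  w
}

#' Time-integrated mean of an irregular series
#'
#' The seasonal (or annual) average of a station is computed as
#' `sum(x_i * w_i) / sum(w_i)` with midpoint interval weights from
#' [interval_weights()]. This equals the integral of the piecewise-constant
#' midpoint step function divided by the period length, and reduces to the
#' arithmetic mean for equally spaced series. Collapsing a station's series
#' to this single number is the pooling step that removes seasonal trend,
#' autocorrelation and non-normality from all downstream statistics.
#'
#' @param values Numeric vector of measurements.
#' @param times Sampling times, strictly increasing, same length as `values`.
#' @return Length-1 numeric, always within `range(values)`.
#' @examples
#' time_integrated_mean(c(1, 2, 3), c(0, 7, 14))   # 2 (equal spacing)
#' time_integrated_mean(c(1, 1, 4), c(0, 10, 40))  # 2.5
#' @export
time_integrated_mean <- function(values, times) {
  stopifnot(is.numeric(values), length(values) == length(times))
  if (length(values) == 0) stop("empty series")
  if (anyNA(values) || anyNA(times)) stop("missing values are not allowed")
  w <- interval_weights(times)
  # equal weights reduce to the arithmetic mean; take that branch exactly
  if (all(w == w[1])) return(mean(values))
  sum(values * w) / sum(w)
}

#' Area summary: time-integrated station means and their between-station CV
#'
#' Integrates each station's series with [time_integrated_mean()], then
#' treats the station means as exchangeable replicates of the area mean:
#' reports their arithmetic mean, sample standard deviation (denominator
#' n - 1) and coefficient of variation `CV% = 100 * sd / mean`. This CV% is
#' the precision currency of the whole design calculus (see [ci_percent()]).
#'
#' @param data Data frame with columns `station_id`, `day`, `value` holding
#'   one variable's station x occasion values (e.g. one variable of
#'   [cast_summaries()] output).
#' @param variable Optional variable label stored in the result.
#' @param min_points Stations with fewer occasions than this are excluded
#'   with a warning. Default 4.
#' @return Object of class `area_summary`: list with `variable`,
#'   `station_means` (named numeric), `area_mean`, `sd`, `cv_percent`
#'   (`NA` with a warning if the mean is 0), and `n_stations`.
#' @examples
#' d <- expand.grid(station_id = c("a", "b"), day = c(0, 7, 14))
#' d$value <- ifelse(d$station_id == "a", 3, 5)
#' area_summary(d)$cv_percent
#' @export
area_summary <- function(data, variable = NA_character_, min_points = 4) {
  stopifnot(is.data.frame(data),
            all(c("station_id", "day", "value") %in% names(data)))
  series <- split(data, data$station_id, drop = TRUE)
  if (length(series) < 2) stop("at least 2 stations are required")
  means <- vapply(series, function(s) {
    if (nrow(s) < min_points) return(NA_real_)
    s <- s[order(s$day), ]
    time_integrated_mean(s$value, s$day)
  }, numeric(1))
  if (anyNA(means)) {
    warning(sprintf("excluding %d station(s) with fewer than %d occasions: %s",
                    sum(is.na(means)), min_points,
                    paste(names(means)[is.na(means)], collapse = ", ")))
    means <- means[!is.na(means)]
  }
  if (length(means) < 2) stop("fewer than 2 stations remain after exclusions")
  m <- mean(means)
  s <- stats::sd(means)
  cv <- if (m == 0) {
    warning("area mean is 0; CV% undefined")
    NA_real_
  } else 100 * s / m
  structure(
    list(variable = variable, station_means = means, area_mean = m, sd = s,
         cv_percent = cv, n_stations = length(means)),
    class = "area_summary"
  )
}

#' @export
print.area_summary <- function(x, ...) {
  cat(sprintf("Area summary%s: %d stations\n",
              if (is.na(x$variable)) "" else paste0(" [", x$variable, "]"),
              x$n_stations))
  cat(sprintf("  time-integrated area mean %.4g, sd %.4g, CV%% %.2f\n",
              x$area_mean, x$sd, x$cv_percent))
  invisible(x)
}

#' Spatial or temporal variability of raw station x occasion values
#'
#' Quantifies the variability that time integration removes. With
#' `axis = "over_time"` a CV% across stations is computed for every sampling
#' occasion (spatial spread of a single-day snapshot); with
#' `axis = "over_stations"` a CV% across occasions is computed for every
#' station (temporal spread of a single fixed station). The per-unit CVs are
#' summarised by their mean and range. `transform = "log"` applies the
#' natural log elementwise before the same mean/SD/CV arithmetic; its grand
#' mean is reported back-transformed (geometric mean).
#'
#' @param data Data frame with columns `station_id`, `day`, `value`.
#' @param axis `"over_time"` or `"over_stations"`.
#' @param transform `"raw"` or `"log"` (natural log; all values must be
#'   positive).
#' @param variable Optional variable label stored in the result.
#' @return Object of class `variability_table`: list with `axis`,
#'   `transform`, `cv_percent` (named per-unit vector), `mean_cv`,
#'   `cv_range`, `grand_mean`, and `variable`.
#' @examples
#' d <- expand.grid(station_id = c("a", "b"), day = c(1, 8))
#' d$value <- c(2, 6, 4, 8)
#' variability_table(d, "over_stations")$cv_percent
#' @export
variability_table <- function(data, axis = c("over_time", "over_stations"),
                              transform = c("raw", "log"),
                              variable = NA_character_) {
  axis <- match.arg(axis)
  transform <- match.arg(transform)
  stopifnot(is.data.frame(data),
            all(c("station_id", "day", "value") %in% names(data)))
  x <- data$value
  if (transform == "log") {
    bad <- which(x <= 0)
    if (length(bad)) {
      stop(sprintf("log transform requires positive values; offending rows: %s",
                   paste(utils::head(bad, 10), collapse = ", ")))
    }
    x <- log(x)
  }
  unit <- if (axis == "over_time") data$day else data$station_id
  groups <- split(x, unit)
  cvs <- vapply(groups, function(v) {
    m <- mean(v)
    if (m == 0) return(NA_real_)
    100 * stats::sd(v) / m
  }, numeric(1))
  gm <- if (transform == "log") exp(mean(x)) else mean(x)
  structure(
    list(variable = variable, axis = axis, transform = transform,
         cv_percent = cvs, mean_cv = mean(cvs, na.rm = TRUE),
         cv_range = range(cvs, na.rm = TRUE), grand_mean = gm),
    class = "variability_table"
  )
}

#' @export
print.variability_table <- function(x, ...) {
  cat(sprintf("Variability (%s, %s)%s: grand mean %.4g\n", x$axis, x$transform,
              if (is.na(x$variable)) "" else paste0(" [", x$variable, "]"),
              x$grand_mean))
  cat(sprintf("  mean CV%% %.2f (range %.2f-%.2f over %d units)\n",
              x$mean_cv, x$cv_range[1], x$cv_range[2], length(x$cv_percent)))
  invisible(x)
}

#' Shapiro-Wilk normality check of station-level integrated means
#'
#' The precision and power calculus assumes the time-integrated station
#' means are approximately normal; this wraps the Shapiro-Wilk test so that
#' assumption can be checked on a pilot dataset. A p-value above the chosen
#' significance level indicates no detectable deviation from normality.
#'
#' @param values Numeric vector, 3 to 5000 values, not all identical.
#' @return List with `W` (test statistic) and `p` (p-value).
#' @export
normality_check <- function(values) {
  stopifnot(is.numeric(values))
  if (length(values) < 3 || length(values) > 5000) {
    stop("Shapiro-Wilk requires between 3 and 5000 values")
  }
  if (stats::sd(values) == 0) stop("values are all identical; test undefined")
  ht <- stats::shapiro.test(values)
  list(W = unname(ht$statistic), p = ht$p.value)
}
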
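#' Evenly thinned subsampling schedule
#'
#' Selects `n_keep` of `n_total` occasions as evenly as possible:
#' occasion indices `floor(j * n_total / n_keep) + 1` for
#' `j = 0, ..., n_keep - 1`, shifted by `phase`. When `n_total` is divisible
#' by `n_keep` the schedule is exactly periodic (every 2nd, every 6th, ...).
#'
#' @param n_total Number of available occasions.
#' @param n_keep Number of occasions to retain, between 1 and `n_total`.
#' @param phase Non-negative integer shift applied to all indices; must not
#'   push the last index past `n_total`. Default 0 keeps the first occasion.
#' @return Integer vector of 1-based occasion indices, strictly increasing.
#' @examples
#' subsample_schedule(24, 12)  # every 2nd occasion
#' subsample_schedule(24, 5)   # 1 5 10 15 20
#' @export
subsample_schedule <- function(n_total, n_keep, phase = 0) {
  stopifnot(n_total >= 1, n_keep >= 1, n_keep <= n_total,
            phase >= 0, phase == as.integer(phase))
  idx <- floor((seq_len(n_keep) - 1) * n_total / n_keep) + 1L + as.integer(phase)
  if (idx[length(idx)] > n_total) {
    stop(sprintf("schedule overflow: phase %d pushes last index to %d > %d",
                 phase, idx[length(idx)], n_total))
  }
  idx
}

#' Sampling-frequency reduction analysis
#'
#' Recomputes the area mean of time-integrated station averages under
#' progressively thinned sampling schedules and expresses each result as a
#' percentage of the full-frequency reference (the "true value", 100%).
#' A reduced frequency is acceptable when its standardized mean stays within
#' `tolerance` percent of 100. The 95% confidence interval is computed
#' across stations with Student's t (df = stations - 1) and standardized the
#' same way.
#'
#' @param data Data frame with columns `station_id`, `day`, `value` for one
#'   variable; every station must share the same occasion grid.
#' @param keep_counts Occasion counts to evaluate; must include the full
#'   count as reference. Default `c(24, 12, 8, 6, 5, 4)` steps weekly
#'   sampling down to one occasion per six weeks.
#' @param tolerance Acceptance half-width in percent of the reference.
#'   Default 5.
#' @param phase Schedule shift passed to [subsample_schedule()].
#' @param variable Optional variable label stored in the result.
#' @return A `frequency_result` data frame with one row per element of
#'   `keep_counts`: `n_keep`, `mean` (raw area mean), `standardized_mean`,
#'   `ci95_low`, `ci95_high` (both standardized), `within_tolerance`.
#' @examples
#' d <- expand.grid(station_id = letters[1:3], day = seq(1, 162, by = 7))
#' d$value <- 5 + 0.01 * d$day
#' frequency_analysis(d, keep_counts = c(24, 12, 6))
#' @export
frequency_analysis <- function(data, keep_counts = c(24, 12, 8, 6, 5, 4),
                               tolerance = 5, phase = 0,
                               variable = NA_character_) {
  stopifnot(is.data.frame(data),
            all(c("station_id", "day", "value") %in% names(data)))
  days <- sort(unique(data$day))
  n_total <- length(days)
  if (max(keep_counts) != n_total) {
    stop(sprintf("max(keep_counts) = %d must equal the %d occasions available",
                 max(keep_counts), n_total))
  }
  series <- split(data, data$station_id, drop = TRUE)
  grid_ok <- vapply(series, function(s) identical(sort(s$day), days), logical(1))
  if (!all(grid_ok)) {
    stop(sprintf("stations do not share the occasion grid: %s",
                 paste(names(series)[!grid_ok], collapse = ", ")))
  }
  series <- lapply(series, function(s) s[order(s$day), ])
  n_st <- length(series)

  one <- function(n_keep) {
    # the reference is always the untouched full grid; phase shifts only
    # the thinned schedules
    idx <- subsample_schedule(n_total, n_keep,
                              if (n_keep < n_total) phase else 0)
    means <- vapply(series, function(s)
      time_integrated_mean(s$value[idx], s$day[idx]), numeric(1))
    m <- mean(means)
    half <- if (n_st > 1) stats::qt(0.975, n_st - 1) * stats::sd(means) / sqrt(n_st) else 0
    c(mean = m, lo = m - half, hi = m + half)
  }

  keep_counts <- sort(keep_counts, decreasing = TRUE)
  raw <- t(vapply(keep_counts, one, numeric(3)))
  ref <- raw[1, "mean"]
  if (ref == 0) stop("full-frequency area mean is 0; standardization undefined")
  std <- 100 * raw / ref
  res <- data.frame(
    variable = variable,
    n_keep = keep_counts,
    mean = raw[, "mean"],
    standardized_mean = std[, "mean"],
    ci95_low = std[, "lo"],
    ci95_high = std[, "hi"],
    within_tolerance = abs(std[, "mean"] - 100) <= tolerance,
    row.names = NULL
  )
  class(res) <- c("frequency_result", "data.frame")
  attr(res, "tolerance") <- tolerance
  res
}

#' Lowest acceptable sampling frequency
#'
#' Walks the frequency-reduction results from the full frequency downward
#' and returns the smallest occasion count still within tolerance, stopping
#' at the first failure (monotone acceptance: a low frequency is only
#' trusted if every intermediate frequency also passed). The chosen count is
#' the natural value for the surveys-per-year factor of the cost model.
#'
#' @param results A `frequency_result` data frame from
#'   [frequency_analysis()].
#' @return Integer occasion count. If no reduced frequency is acceptable the
#'   reference count is returned with a warning.
#' @export
min_frequency <- function(results) {
  stopifnot(inherits(results, "data.frame"),
            all(c("n_keep", "within_tolerance") %in% names(results)))
  res <- results[order(results$n_keep, decreasing = TRUE), ]
  ok <- res$within_tolerance
  if (!ok[1]) stop("reference frequency itself is flagged outside tolerance")
  run <- cumprod(ok) == 1   # TRUE until the first failure
  best <- min(res$n_keep[run])
  if (best == max(res$n_keep) && length(res$n_keep) > 1) {
    warning("no reduced frequency within tolerance; returning the reference count")
  }
  as.integer(best)
}

#' @export
print.frequency_result <- function(x, ...) {
  tol <- attr(x, "tolerance")
  cat(sprintf("Frequency reduction%s (tolerance +/-%g%% of reference):\n",
              if (all(is.na(x$variable))) "" else paste0(" [", x$variable[1], "]"),
              if (is.null(tol)) NA else tol))
  df <- data.frame(n_keep = x$n_keep,
                   `mean%` = sprintf("%.2f", x$standardized_mean),
                   ci95 = sprintf("[%.2f, %.2f]", x$ci95_low, x$ci95_high),
                   ok = ifelse(x$within_tolerance, "yes", "no"),
                   check.names = FALSE)
  print(df, row.names = FALSE)
  invisible(x)
}
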
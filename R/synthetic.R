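#' Specification of one synthetic variable's seasonal behaviour
#'
#' Describes how a variable evolves over the season and how it varies
#' between stations and occasions. A station's value at day `t` and depth
#' `z` is built multiplicatively,
#' `trend(t) * (1 + gradient * z) * (1 + e_s) * (1 + eps_st)`,
#' with a station effect `e_s ~ N(0, station_effect_cv/100)` and AR(1)
#' occasion noise `eps_st` of marginal SD `noise_cv/100`. Multiplicative
#' noise keeps the configured CVs scale-free and values positive for
#' realistic parameter levels, matching the CV-centric design calculus.
#'
#' Light is special-cased: `shape = "light"` generates irradiance profiles
#' `I0(t) * exp(-k_st * z)` where the station- and occasion-varying
#' attenuation coefficient `k_st = k * (1 + e_s) * (1 + eps_st)` carries the
#' spread, so the downstream extinction fit can recover it.
#'
#' @param variable Variable name.
#' @param shape One of `"constant"`, `"linear"`, `"piecewise_peak"`,
#'   `"decay"`, `"baseline_pulse"`, `"irregular"`, `"light"`.
#' @param params Named list of shape parameters:
#'   \describe{
#'     \item{constant}{`level`.}
#'     \item{linear}{`start`, `end` (values at the first/last occasion).}
#'     \item{piecewise_peak}{`start`, `peak`, `end`, `peak_day` (rise to
#'       `peak` at `peak_day`, then fall to `end`).}
#'     \item{decay}{`start`, `end` (exponential interpolation).}
#'     \item{baseline_pulse}{`base`, `pulse_height`, `pulse_from`,
#'       `pulse_to` (additive pulse inside the day window).}
#'     \item{irregular}{`level`, `amplitude`, plus fixed-frequency bumps;
#'       deterministic, reproducible wiggles around `level`.}
#'     \item{light}{`I0` (surface irradiance at mid-season), `k` (mean
#'       attenuation, per meter).}
#'   }
#' @param gradient Relative change per meter depth of the trend value
#'   (ignored for `"light"`). Default 0.
#' @param station_effect_cv Between-station spread of the station-level
#'   mean, percent.
#' @param noise_cv Within-station occasion noise, percent.
#' @param ar1_rho Lag-1 autocorrelation of the occasion noise, in `[0, 1)`.
#'   Default 0.3.
#' @return Object of class `trend_spec`.
#' @seealso [default_world()], [generate_dataset()]
#' @export
trend_spec <- function(variable, shape, params, gradient = 0,
                       station_effect_cv = 5, noise_cv = 20, ar1_rho = 0.3) {
  shapes <- c("constant", "linear", "piecewise_peak", "decay",
              "baseline_pulse", "irregular", "light")
  if (!shape %in% shapes) {
    stop(sprintf("unknown shape '%s'; use one of: %s", shape,
                 paste(shapes, collapse = ", ")))
  }
  stopifnot(station_effect_cv >= 0, noise_cv >= 0,
            ar1_rho >= 0, ar1_rho < 1, is.list(params))
  need <- switch(shape,
    constant = "level", linear = c("start", "end"),
    piecewise_peak = c("start", "peak", "end", "peak_day"),
    decay = c("start", "end"),
    baseline_pulse = c("base", "pulse_height", "pulse_from", "pulse_to"),
    irregular = c("level", "amplitude"),
    light = c("I0", "k"))
  missing <- setdiff(need, names(params))
  if (length(missing)) {
    stop(sprintf("shape '%s' requires params: %s", shape,
                 paste(missing, collapse = ", ")))
  }
  structure(list(variable = variable, shape = shape, params = params,
                 gradient = gradient, station_effect_cv = station_effect_cv,
                 noise_cv = noise_cv, ar1_rho = ar1_rho),
            class = "trend_spec")
}

# deterministic seasonal trend value(s) at day t for a spec
trend_value <- function(spec, t, t_range) {
  p <- spec$params
  frac <- if (diff(t_range) > 0) (t - t_range[1]) / diff(t_range) else 0
  switch(spec$shape,
    constant = rep(p$level, length(t)),
    linear = p$start + frac * (p$end - p$start),
    decay = p$start * (p$end / p$start)^frac,
    piecewise_peak = {
      up <- t <= p$peak_day
      out <- numeric(length(t))
      fu <- (t - t_range[1]) / max(p$peak_day - t_range[1], 1)
      fd <- (t - p$peak_day) / max(t_range[2] - p$peak_day, 1)
      out[up] <- p$start + fu[up] * (p$peak - p$start)
      out[!up] <- p$peak + fd[!up] * (p$end - p$peak)
      out
    },
    baseline_pulse = {
      out <- rep(p$base, length(t))
      inwin <- t >= p$pulse_from & t <= p$pulse_to
      if (any(inwin)) {
        # smooth half-sine pulse inside the window
        u <- (t[inwin] - p$pulse_from) / max(p$pulse_to - p$pulse_from, 1)
        out[inwin] <- p$base + p$pulse_height * sin(pi * u)
      }
      out
    },
    irregular = p$level * (1 + p$amplitude *
      (0.6 * sin(2 * pi * t / 47) + 0.4 * sin(2 * pi * t / 23 + 1.1))),
    light = rep(p$I0, length(t))  # surface irradiance; depth handled later
  )
}

#' Default synthetic world: six variables of a coastal monitoring survey
#'
#' A ready-made set of [trend_spec()]s emulating a half-year (early June to
#' early December) of weekly sensor profiles in a temperate coastal area:
#' salinity slowly increasing; temperature rising to a peak near day 220
#' then falling; oxygen saturation slowly declining; CDOM with a late-summer
#' pulse between days 218 and 247; chlorophyll a fluctuating irregularly;
#' and PAR with a mean attenuation coefficient of 0.77 per meter. The
#' between-station spreads are set to the CV% levels a heterogeneous
#' estuarine pilot survey would report for time-integrated station means
#' (0.5--12.4%), with much larger within-station occasion noise, so the
#' generated world reproduces the situation the design calculus targets:
#' noisy snapshots, stable seasonal integrals.
#'
#' @return Named list of six `trend_spec` objects.
#' @examples
#' world <- default_world()
#' names(world)
#' @export
default_world <- function() {
  specs <- list(
    trend_spec("salinity", "linear", list(start = 3.4, end = 4.4),
               gradient = 0.02, station_effect_cv = 6.21, noise_cv = 16),
    trend_spec("temperature", "piecewise_peak",
               list(start = 8, peak = 18, end = 2, peak_day = 220),
               gradient = -0.02, station_effect_cv = 0.97, noise_cv = 8),
    trend_spec("oxygen", "decay", list(start = 95, end = 86),
               gradient = -0.005, station_effect_cv = 0.55, noise_cv = 4),
    trend_spec("cdom", "baseline_pulse",
               list(base = 4.2, pulse_height = 6, pulse_from = 218,
                    pulse_to = 247),
               gradient = 0.01, station_effect_cv = 10.83, noise_cv = 30),
    trend_spec("chlorophyll", "irregular",
               list(level = 2.6, amplitude = 0.5),
               gradient = -0.03, station_effect_cv = 4.76, noise_cv = 29),
    trend_spec("par", "light", list(I0 = 600, k = 0.77),
               station_effect_cv = 12.36, noise_cv = 25)
  )
  stats::setNames(specs, vapply(specs, `[[`, "", "variable"))
}

#' Between-station CVs of the default synthetic world
#'
#' The configured `station_effect_cv` of each [default_world()] variable
#' (percent): the between-station coefficients of variation of
#' time-integrated means around which the package's worked examples are
#' built. They span the range (about 0.5--12.4%) a heterogeneous coastal
#' area shows once stations are reduced to seasonal integrals.
#'
#' @return Named numeric vector of CV% values.
#' @examples
#' design_table(default_cv_set())
#' @export
default_cv_set <- function() {
  world <- default_world()
  out <- vapply(world, `[[`, numeric(1), "station_effect_cv")
  names(out)[names(out) == "par"] <- "extinction"
  out
}

# AR(1) sequence with marginal SD `sd` (stationary start)
ar1_noise <- function(n, rho, sd) {
  if (sd == 0 || n == 0) return(numeric(n))
  innov_sd <- sd * sqrt(1 - rho^2)
  x <- numeric(n)
  x[1] <- stats::rnorm(1, 0, sd)
  for (i in seq_len(n)[-1]) x[i] <- rho * x[i - 1] + stats::rnorm(1, 0, innov_sd)
  x
}

#' Generate a synthetic multi-station sensor dataset with known truth
#'
#' Builds a long-format observation set (station x occasion x depth x
#' variable) from a list of [trend_spec()]s, together with the exact ground
#' truth needed to test every pipeline stage: the noise-free time-integrated
#' mean of each station's curve and the realized station effects.
#'
#' @param specs List of [trend_spec()]s, e.g. [default_world()].
#' @param n_stations Number of stations (>= 2). Default 21.
#' @param occasions Increasing vector of sampling days. Default: 24 roughly
#'   weekly occasions from day 155 to day 338.
#' @param depths Sampling depths in meters. Default `seq(0, 3, by = 0.5)`.
#' @param seed Integer seed; the full dataset is reproducible bit-for-bit
#'   from it.
#' @return List with elements:
#'   \describe{
#'     \item{observations}{Data frame `station_id`, `day`, `depth_m`,
#'       `variable`, `value` (class `observation_set`).}
#'     \item{truth}{Per-variable list: `trend_mean` (time-weighted mean of
#'       the noise-free trend over the occasions), `station_effects`
#'       (realized `e_s`), `station_true_means` (trend mean scaled by each
#'       station's effect; for light these are the per-station attenuation
#'       coefficients), `station_effect_cv`, `noise_cv` as configured, and
#'       the `seed`.}
#'   }
#' @examples
#' sim <- generate_dataset(default_world(), n_stations = 5,
#'                         occasions = seq(160, 260, by = 20), seed = 1)
#' head(sim$observations)
#' @export
generate_dataset <- function(specs, n_stations = 21,
                             occasions = round(seq(155, 338, length.out = 24)),
                             depths = seq(0, 3, by = 0.5), seed = 1) {
  if (inherits(specs, "trend_spec")) specs <- list(specs)
  ok <- vapply(specs, inherits, logical(1), "trend_spec")
  if (!all(ok)) stop("`specs` must be a list of trend_spec objects")
  stopifnot(n_stations >= 2, length(depths) >= 1)
  if (any(diff(occasions) <= 0)) stop("`occasions` must be strictly increasing")
  t_range <- range(occasions)
  stations <- sprintf("st%02d", seq_len(n_stations))

  set.seed(seed)
  rows <- vector("list", length(specs))
  truth <- vector("list", length(specs))
  for (j in seq_along(specs)) {
    spec <- specs[[j]]
    trend <- trend_value(spec, occasions, t_range)
    e_s <- stats::rnorm(n_stations, 0, spec$station_effect_cv / 100)
    depth_factor <- 1 + spec$gradient * depths
    w <- interval_weights(occasions)

    per_station <- vector("list", n_stations)
    for (s in seq_len(n_stations)) {
      eps <- ar1_noise(length(occasions), spec$ar1_rho, spec$noise_cv / 100)
      # integral-preserving noise: remove the component that would shift the
      # time-weighted mean, so each station's seasonal integral is exactly
      # trend_mean * (1 + e_s) and the recorded ground truth is exact
      ref <- if (spec$shape == "light") rep(1, length(trend)) else trend
      if (sum(w * ref) != 0) eps <- eps - sum(w * ref * eps) / sum(w * ref)
      occ_level <- trend * (1 + e_s[s]) * (1 + eps)
      if (spec$shape == "light") {
        k_st <- spec$params$k * (1 + e_s[s]) * (1 + eps)
        vals <- as.vector(outer(depths, seq_along(occasions),
                                function(z, i) trend[i] * exp(-k_st[i] * z)))
      } else {
        vals <- as.vector(outer(depth_factor, occ_level))
      }
      per_station[[s]] <- data.frame(
        station_id = stations[s],
        day = rep(occasions, each = length(depths)),
        depth_m = rep(depths, times = length(occasions)),
        variable = spec$variable,
        value = vals,
        stringsAsFactors = FALSE)
    }
    rows[[j]] <- do.call(rbind, per_station)

    if (spec$shape == "light") {
      k_trend <- rep(spec$params$k, length(occasions))
      trend_mean <- time_integrated_mean(k_trend, occasions)
    } else {
      trend_mean <- time_integrated_mean(trend, occasions)
    }
    truth[[j]] <- list(
      variable = spec$variable,
      trend_mean = trend_mean,
      station_effects = stats::setNames(e_s, stations),
      station_true_means = stats::setNames(trend_mean * (1 + e_s), stations),
      station_effect_cv = spec$station_effect_cv,
      noise_cv = spec$noise_cv)
  }
  obs <- do.call(rbind, rows)
  rownames(obs) <- NULL
  class(obs) <- c("observation_set", "data.frame")
  attr(obs, "seed") <- seed
  names(truth) <- vapply(specs, `[[`, "", "variable")
  list(observations = obs,
       truth = c(truth, list(seed = seed)))
}
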
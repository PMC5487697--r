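#' Mean of a variable over a depth band
#'
#' Reduces one vertical cast to a scalar by averaging all samples of a
#' variable whose depth falls inside a closed depth interval. Monitoring
#' designs built on surface-layer conditions conventionally average the top
#' few meters of each profile; the default band is 0--3 m.
#'
#' @param cast Data frame with at least columns `depth_m`, `variable`,
#'   `value`; columns `station_id` and `day`, if present, are used in error
#'   messages only.
#' @param variable Name of the variable to average.
#' @param depth_min,depth_max Band limits in meters (closed interval;
#'   boundary samples are included). Defaults 0 and 3.
#' @return Arithmetic mean of the selected values (length-1 numeric).
#' @examples
#' cast <- data.frame(depth_m = c(0, 1, 2, 5),
#'                    variable = "temperature",
#'                    value = c(10, 10, 10, 2))
#' band_mean(cast, "temperature")  # deep sample excluded -> 10
#' @export
band_mean <- function(cast, variable, depth_min = 0, depth_max = 3) {
  stopifnot(is.data.frame(cast),
            all(c("depth_m", "variable", "value") %in% names(cast)))
  if (!(depth_min < depth_max)) {
    stop("`depth_min` must be strictly less than `depth_max`")
  }
  sel <- cast$variable == variable &
    cast$depth_m >= depth_min & cast$depth_m <= depth_max
  if (!any(sel)) {
    where <- character(0)
    if (!is.null(cast$station_id)) where <- c(where, paste0("station ", cast$station_id[1]))
    if (!is.null(cast$day)) where <- c(where, paste0("day ", cast$day[1]))
    stop(sprintf("empty band: no '%s' samples in [%g, %g] m%s",
                 variable, depth_min, depth_max,
                 if (length(where)) paste0(" (", paste(where, collapse = ", "), ")") else ""))
  }
  mean(cast$value[sel])
}

#' Fit a light extinction coefficient to an irradiance profile
#'
#' Downwelling irradiance decays approximately exponentially with depth,
#' `I(d) = I0 * exp(-k * d)`. The attenuation coefficient `k` (per meter) is
#' estimated by ordinary least squares of `log(irradiance)` on depth;
#' `k` is minus the slope and `I0` the exponentiated intercept.
#'
#' @param depths Numeric vector of depths in meters, non-negative, unique.
#' @param irradiance Numeric vector of irradiance values (e.g. PAR), same
#'   length as `depths`. Points at or below `floor` are excluded before
#'   fitting (the log is undefined for them); at least 3 usable points are
#'   required.
#' @param floor Detection floor; only irradiance strictly above it enters
#'   the fit. Default 0.
#' @return An object of class `extinction_fit`: a list with elements `k`
#'   (per meter), `I0` (surface irradiance estimate), `r_squared`
#'   (coefficient of determination of the log-linear fit), and `n` (points
#'   used).
#' @examples
#' d <- 0:4
#' fit <- fit_extinction(d, 80 * exp(-0.77 * d))
#' fit$k          # 0.77
#' euphotic_depth(fit$k)
#' @seealso [euphotic_depth()]
#' @export
fit_extinction <- function(depths, irradiance, floor = 0) {
  stopifnot(is.numeric(depths), is.numeric(irradiance),
            length(depths) == length(irradiance))
  if (any(depths < 0)) stop("depths must be non-negative")
  if (anyDuplicated(depths)) stop("depths must be unique")
  keep <- irradiance > floor & !is.na(irradiance)
  if (floor <= 0 && any(irradiance[!is.na(irradiance)] <= 0)) {
    stop("irradiance must be strictly positive for log-linear fitting; ",
         "set `floor` to drop below-detection points explicitly")
  }
  if (sum(keep) < 3) stop("fewer than 3 usable points above the detection floor")
  d <- depths[keep]
  y <- log(irradiance[keep])
  fit <- stats::lm(y ~ d)
  b <- stats::coef(fit)
  ss_res <- sum(fit$residuals^2)
  ss_tot <- sum((y - mean(y))^2)
  r2 <- if (ss_tot == 0) 1 else 1 - ss_res / ss_tot
  structure(
    list(k = unname(-b[2]), I0 = unname(exp(b[1])), r_squared = r2,
         n = sum(keep)),
    class = "extinction_fit"
  )
}

#' @export
print.extinction_fit <- function(x, ...) {
  cat(sprintf("Extinction fit: k = %.4f m^-1, I0 = %.3g, R^2 = %.4f (n = %d)\n",
              x$k, x$I0, x$r_squared, x$n))
  invisible(x)
}

#' Depth at which irradiance falls to a given fraction of the surface value
#'
#' With exponential attenuation the depth where irradiance reaches a
#' fraction `f` of its surface value is `-log(f) / k`. The 1% light depth
#' (the default) approximates the bottom of the euphotic zone.
#'
#' @param k Attenuation coefficient, per meter; must be positive.
#' @param fraction Fraction of surface irradiance, strictly between 0 and 1.
#' @return Depth in meters.
#' @examples
#' euphotic_depth(0.77)   # ~6 m
#' @export
euphotic_depth <- function(k, fraction = 0.01) {
  if (any(k <= 0)) stop("no positive attenuation: k must be > 0")
  if (any(fraction <= 0 | fraction >= 1)) stop("`fraction` must be in (0, 1)")
  -log(fraction) / k
}

#' Reduce an observation set to per-station, per-occasion scalar values
#'
#' Applies [band_mean()] to every non-light variable and [fit_extinction()]
#' to the light variable for each station and sampling day, yielding the
#' long station x occasion table on which time integration operates.
#'
#' @param observations Long-format data frame with columns `station_id`,
#'   `day`, `depth_m`, `variable`, `value` (see [read_observations()]).
#' @param band Numeric length-2: depth band for band means. Default `c(0, 3)`.
#' @param light_var Name of the irradiance variable whose profile is fitted
#'   for an extinction coefficient; `NULL` to skip. Default `"par"`.
#' @param extinction_name Variable name given to the fitted coefficient in
#'   the output. Default `"extinction"`.
#' @param min_r_squared Profiles whose log-linear fit falls below this are
#'   dropped with a warning; default 0 keeps all fits.
#' @param floor Detection floor passed to [fit_extinction()].
#' @return Data frame with columns `station_id`, `day`, `variable`, `value`,
#'   one row per station x day x variable.
#' @export
cast_summaries <- function(observations, band = c(0, 3), light_var = "par",
                           extinction_name = "extinction",
                           min_r_squared = 0, floor = 0) {
  stopifnot(is.data.frame(observations),
            all(c("station_id", "day", "depth_m", "variable", "value") %in%
                  names(observations)))
  vars <- unique(observations$variable)
  band_vars <- setdiff(vars, light_var)
  out <- list()

  key <- interaction(observations$station_id, observations$day, drop = TRUE)
  for (grp in split(observations, key)) {
    sid <- grp$station_id[1]; dy <- grp$day[1]
    for (v in band_vars) {
      if (!any(grp$variable == v)) next
      out[[length(out) + 1L]] <- data.frame(
        station_id = sid, day = dy, variable = v,
        value = band_mean(grp, v, band[1], band[2]),
        stringsAsFactors = FALSE)
    }
    if (!is.null(light_var) && any(grp$variable == light_var)) {
      lg <- grp[grp$variable == light_var, ]
      fit <- try(fit_extinction(lg$depth_m, lg$value, floor = floor),
                 silent = TRUE)
      if (inherits(fit, "try-error")) {
        warning(sprintf("extinction fit failed for station %s day %s: %s",
                        sid, dy, attr(fit, "condition")$message))
      } else if (fit$r_squared < min_r_squared) {
        warning(sprintf(
          "extinction fit dropped for station %s day %s: R^2 = %.3f < %.3f",
          sid, dy, fit$r_squared, min_r_squared))
      } else {
        out[[length(out) + 1L]] <- data.frame(
          station_id = sid, day = dy, variable = extinction_name,
          value = fit$k, stringsAsFactors = FALSE)
      }
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res[order(res$variable, res$station_id, res$day), , drop = FALSE]
}
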
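#' Read a long-format observation file
#'
#' The interchange format is a delimited text file with a header row naming
#' the five columns `station_id`, `day`, `depth_m`, `variable`, `value`:
#' one row per measurement. Validation is strict — missing columns,
#' unparseable numbers and duplicate (station, day, depth, variable) keys
#' are hard errors reported with file line numbers; suspicious but legal
#' values (negative depths, days outside 1--366) raise warnings.
#'
#' @param path Path to the delimited text file.
#' @param delim Field delimiter. Default `","`.
#' @return An `observation_set` data frame.
#' @seealso [write_observations()], [generate_dataset()]
#' @export
read_observations <- function(path, delim = ",") {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  df <- utils::read.csv(path, sep = delim, stringsAsFactors = FALSE,
                        colClasses = "character")
  required <- c("station_id", "day", "depth_m", "variable", "value")
  missing <- setdiff(required, names(df))
  if (length(missing)) {
    stop(sprintf("missing columns in %s: %s", path,
                 paste(missing, collapse = ", ")))
  }
  df <- df[required]
  # header is line 1, so data row i sits on file line i + 1
  for (col in c("day", "depth_m", "value")) {
    num <- suppressWarnings(as.numeric(df[[col]]))
    bad <- which(is.na(num) & !is.na(df[[col]]) & nzchar(df[[col]]))
    if (length(bad)) {
      stop(sprintf("unparseable numeric in column '%s' at line(s): %s",
                   col, paste(utils::head(bad + 1L, 10), collapse = ", ")))
    }
    df[[col]] <- num
  }
  key <- paste(df$station_id, df$day, df$depth_m, df$variable, sep = "\r")
  dup <- which(duplicated(key))
  if (length(dup)) {
    stop(sprintf("duplicate (station, day, depth, variable) key at line(s): %s",
                 paste(utils::head(dup + 1L, 10), collapse = ", ")))
  }
  if (any(df$depth_m < 0, na.rm = TRUE)) {
    warning("negative depths present; check units/sign convention")
  }
  if (any(df$day < 1 | df$day > 366, na.rm = TRUE)) {
    warning("days outside [1, 366]; expected day-of-year")
  }
  class(df) <- c("observation_set", "data.frame")
  attr(df, "source") <- path
  df
}

#' Write an observation set to delimited text
#'
#' @param observations Data frame with columns `station_id`, `day`,
#'   `depth_m`, `variable`, `value`.
#' @param path Output path.
#' @param delim Field delimiter. Default `","`.
#' @return `path`, invisibly.
#' @export
write_observations <- function(observations, path, delim = ",") {
  required <- c("station_id", "day", "depth_m", "variable", "value")
  stopifnot(all(required %in% names(observations)))
  df <- as.data.frame(observations)[required]
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Pipeline configuration
#'
#' Bundles every tunable of the full pipeline with validated defaults: the
#' cost-model constants, the surface depth band, the frequency-reduction
#' schedule and tolerance, the significance/power conventions and the
#' percent changes of interest.
#'
#' @param A,B,n,m,N_time Cost-model constants, see [cost_model()]. Defaults
#'   `A = 1`, `B = 20`, `n = 3`, `m = 0.1`, `N_time = 12` give costs in
#'   relative units.
#' @param band Depth band (meters) for [cast_summaries()]. Default `c(0, 3)`.
#' @param light_var,extinction_name Irradiance variable and the name of the
#'   fitted attenuation coefficient; see [cast_summaries()].
#' @param keep_counts Occasion counts for [frequency_analysis()]; `NULL`
#'   (default) derives a ladder from the available occasions.
#' @param tolerance Frequency-acceptance half-width, percent. Default 5.
#' @param alpha Two-sided significance level. Default 0.05.
#' @param beta Type-II error rate; target power is `1 - beta`. Default 0.2.
#' @param deltas Percent changes to detect. Default `c(5, 10)`.
#' @param target_ci Precision target (CI%, percent) for station counts and
#'   portfolio budgets. Default 20.
#' @param t_mode,t_value Confidence multiplier convention, see
#'   [ci_percent()].
#' @param min_points Minimum occasions per station for integration.
#' @return Object of class `run_config` (a validated list).
#' @export
run_config <- function(A = 1, B = 20, n = 3, m = 0.1, N_time = 12,
                       band = c(0, 3), light_var = "par",
                       extinction_name = "extinction",
                       keep_counts = NULL, tolerance = 5,
                       alpha = 0.05, beta = 0.2, deltas = c(5, 10),
                       target_ci = 20, t_mode = "fixed", t_value = 2.01,
                       min_points = 4) {
  stopifnot(length(band) == 2, band[1] < band[2], tolerance > 0,
            alpha > 0, alpha < 1, beta > 0, beta < 1, all(deltas > 0),
            target_ci > 0)
  t_mode <- match.arg(t_mode, c("fixed", "exact"))
  cfg <- list(cost = cost_model(A, B, n, m, N_time), band = band,
              light_var = light_var, extinction_name = extinction_name,
              keep_counts = keep_counts, tolerance = tolerance,
              alpha = alpha, beta = beta, deltas = deltas,
              target_ci = target_ci, t_mode = t_mode, t_value = t_value,
              min_points = min_points)
  class(cfg) <- "run_config"
  cfg
}

# descending ladder of occasion counts: full, then halving-ish steps
default_keep_counts <- function(n_total) {
  ladder <- unique(pmax(2, round(n_total / c(1, 2, 3, 4, 4.8, 6))))
  ladder[ladder <= n_total]
}

#' Run the full design pipeline on an observation set
#'
#' Executes the four analysis stages in order: (1) cast reduction to
#' station x occasion values ([cast_summaries()]); (2) time integration and
#' variability ([area_summary()], [variability_table()],
#' [normality_check()]); (3) frequency reduction ([frequency_analysis()],
#' [min_frequency()]); (4) the cost-precision-power calculus
#' ([design_table()], [budget_for_portfolio()]). Stage errors abort with a
#' stage-tagged message.
#'
#' @param config A [run_config()].
#' @param observations An `observation_set` (from [read_observations()] or
#'   [generate_dataset()]).
#' @return Object of class `pipeline_report`: list with
#'   \describe{
#'     \item{summary}{Per-variable table: area mean, range of station
#'       means, CV%, CI% prefactor, Shapiro-Wilk W and p.}
#'     \item{variability}{Per-variable mean/range CV% for both axes and
#'       both transforms (long data frame).}
#'     \item{frequency}{Stacked [frequency_analysis()] tables plus the
#'       per-variable minimum acceptable frequency.}
#'     \item{allocation}{[design_table()] on the estimated CVs.}
#'     \item{budget}{[budget_for_portfolio()] at `config$target_ci`.}
#'     \item{station_values, area}{Intermediate products for inspection.}
#'   }
#' @export
run_pipeline <- function(config, observations) {
  stopifnot(inherits(config, "run_config"))
  if (nrow(observations) == 0) stop("pipeline: empty observation set")

  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("[%s] %s", name, conditionMessage(e)), call. = FALSE)
    })
  }

  station_values <- stage("profiles", cast_summaries(
    observations, band = config$band, light_var = config$light_var,
    extinction_name = config$extinction_name))
  vars <- unique(station_values$variable)

  area <- stage("integration", lapply(stats::setNames(vars, vars), function(v) {
    area_summary(station_values[station_values$variable == v, ],
                 variable = v, min_points = config$min_points)
  }))

  tmult <- t_multiplier(2, config$t_mode, config$t_value, config$alpha)
  summary_tab <- stage("integration", do.call(rbind, lapply(vars, function(v) {
    a <- area[[v]]
    sw <- tryCatch(normality_check(a$station_means),
                   error = function(e) list(W = NA_real_, p = NA_real_))
    data.frame(variable = v, area_mean = a$area_mean,
               min_station_mean = min(a$station_means),
               max_station_mean = max(a$station_means),
               cv_percent = a$cv_percent,
               ci_prefactor = tmult * a$cv_percent,
               shapiro_w = sw$W, shapiro_p = sw$p, row.names = NULL)
  })))

  variability <- stage("integration", do.call(rbind, lapply(vars, function(v) {
    d <- station_values[station_values$variable == v, ]
    do.call(rbind, lapply(c("over_time", "over_stations"), function(ax) {
      do.call(rbind, lapply(c("raw", "log"), function(tr) {
        vt <- variability_table(d, ax, tr, variable = v)
        data.frame(variable = v, axis = ax, transform = tr,
                   grand_mean = vt$grand_mean, mean_cv = vt$mean_cv,
                   cv_min = vt$cv_range[1], cv_max = vt$cv_range[2],
                   row.names = NULL)
      }))
    }))
  })))

  n_occ <- length(unique(station_values$day))
  keep_counts <- config$keep_counts %||% default_keep_counts(n_occ)
  freq <- stage("frequency", lapply(stats::setNames(vars, vars), function(v) {
    frequency_analysis(station_values[station_values$variable == v, ],
                       keep_counts = keep_counts,
                       tolerance = config$tolerance, variable = v)
  }))
  freq_tab <- do.call(rbind, freq)
  rownames(freq_tab) <- NULL
  min_freq <- vapply(freq, function(f) suppressWarnings(min_frequency(f)),
                     integer(1))

  cvs <- stats::setNames(summary_tab$cv_percent, summary_tab$variable)
  allocation <- stage("design", design_table(
    cvs, target_ci = config$target_ci, deltas = config$deltas,
    power = 1 - config$beta, alpha = config$alpha,
    t_mode = config$t_mode, t_value = config$t_value))
  budget <- stage("design", budget_for_portfolio(
    config$cost, cvs, config$target_ci, config$t_mode, config$t_value))

  structure(list(summary = summary_tab, variability = variability,
                 frequency = freq_tab, min_frequency = min_freq,
                 allocation = allocation, budget = budget,
                 station_values = station_values, area = area,
                 config = config),
            class = "pipeline_report")
}

#' @export
print.pipeline_report <- function(x, ...) {
  cat("== Time-integrated area summary ==\n")
  s <- x$summary
  s[-1] <- lapply(s[-1], function(v) round(v, 3))
  print(s, row.names = FALSE)
  cat("\n== Minimum acceptable sampling frequency (occasions) ==\n")
  print(x$min_frequency)
  cat("\n== Allocation ==\n")
  a <- x$allocation
  a$cv_percent <- round(a$cv_percent, 2)
  a$ci_prefactor <- round(a$ci_prefactor, 2)
  print(a, row.names = FALSE)
  cat("\n")
  print(x$budget)
  invisible(x)
}

#' Design-only report from a table of CV values
#'
#' The cost-precision-power calculus does not need raw observations; a
#' table of per-variable CV% from a pilot study (or from the literature) is
#' enough. This entry point skips the data stages and produces the
#' allocation table and portfolio budget directly.
#'
#' @param cvs Named numeric vector of per-variable CV%.
#' @param config A [run_config()]; only its design-stage settings are used.
#' @return List with `allocation` ([design_table()]) and `budget`
#'   ([budget_for_portfolio()]).
#' @examples
#' design_report(default_cv_set())
#' @export
design_report <- function(cvs, config = run_config()) {
  stopifnot(inherits(config, "run_config"), length(cvs) >= 1)
  list(
    allocation = design_table(cvs, target_ci = config$target_ci,
                              deltas = config$deltas,
                              power = 1 - config$beta, alpha = config$alpha,
                              t_mode = config$t_mode, t_value = config$t_value),
    budget = budget_for_portfolio(config$cost, cvs, config$target_ci,
                                  config$t_mode, config$t_value)
  )
}

#' Write a pipeline report as delimited-text tables
#'
#' Serializes each table of a [run_pipeline()] report to CSV under `dir`
#' (full precision; display rounding is left to the reader) plus a
#' `report.txt` key-value summary.
#'
#' @param report A `pipeline_report`.
#' @param dir Output directory, created if needed.
#' @return `dir`, invisibly.
#' @export
write_report <- function(report, dir) {
  stopifnot(inherits(report, "pipeline_report"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(report$summary, file.path(dir, "summary.csv"),
                   row.names = FALSE)
  utils::write.csv(report$variability, file.path(dir, "variability.csv"),
                   row.names = FALSE)
  utils::write.csv(report$frequency, file.path(dir, "frequency.csv"),
                   row.names = FALSE)
  utils::write.csv(report$allocation, file.path(dir, "allocation.csv"),
                   row.names = FALSE)
  con <- file(file.path(dir, "report.txt"), "w")
  on.exit(close(con))
  b <- report$budget
  writeLines(c(
    sprintf("target_ci_percent: %g", b$target_ci),
    sprintf("budget: %g", b$budget),
    sprintf("budget_exact: %.6f", b$budget_exact),
    sprintf("stations_per_survey: %.6f", b$N_space),
    sprintf("binding_variable: %s", b$worst_variable),
    sprintf("min_frequency: %s",
            paste(sprintf("%s=%d", names(report$min_frequency),
                          report$min_frequency), collapse = " "))
  ), con)
  invisible(dir)
}
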
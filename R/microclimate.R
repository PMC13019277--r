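## Soil-microclimate logger processing: daylight growing-season means,
## snow-day classification, snowmelt dates and treatment deltas.

.logger_vars <- c("t_air_15cm", "t_surface_2cm", "t_soil_8cm", "swc")

#' Daylight growing-season means of a logger series
#'
#' Arithmetic mean per channel over the growing-season months (default
#' June-August) restricted to daylight hours, the half-open local-time
#' window `[9, 17)` by default (half-open so 17:00 samples are not
#' double-counted against a following window).
#'
#' @param series Logger data.frame with `timestamp` (POSIXct) and the
#'   channels `t_air_15cm`, `t_surface_2cm`, `t_soil_8cm`, `swc` (any
#'   subset).
#' @param months Integer months of the window (default `6:8`, JJA).
#' @param hours Numeric `c(from, to)` local-hour window, half-open
#'   (default `c(9, 17)`).
#' @return List with `means` (named numeric per channel; `NA` with a
#'   warning when the window is empty) and `n` (samples used).
#' @export
daylight_season_mean <- function(series, months = 6:8, hours = c(9, 17)) {
  ts <- series$timestamp
  mon <- as.integer(strftime(ts, "%m", tz = "UTC"))
  hr <- as.integer(strftime(ts, "%H", tz = "UTC")) +
    as.integer(strftime(ts, "%M", tz = "UTC")) / 60
  keep <- mon %in% months & hr >= hours[1] & hr < hours[2]
  vars <- intersect(.logger_vars, names(series))
  if (!any(keep)) {
    warning("no samples in the requested window", call. = FALSE)
    means <- stats::setNames(rep(NA_real_, length(vars)), vars)
    return(list(means = means, n = 0L))
  }
  means <- vapply(vars, function(v) mean(series[[v]][keep], na.rm = TRUE),
                  numeric(1))
  list(means = means, n = sum(keep))
}

#' Classify days as snow-covered from the surface-temperature signature
#'
#' A snowpack thermally decouples the 2 cm surface sensor from the
#' atmosphere: the diurnal amplitude collapses and the temperature sits
#' near 0 C. A calendar day is classified snow-covered when the daily
#' range of `t_surface_2cm` is below `range_max` **and** the daily mean
#' lies within `mean_tol` of 0 C. Both thresholds are tunable; the
#' defaults (1.5 C each) are validated against the package's synthetic
#' logger generator only. Partial days at the series edges are excluded.
#'
#' Note the deliberate boundary: a clear-sky deep-freeze day with a tiny
#' range but mean far below zero is classified snow-free.
#'
#' @param series Logger data.frame with `timestamp` and `t_surface_2cm`.
#' @param range_max Maximum daily range in C for snow (default 1.5).
#' @param mean_tol Maximum |daily mean| in C for snow (default 1.5).
#' @return data.frame with `date`, `doy`, `snow` (logical), `t_range`,
#'   `t_mean`.
#' @export
detect_snow_days <- function(series, range_max = 1.5, mean_tol = 1.5) {
  day <- strftime(series$timestamp, "%Y-%m-%d", tz = "UTC")
  # expected samples per day from the series' own step; drop edge days
  counts <- table(day)
  full <- names(counts)[counts == max(counts)]
  keep <- day %in% full
  x <- series$t_surface_2cm[keep]
  dsub <- day[keep]
  t_min <- tapply(x, dsub, min, na.rm = TRUE)
  t_max <- tapply(x, dsub, max, na.rm = TRUE)
  t_mean <- tapply(x, dsub, mean, na.rm = TRUE)
  dates <- as.Date(names(t_mean))
  rng <- as.numeric(t_max - t_min)
  mu <- as.numeric(t_mean)
  data.frame(date = dates,
             doy = as.integer(strftime(dates, "%j")),
             snow = rng < range_max & abs(mu) <= mean_tol,
             t_range = rng, t_mean = mu)
}

#' First melt-out day from a daily snow classification
#'
#' The snowmelt day is the first day on or after April 1 that begins a
#' run of at least three consecutive snow-free days. April 1 is found by
#' date arithmetic, so leap years are handled (DOY 92 in regular years,
#' 91 in leap years). If the series is snow-free from April 1 onward the
#' melt day is April 1 itself; if no such run exists the result is
#' undefined and flagged.
#'
#' @param snow_days data.frame from [detect_snow_days()] (columns `date`
#'   and `snow`), covering at least April-August of one year.
#' @param year Calendar year; default taken from the data.
#' @return List with `melt_doy` (integer or `NA`), `melt_date`,
#'   `n_snow_days` (snow days in the year up to the melt day, or total
#'   when undefined) and `flags`.
#' @export
snowmelt_day <- function(snow_days, year = NULL) {
  if (is.null(year)) {
    year <- as.integer(strftime(snow_days$date[1], "%Y"))
  }
  april1 <- as.Date(sprintf("%d-04-01", year))
  sub <- snow_days[snow_days$date >= april1 &
                     snow_days$date <= as.Date(sprintf("%d-12-31", year)), ]
  sub <- sub[order(sub$date), ]
  flags <- character(0)
  melt_date <- as.Date(NA)
  if (nrow(sub) >= 3) {
    free <- !sub$snow
    # contiguity guard: a run must also be consecutive calendar days
    for (i in seq_len(nrow(sub) - 2)) {
      if (all(free[i:(i + 2)]) &&
          as.integer(sub$date[i + 2] - sub$date[i]) == 2) {
        melt_date <- sub$date[i]
        break
      }
    }
  }
  if (is.na(melt_date)) {
    flags <- c(flags, "NO_MELT_DETECTED")
    n_snow <- sum(snow_days$snow[strftime(snow_days$date, "%Y") ==
                                   as.character(year)], na.rm = TRUE)
    return(list(melt_doy = NA_integer_, melt_date = melt_date,
                n_snow_days = n_snow, flags = flags,
                criterion = "default"))
  }
  in_year <- strftime(snow_days$date, "%Y") == as.character(year)
  n_snow <- sum(snow_days$snow[in_year & snow_days$date < melt_date],
                na.rm = TRUE)
  list(melt_doy = as.integer(strftime(melt_date, "%j")),
       melt_date = melt_date, n_snow_days = n_snow, flags = flags,
       criterion = "default")
}

#' Warming-treatment differences of microclimate summaries
#'
#' Per community, the OTC minus Ambient difference of plot-level values
#' (e.g. daylight means or melt days), with a standard error combining
#' the between-plot variances of the two arms:
#' \eqn{SE = \sqrt{s^2_{OTC}/n_{OTC} + s^2_{Amb}/n_{Amb}}}.
#'
#' @param plot_means data.frame with `community`, `treatment` and one or
#'   more numeric value columns (every non-key column is summarised).
#' @return data.frame with one row per community x variable: `delta`
#'   (OTC - Ambient), `se`, `n_ambient`, `n_otc`. Communities with one
#'   arm only are skipped with a warning.
#' @export
treatment_delta <- function(plot_means) {
  keys <- c("community", "treatment")
  stopifnot(all(keys %in% names(plot_means)))
  vars <- setdiff(names(plot_means), c(keys, "plot_id", "logger_id"))
  vars <- vars[vapply(plot_means[vars], is.numeric, logical(1))]
  out <- list()
  for (comm in unique(plot_means$community)) {
    sub <- plot_means[plot_means$community == comm, ]
    amb <- sub[sub$treatment == "Ambient", , drop = FALSE]
    otc <- sub[sub$treatment == "OTC", , drop = FALSE]
    if (nrow(amb) == 0 || nrow(otc) == 0) {
      warning("community ", comm, " has a single arm; skipped",
              call. = FALSE)
      next
    }
    for (v in vars) {
      a <- amb[[v]][!is.na(amb[[v]])]
      o <- otc[[v]][!is.na(otc[[v]])]
      se <- if (length(a) >= 2 && length(o) >= 2) {
        sqrt(stats::var(o) / length(o) + stats::var(a) / length(a))
      } else NA_real_
      out[[length(out) + 1]] <- data.frame(
        community = comm, variable = v, delta = mean(o) - mean(a),
        se = se, n_ambient = length(a), n_otc = length(o),
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}
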
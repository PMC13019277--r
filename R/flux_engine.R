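## Flux engine: closure curves -> QC'd plot-level areal fluxes.

#' Barometric pressure at a given elevation
#'
#' Isothermal barometric formula
#' \eqn{P = P_0 \exp(-g M h / (R T))} with \eqn{P_0 = 101325} Pa,
#' \eqn{g = 9.80665} m s^-2, \eqn{M = 0.0289644} kg mol^-1 (dry air) and
#' \eqn{R = 8.314} J mol^-1 K^-1, evaluated at the chamber temperature.
#'
#' @param elevation Elevation above sea level in metres (between -100 and
#'   5000).
#' @param t_ref Reference (chamber) temperature in degrees Celsius.
#' @return Pressure in Pa.
#' @examples
#' elevation_to_pressure(0, 10)      # 101325
#' elevation_to_pressure(981, 10)    # ~ 90 kPa
#' @export
elevation_to_pressure <- function(elevation, t_ref) {
  stopifnot(is.numeric(elevation), is.numeric(t_ref))
  if (any(elevation < -100 | elevation > 5000)) {
    stop("elevation must be between -100 and 5000 m", call. = FALSE)
  }
  t_k <- t_ref + .T0K
  .P0 * exp(-.G0 * .M_AIR * elevation / (.R_GAS * t_k))
}

#' Convert a ppm/s concentration slope to an areal CH4 flux
#'
#' Ideal-gas conversion of a chamber headspace concentration slope to a
#' carbon-mass areal flux:
#' \deqn{F = s \cdot 10^{-6} \cdot \frac{P}{R T} \cdot h_{eff}
#'       \cdot 12.011 \cdot 1000 \cdot 86400}
#' where \eqn{s} is in ppm s^-1, \eqn{P} in Pa, \eqn{T} in K and
#' \eqn{h_{eff}} (effective headspace height = chamber height + collar
#' headspace) in m. The result is in mg C-CH4 m^-2 d^-1; negative slopes
#' give negative fluxes (net uptake).
#'
#' @param slope Concentration slope in ppm s^-1.
#' @param chamber_temp Chamber air temperature in degrees Celsius.
#' @param pressure Chamber pressure in Pa (the vent is assumed to
#'   equalise the chamber to ambient barometric pressure; see
#'   [elevation_to_pressure()]).
#' @param h_eff Effective headspace height in m (> 0).
#' @return Flux in mg C-CH4 m^-2 d^-1.
#' @examples
#' ppm_slope_to_flux(-1e-4, 10, 90000, 0.25)  # -0.992
#' @export
ppm_slope_to_flux <- function(slope, chamber_temp, pressure, h_eff) {
  if (any(h_eff <= 0)) stop("h_eff must be positive", call. = FALSE)
  if (any(pressure <= 0)) stop("pressure must be positive", call. = FALSE)
  t_k <- chamber_temp + .T0K
  slope * 1e-6 * (pressure / (.R_GAS * t_k)) * h_eff * .M_C * 1000 * 86400
}

#' Inverse of [ppm_slope_to_flux()]: flux to concentration slope
#'
#' Used by the synthetic generator to construct closure curves whose
#' noiseless slope corresponds exactly to a stated areal flux.
#'
#' @inheritParams ppm_slope_to_flux
#' @param flux Flux in mg C-CH4 m^-2 d^-1.
#' @return Slope in ppm s^-1.
#' @export
flux_to_ppm_slope <- function(flux, chamber_temp, pressure, h_eff) {
  if (any(h_eff <= 0)) stop("h_eff must be positive", call. = FALSE)
  if (any(pressure <= 0)) stop("pressure must be positive", call. = FALSE)
  t_k <- chamber_temp + .T0K
  flux / (1e-6 * (pressure / (.R_GAS * t_k)) * h_eff * .M_C * 1000 * 86400)
}

#' Fit the closure regression slope
#'
#' Ordinary least squares of CH4 concentration on time over the samples
#' after the deadband (`t > deadband_s`; the first 30 s of a deployment
#' are discarded by default to remove placement disturbance).
#'
#' The coefficient of determination of a zero-variance response is
#' defined as 0 rather than NaN so that the downstream R-squared
#' screening rule is total.
#'
#' @param series A closure series: a data.frame (or list) with numeric
#'   fields `t` (seconds, strictly increasing) and `ch4` (ppm).
#' @param deadband_s Deadband in seconds (default 30); samples with
#'   `t <= deadband_s` are dropped before the fit.
#' @return A list with `slope` (ppm s^-1), `slope_se`, `r2`, `n_used`
#'   and `flags` (character vector; `"SHORT_SERIES"` with `NA` slope when
#'   fewer than 30 samples survive the deadband).
#' @examples
#' s <- list(t = 0:239, ch4 = 1.9 + 0.001 * (0:239))
#' fit_slope(s)$slope  # 0.001
#' @export
fit_slope <- function(series, deadband_s = 30) {
  t <- series$t
  y <- series$ch4
  if (is.unsorted(t, strictly = TRUE)) {
    stop("closure time vector must be strictly increasing", call. = FALSE)
  }
  keep <- t > deadband_s
  t <- t[keep]
  y <- y[keep]
  n <- length(t)
  if (n < 30) {
    return(list(slope = NA_real_, slope_se = NA_real_, r2 = NA_real_,
                n_used = n, flags = "SHORT_SERIES"))
  }
  tc <- t - mean(t)
  yc <- y - mean(y)
  sxx <- sum(tc^2)
  sxy <- sum(tc * yc)
  syy <- sum(yc^2)
  slope <- sxy / sxx
  rss <- syy - slope * sxy
  rss <- max(rss, 0)  # guard tiny negative from cancellation
  if (syy <= 0) {
    # flat response: slope 0 by construction, r2 defined as 0
    return(list(slope = 0, slope_se = 0, r2 = 0, n_used = n,
                flags = character(0)))
  }
  se <- sqrt(rss / (n - 2) / sxx)
  r2 <- 1 - rss / syy
  list(slope = slope, slope_se = se, r2 = r2, n_used = n,
       flags = character(0))
}

#' Compute the flux estimate for one closure series
#'
#' Convenience wrapper chaining [fit_slope()], [elevation_to_pressure()]
#' and [ppm_slope_to_flux()].
#'
#' @param series A closure series as produced by [simulate_closure()] or
#'   [read_closures()]: needs `t`, `ch4`, `chamber_temp`, `elevation`
#'   and either `h_eff` or `chamber_height` + `collar_headspace`.
#' @param deadband_s Deadband in seconds passed to [fit_slope()].
#' @return A one-row data.frame with `slope`, `slope_se`, `r2`, `flux`
#'   (mg C m^-2 d^-1), `n_used` and `qc_flags` (comma-joined string).
#' @export
closure_flux <- function(series, deadband_s = 30) {
  fit <- fit_slope(series, deadband_s = deadband_s)
  h_eff <- series$h_eff
  if (is.null(h_eff)) {
    h_eff <- series$chamber_height + series$collar_headspace
  }
  h_eff <- h_eff[1]
  tchamb <- mean(series$chamber_temp, na.rm = TRUE)
  p <- elevation_to_pressure(series$elevation[1], tchamb)
  flux <- if (is.na(fit$slope)) NA_real_ else {
    ppm_slope_to_flux(fit$slope, tchamb, p, h_eff)
  }
  data.frame(slope = fit$slope, slope_se = fit$slope_se, r2 = fit$r2,
             flux = flux, n_used = fit$n_used,
             qc_flags = paste(fit$flags, collapse = ","),
             stringsAsFactors = FALSE)
}

#' Average replicate flux estimates for one collar and occasion
#'
#' Three chamber deployments per collar and occasion are averaged to one
#' plot-level flux. The mean is the arithmetic mean of the replicate
#' fluxes; `r2` is reported as the mean replicate R-squared and QC flags
#' are unioned.
#'
#' @param estimates data.frame of 1-3 replicate rows with columns `flux`,
#'   `r2` and optionally `qc_flags`.
#' @return One-row data.frame with `flux`, `r2`, `n_reps`, `qc_flags`.
#'   Zero surviving replicates give an `NA` flux (a missing value, not an
#'   error).
#' @export
average_collar <- function(estimates) {
  n <- nrow(estimates)
  if (is.null(n) || n == 0) {
    return(data.frame(flux = NA_real_, r2 = NA_real_, n_reps = 0L,
                      qc_flags = "", stringsAsFactors = FALSE))
  }
  if (n > 3) stop("at most 3 replicates per collar and occasion",
                  call. = FALSE)
  flags <- if ("qc_flags" %in% names(estimates)) {
    unique(unlist(strsplit(estimates$qc_flags, ",", fixed = TRUE)))
  } else character(0)
  flags <- flags[nzchar(flags)]
  data.frame(flux = mean(estimates$flux), r2 = mean(estimates$r2),
             n_reps = n, qc_flags = paste(sort(flags), collapse = ","),
             stringsAsFactors = FALSE)
}

#' Quality-control screening of a campaign flux table
#'
#' Rows with `r2 >= r2_include` (default 0.8) are always retained. Rows
#' in the range `0 <= r2 < r2_include` — kept in the table so that valid
#' low and zero fluxes survive — are screened as outliers: a row is
#' removed when its flux deviates by more than `outlier_sigma` (default
#' 3) standard deviations from the mean of the *other* rows of its group
#' (leave-one-out, so a gross outlier cannot mask itself by inflating
#' the group spread). The group is community x treatment x year by
#' default (the narrowest grouping with enough rows). Groups with fewer
#' than 3 rows are retained unscreened with a warning.
#'
#' The function is idempotent: re-filtering a retained table removes
#' nothing further.
#'
#' @param table Campaign table with columns `f_net`, `r2`, `community`,
#'   `treatment` and `occasion` (Date or ISO string; the year is taken
#'   from it).
#' @param r2_include R-squared above which rows bypass screening.
#' @param outlier_sigma Number of group standard deviations.
#' @param group Character vector of grouping columns; `"year"` is derived
#'   from `occasion`.
#' @return List with `retained` (input rows passing QC) and `rejected`
#'   (removed rows, with `qc_flags` gaining `"OUTLIER_3SIGMA"`).
#' @export
qc_filter <- function(table, r2_include = 0.8, outlier_sigma = 3,
                      group = c("community", "treatment", "year")) {
  stopifnot(all(c("f_net", "r2") %in% names(table)))
  tab <- table
  if ("year" %in% group && !"year" %in% names(tab)) {
    tab$year <- format(as.Date(tab$occasion), "%Y")
  }
  key <- interaction(tab[group], drop = TRUE)
  remove <- rep(FALSE, nrow(tab))
  for (g in levels(key)) {
    idx <- which(key == g)
    if (length(idx) < 3) {
      warning("group ", g, " has fewer than 3 rows; outlier screening skipped",
              call. = FALSE)
      next
    }
    low_r2 <- !is.na(tab$r2[idx]) & tab$r2[idx] < r2_include
    for (j in idx[low_r2]) {
      others <- tab$f_net[setdiff(idx, j)]
      mu <- mean(others, na.rm = TRUE)
      sg <- stats::sd(others, na.rm = TRUE)
      if (!is.finite(sg) || sg == 0) next
      if (!is.na(tab$f_net[j]) &&
          abs(tab$f_net[j] - mu) > outlier_sigma * sg) {
        remove[j] <- TRUE
      }
    }
  }
  rejected <- table[remove, , drop = FALSE]
  if (nrow(rejected) > 0) {
    rejected$qc_flags <- if ("qc_flags" %in% names(rejected)) {
      ifelse(nzchar(rejected$qc_flags),
             paste0(rejected$qc_flags, ",OUTLIER_3SIGMA"), "OUTLIER_3SIGMA")
    } else "OUTLIER_3SIGMA"
  }
  list(retained = table[!remove, , drop = FALSE], rejected = rejected)
}

#' Fill short gaps with the group mean
#'
#' Missing plot-level fluxes (NA `f_net`) are replaced by the mean of the
#' available values in their community x treatment x occasion group, but
#' only when no more than two of the `n_expected` (default 5) plots are
#' missing. Groups with three or more missing values are left untouched.
#' This restores the balanced structure needed by repeated-measures
#' models without inventing data in poorly sampled cells.
#'
#' @param table Campaign table with `f_net` and the grouping columns.
#' @param group Grouping columns (default community x treatment x
#'   occasion).
#' @param n_expected Plots expected per group (default 5).
#' @return The table with eligible NAs filled and `qc_flags` gaining
#'   `"IMPUTED"` on filled rows. Non-missing values are never changed.
#' @export
impute_missing <- function(table,
                           group = c("community", "treatment", "occasion"),
                           n_expected = 5) {
  stopifnot("f_net" %in% names(table), n_expected >= 2)
  if (!"qc_flags" %in% names(table)) table$qc_flags <- ""
  key <- interaction(table[group], drop = TRUE)
  for (g in levels(key)) {
    idx <- which(key == g)
    miss <- idx[is.na(table$f_net[idx])]
    n_miss <- (n_expected - (length(idx) - length(miss)))
    if (length(miss) == 0 || n_miss > 2 || n_miss < 1) next
    have <- table$f_net[idx]
    table$f_net[miss] <- mean(have, na.rm = TRUE)
    table$qc_flags[miss] <- ifelse(nzchar(table$qc_flags[miss]),
                                   paste0(table$qc_flags[miss], ",IMPUTED"),
                                   "IMPUTED")
  }
  table
}

#' Seasonal accumulation of covariates and response transforms
#'
#' Adds, per plot and year (occasions ordered in time), the cumulative
#' sums `cum_t_soil` and `cum_swc` of soil temperature and soil water
#' content up to each occasion, plus two response transforms used for
#' model tables:
#' * `f_net_nsqrt`: negative square root, \eqn{-\sqrt{-x}} for
#'   \eqn{x \le 0} (variance stabilisation of uptake rates; `NA` for
#'   positive fluxes),
#' * `f_net_slog`: signed log, \eqn{\mathrm{sign}(x)\ln(1+|x|)}.
#'
#' @param table Campaign table with `plot_id`, `occasion`, `t_soil`,
#'   `swc` and `f_net`.
#' @return The table with the four added columns.
#' @export
covariate_accumulate <- function(table) {
  stopifnot(all(c("plot_id", "occasion", "t_soil", "swc", "f_net") %in%
                  names(table)))
  occ <- as.Date(table$occasion)
  year <- format(occ, "%Y")
  key <- interaction(table$plot_id, year, drop = TRUE)
  table$cum_t_soil <- NA_real_
  table$cum_swc <- NA_real_
  for (g in levels(key)) {
    idx <- which(key == g)
    if (is.unsorted(occ[idx])) {
      stop("occasions must be ordered in time within plot and year",
           call. = FALSE)
    }
    table$cum_t_soil[idx] <- cumsum(table$t_soil[idx])
    table$cum_swc[idx] <- cumsum(table$swc[idx])
  }
  x <- table$f_net
  nsq <- rep(NA_real_, length(x))
  neg <- !is.na(x) & x <= 0
  nsq[neg] <- -sqrt(-x[neg])
  table$f_net_nsqrt <- nsq
  table$f_net_slog <- sign(x) * log1p(abs(x))
  table
}
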
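## Seeded synthetic-data generators with known ground truth.
##
## Every downstream stage (flux engine, partitioning, statistics,
## microclimate) has a recovery test against these generators: they
## invert the exact same unit conversions the analysis applies, so a
## noiseless round trip is an identity.

# evaluate expr under a temporary RNG state seeded with `seed`;
# the caller's RNG stream is untouched
.with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (has_old) assign(".Random.seed", old, envir = globalenv())
      else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    })
    set.seed(as.integer(seed))
  }
  expr
}

# deterministic sub-stream seeds derived from one global seed
# (double arithmetic: 2^31 * 48271 stays well inside 2^53)
.sub_seed <- function(seed, k) {
  as.integer((as.numeric(seed) * 48271 + as.numeric(k)) %% 2147483647)
}

#' Ground truth for one synthetic chamber closure
#'
#' @param true_flux True areal flux in mg C-CH4 m^-2 d^-1 (negative =
#'   uptake).
#' @param c0 Initial chamber CH4 concentration in ppm (default 1.9,
#'   roughly ambient).
#' @param noise_sd Per-sample AR(1) innovation standard deviation in ppm.
#' @param ar1_rho AR(1) autocorrelation of the analyzer noise in `[0, 1)`
#'   (default 0.3; 1 Hz analyzer readings are autocorrelated, so white
#'   noise would make the QC step unrealistically easy).
#' @param disturbance_amp Amplitude in ppm of a decaying placement pulse
#'   confined to the first `d_s` seconds (default 0).
#' @param d_s Disturbance duration in seconds (default 30, the deadband).
#' @param chamber_temp Chamber temperature in degrees C.
#' @param elevation Site elevation in m.
#' @param h_eff Effective headspace height in m (chamber height + collar
#'   headspace; default 0.25 = 0.20 + 0.05).
#' @return A `closure_truth` list.
#' @export
closure_truth <- function(true_flux, c0 = 1.9, noise_sd = 0,
                          ar1_rho = 0.3, disturbance_amp = 0, d_s = 30,
                          chamber_temp = 10, elevation = 981,
                          h_eff = 0.25) {
  stopifnot(noise_sd >= 0, ar1_rho >= 0, ar1_rho < 1, h_eff > 0, d_s >= 0)
  structure(list(true_flux = true_flux, c0 = c0, noise_sd = noise_sd,
                 ar1_rho = ar1_rho, disturbance_amp = disturbance_amp,
                 d_s = d_s, chamber_temp = chamber_temp,
                 elevation = elevation, h_eff = h_eff),
            class = "closure_truth")
}

#' Simulate one chamber closure concentration series
#'
#' The noiseless series is a straight line whose slope is the exact
#' inversion of the ppm-to-flux conversion ([flux_to_ppm_slope()]) at the
#' stated chamber temperature, elevation and headspace height, plus an
#' exponentially decaying placement pulse that is identically zero after
#' `truth$d_s` seconds. Gaussian AR(1) noise is added on top.
#'
#' @param truth A [closure_truth()] object.
#' @param duration_s Closure length in seconds (default 240, i.e. 4 min;
#'   must be at least `d_s + 60`).
#' @param hz Sampling rate in samples per second (default 1).
#' @param seed Integer seed; the caller's RNG stream is left untouched.
#' @return A `closure_series` list with `t` (s), `ch4` (ppm), scalar
#'   `chamber_temp`, `elevation`, `h_eff`, and the `truth` attached for
#'   test access.
#' @examples
#' tr <- closure_truth(true_flux = -1, noise_sd = 0)
#' s <- simulate_closure(tr, seed = 1)
#' fit_slope(s)$r2
#' @export
simulate_closure <- function(truth, duration_s = 240, hz = 1, seed = NULL) {
  stopifnot(inherits(truth, "closure_truth"))
  if (duration_s <= 0 || hz < 1) {
    stop("duration_s must be positive and hz >= 1", call. = FALSE)
  }
  if (duration_s < truth$d_s + 60) {
    stop("duration_s must be at least d_s + 60 seconds", call. = FALSE)
  }
  n <- as.integer(round(duration_s * hz))
  t <- (seq_len(n) - 1L) / hz
  pressure <- elevation_to_pressure(truth$elevation, truth$chamber_temp)
  slope <- flux_to_ppm_slope(truth$true_flux, truth$chamber_temp,
                             pressure, truth$h_eff)
  ch4 <- truth$c0 + slope * t
  if (truth$disturbance_amp != 0 && truth$d_s > 0) {
    pulse <- truth$disturbance_amp * exp(-6 * t / truth$d_s)
    pulse[t > truth$d_s] <- 0
    ch4 <- ch4 + pulse
  }
  if (truth$noise_sd > 0) {
    noise <- .with_seed(seed, {
      innov <- stats::rnorm(n, 0, truth$noise_sd)
      as.numeric(stats::filter(innov, truth$ar1_rho, method = "recursive"))
    })
    ch4 <- ch4 + noise
  }
  structure(list(t = t, ch4 = ch4, chamber_temp = truth$chamber_temp,
                 elevation = truth$elevation, h_eff = truth$h_eff,
                 truth = truth),
            class = "closure_series")
}

## --- campaign generator ----------------------------------------------------

# concave-down soil-moisture modifier for methanotrophy: peaks at swc_opt,
# falls to zero at swc_opt +/- width (diffusion limitation when wet,
# desiccation when dry)
.f_swc <- function(swc, swc_opt = 0.2, width = 0.55) {
  pmax(0, 1 - ((swc - swc_opt) / width)^2)
}

# increasing (logistic) soil-moisture modifier for methanogenesis:
# anoxia develops as pores saturate
.g_swc <- function(swc, mid = 0.5, scale = 0.08) {
  1 / (1 + exp(-(swc - mid) / scale))
}

#' Default community parameters for the campaign generator
#'
#' One row per plant community (dry heath HD, dry meadow MD, mesic meadow
#' MM, wet meadow MW, tussock tundra TT) and treatment (Ambient, OTC):
#' baseline production `p0` and atmospheric-uptake capacity `catm0` (mg C
#' m^-2 d^-1 at 10 C and optimal moisture), soil-derived-oxidation demand
#' `cs0`, temperature sensitivities `q10_prod` and `q10_ox`, and the
#' moisture and soil-temperature climate of the community
#' (`swc_mean`/`swc_sd` in m^3 m^-3, `tsoil_mean`/`tsoil_sd` in C).
#'
#' The defaults are fixture constants chosen so the Ambient cells
#' reproduce the qualitative sign pattern of an oro-arctic warming site:
#' net uptake in HD/MD/MM, near-zero net flux in MW, net emission in TT;
#' and so the OTC cells show increased oxidation capacity (HD uptake
#' capacity x2.4, strongly reduced TT emission). They are not field
#' estimates.
#'
#' @return data.frame with one row per community x treatment.
#' @export
default_community_params <- function() {
  amb <- data.frame(
    community = c("HD", "MD", "MM", "MW", "TT"),
    treatment = "Ambient",
    p0    = c(0.05, 0.10, 0.40, 0.40, 8.0),
    cs0   = c(0.50, 0.60, 0.60, 0.70, 1.0),
    catm0 = c(1.00, 1.10, 0.90, 0.30, 0.40),
    swc_mean = c(0.15, 0.25, 0.45, 0.65, 0.50),
    swc_sd   = c(0.04, 0.05, 0.08, 0.10, 0.08),
    tsoil_mean = c(9.5, 9.0, 8.5, 8.0, 8.5),
    tsoil_sd   = c(2.5, 2.5, 2.5, 2.5, 2.5),
    stringsAsFactors = FALSE
  )
  otc <- amb
  otc$treatment <- "OTC"
  # oxidation capacity scaled up under warming; MD/MM slightly drier;
  # TT keeps its production but oxidises most of it away
  otc$catm0 <- c(2.40, 3.30, 1.44, 0.36, 0.12)
  otc$cs0   <- c(1.20, 1.80, 0.96, 0.70, 5.20)
  otc$swc_mean <- amb$swc_mean - c(0, 0.05, 0.05, 0, 0)
  otc$tsoil_mean <- amb$tsoil_mean + c(0, 0.4, 0, 0, 0)
  out <- rbind(amb, otc)
  out$q10_prod <- 3.0
  out$q10_ox <- 2.0
  out
}

#' Scenario configuration for [simulate_campaign()]
#'
#' @param communities Subset of `c("HD","MD","MM","MW","TT")`.
#' @param treatments Subset of `c("Ambient","OTC")`.
#' @param n_plots_per_cell Plots per community x treatment (default 5).
#' @param occasions Measurement dates; default is bi-weekly June-August
#'   for two consecutive seasons (12 occasions).
#' @param params Community parameter table; default
#'   [default_community_params()].
#' @param noise_sd_flux Plot-level flux measurement noise sd in mg C
#'   m^-2 d^-1 (default 0.15).
#' @param seed Integer seed; all sub-streams are derived from it.
#' @return A `scenario_config` list.
#' @export
scenario_config <- function(communities = c("HD", "MD", "MM", "MW", "TT"),
                            treatments = c("Ambient", "OTC"),
                            n_plots_per_cell = 5,
                            occasions = NULL,
                            params = default_community_params(),
                            noise_sd_flux = 0.15,
                            seed = 1L) {
  if (length(communities) == 0) {
    stop("communities must be non-empty", call. = FALSE)
  }
  .check_community(communities)
  .check_treatment(treatments)
  stopifnot(n_plots_per_cell >= 1, noise_sd_flux >= 0,
            all(params$p0 >= 0), all(params$catm0 >= 0),
            all(params$q10_prod > 0), all(params$q10_ox > 0),
            all(params$swc_mean >= 0 & params$swc_mean <= 1))
  if (is.null(occasions)) {
    occasions <- c(as.Date("2017-06-05") + 14 * (0:5),
                   as.Date("2018-06-05") + 14 * (0:5))
  }
  structure(list(communities = communities, treatments = treatments,
                 n_plots_per_cell = n_plots_per_cell,
                 occasions = as.Date(occasions), params = params,
                 noise_sd_flux = noise_sd_flux, seed = as.integer(seed)),
            class = "scenario_config")
}

#' Simulate a full measurement campaign with known ground truth
#'
#' For every plot and occasion, soil temperature and soil water content
#' are drawn from the community climate, then the component fluxes are
#' computed from the rate laws
#' \deqn{P = p_0\, q_{10,prod}^{(T-10)/10}\, g(SWC)}
#' \deqn{C_{atm} = c_{atm,0}\, q_{10,ox}^{(T-10)/10}\, f(SWC)}
#' \deqn{C_{soil} = \min(P,\; c_{s,0}\, q_{10,ox}^{(T-10)/10}\, f(SWC))}
#' with \eqn{f} a concave-down quadratic in SWC (methanotrophy peaks in
#' moist-but-aerated soil) and \eqn{g} logistic in SWC (methanogenesis
#' requires saturation). The net flux is
#' \eqn{F_{net} = P - C_{soil} - C_{atm}} by construction, to which
#' Gaussian measurement noise is added for the observed table.
#'
#' A proxy closure R-squared is attached per row as
#' \eqn{F^2 / (F^2 + \sigma^2)}, so near-zero true fluxes naturally show
#' low coefficients of determination, as real near-zero closures do.
#'
#' @param config A [scenario_config()].
#' @return List with `table` (the observed campaign table: `plot_id`,
#'   `community`, `treatment`, `occasion`, `f_net`, `r2`, `t_soil`,
#'   `swc`) and `truth` (same keys plus true `p_soil`, `c_soil`,
#'   `c_atm`, `f_net_true`).
#' @export
simulate_campaign <- function(config) {
  stopifnot(inherits(config, "scenario_config"))
  p <- config$params
  cells <- expand.grid(community = config$communities,
                       treatment = config$treatments,
                       stringsAsFactors = FALSE)
  rows <- vector("list", nrow(cells))
  for (i in seq_len(nrow(cells))) {
    par <- p[p$community == cells$community[i] &
               p$treatment == cells$treatment[i], ]
    if (nrow(par) != 1) {
      stop("no parameter row for ", cells$community[i], " ",
           cells$treatment[i], call. = FALSE)
    }
    grid <- expand.grid(plot = seq_len(config$n_plots_per_cell),
                        occasion = config$occasions)
    n <- nrow(grid)
    sim <- .with_seed(.sub_seed(config$seed, i), {
      t_soil <- stats::rnorm(n, par$tsoil_mean, par$tsoil_sd)
      swc <- pmin(1, pmax(0.02, stats::rnorm(n, par$swc_mean, par$swc_sd)))
      eps <- stats::rnorm(n, 0, config$noise_sd_flux)
      list(t_soil = t_soil, swc = swc, eps = eps)
    })
    tf_prod <- par$q10_prod^((sim$t_soil - 10) / 10)
    tf_ox <- par$q10_ox^((sim$t_soil - 10) / 10)
    p_soil <- par$p0 * tf_prod * .g_swc(sim$swc)
    demand <- par$cs0 * tf_ox * .f_swc(sim$swc)
    c_soil <- pmin(p_soil, demand)
    c_atm <- par$catm0 * tf_ox * .f_swc(sim$swc)
    f_true <- p_soil - c_soil - c_atm
    f_obs <- f_true + sim$eps
    sig <- max(config$noise_sd_flux, 1e-8)
    r2 <- pmin(0.99, f_true^2 / (f_true^2 + sig^2))
    rows[[i]] <- data.frame(
      plot_id = sprintf("%s-%s-%02d", cells$community[i],
                        cells$treatment[i], grid$plot),
      community = cells$community[i], treatment = cells$treatment[i],
      occasion = grid$occasion,
      f_net = f_obs, r2 = r2, t_soil = sim$t_soil, swc = sim$swc,
      p_soil = p_soil, c_soil = c_soil, c_atm = c_atm, f_net_true = f_true,
      stringsAsFactors = FALSE
    )
  }
  full <- do.call(rbind, rows)
  obs_cols <- c("plot_id", "community", "treatment", "occasion",
                "f_net", "r2", "t_soil", "swc")
  list(table = full[obs_cols],
       truth = full[c(obs_cols[1:4], "p_soil", "c_soil", "c_atm",
                      "f_net_true", "t_soil", "swc")])
}

#' Simulate a pre/post acetylene-inhibition closure pair
#'
#' The pre-incubation closure realises the row's net flux; the
#' post-incubation closure realises its gross production (complete
#' methanotrophy inhibition assumed). Pre closures use the transparent
#' 20 cm chamber, post closures the opaque 10 cm incubation chamber
#' (h_eff 0.25 m and 0.15 m respectively with the default 5 cm collar
#' headspace).
#'
#' @param row One truth row with `f_net_true` (or `f_net`) and `p_soil`
#'   in mg C m^-2 d^-1, both components nonnegative where applicable.
#' @param seed Integer seed.
#' @param noise_sd Analyzer noise sd in ppm (default 0.002).
#' @param chamber_temp,elevation Closure conditions.
#' @return List with `pre` and `post` closure series.
#' @export
simulate_inhibition_pair <- function(row, seed = NULL, noise_sd = 0.002,
                                     chamber_temp = 10, elevation = 981) {
  f_net <- if (!is.null(row$f_net_true)) row$f_net_true else row$f_net
  p_soil <- row$p_soil
  stopifnot(is.finite(f_net), is.finite(p_soil), p_soil >= 0)
  pre_truth <- closure_truth(true_flux = f_net, noise_sd = noise_sd,
                             chamber_temp = chamber_temp,
                             elevation = elevation, h_eff = 0.25)
  post_truth <- closure_truth(true_flux = p_soil, noise_sd = noise_sd,
                              chamber_temp = chamber_temp,
                              elevation = elevation, h_eff = 0.15)
  list(pre = simulate_closure(pre_truth, seed = .sub_seed(seed %||% 0, 1)),
       post = simulate_closure(post_truth, seed = .sub_seed(seed %||% 0, 2)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

## --- logger generator ------------------------------------------------------

#' Snow scenario for [simulate_logger_year()]
#'
#' @param snow_start_doy,snow_end_doy Day-of-year interval of continuous
#'   snow cover (snow on both endpoints).
#' @param free_amplitude Peak-to-peak diurnal amplitude in C of the
#'   2 cm surface channel when snow-free (default 8).
#' @param under_snow_sd Noise sd in C of the damped near-zero surface
#'   signal under snow (default 0.2).
#' @param melt_swc_pulse Step increase of soil moisture at melt-out in
#'   m^3 m^-3 (default 0.15).
#' @param no_snow If TRUE the year has no snow cover at all (degenerate
#'   interval) and the interval arguments are ignored.
#' @return A `snow_scenario` list.
#' @export
snow_scenario <- function(snow_start_doy = 1, snow_end_doy = 140,
                          free_amplitude = 8, under_snow_sd = 0.2,
                          melt_swc_pulse = 0.15, no_snow = FALSE) {
  if (!no_snow) {
    stopifnot(snow_start_doy >= 1, snow_start_doy < snow_end_doy,
              snow_end_doy <= 366)
  }
  stopifnot(free_amplitude > 0, under_snow_sd >= 0)
  structure(list(snow_start_doy = snow_start_doy,
                 snow_end_doy = snow_end_doy,
                 free_amplitude = free_amplitude,
                 under_snow_sd = under_snow_sd,
                 melt_swc_pulse = melt_swc_pulse, no_snow = no_snow),
            class = "snow_scenario")
}

#' Simulate one year of 15-minute microclimate logger data
#'
#' The 2 cm surface channel shows a seasonal mean plus a diurnal
#' sinusoid (peak-to-peak `free_amplitude`, warmest at 14:00) when
#' snow-free, and a damped near-0 C signal (sd `under_snow_sd`) inside
#' the snow interval. Air (15 cm) and soil (-8 cm) channels are scaled
#' variants; the soil-moisture channel steps up by `melt_swc_pulse` at
#' the melt-out day and relaxes back over about a month.
#'
#' @param scenario A [snow_scenario()].
#' @param year Calendar year of the series (default 2021).
#' @param seed Integer seed.
#' @return A data.frame with `timestamp` (POSIXct, local), `t_air_15cm`,
#'   `t_surface_2cm`, `t_soil_8cm` (C) and `swc` (m^3 m^-3); the
#'   scenario is attached as attribute `"truth"`.
#' @export
simulate_logger_year <- function(scenario, year = 2021, seed = NULL) {
  stopifnot(inherits(scenario, "snow_scenario"))
  t0 <- as.POSIXct(sprintf("%d-01-01 00:00:00", year), tz = "UTC")
  t1 <- as.POSIXct(sprintf("%d-12-31 23:45:00", year), tz = "UTC")
  ts <- seq(t0, t1, by = 15 * 60)
  n <- length(ts)
  doy <- as.integer(strftime(ts, "%j", tz = "UTC"))
  hour <- as.numeric(ts - as.POSIXct(strftime(ts, "%Y-%m-%d", tz = "UTC"),
                                     tz = "UTC"), units = "hours")
  season <- 1.5 - 10 * cos(2 * pi * (doy - 20) / 365)
  diurnal <- cos(2 * pi * (hour - 14) / 24)
  snow <- if (scenario$no_snow) rep(FALSE, n) else {
    doy >= scenario$snow_start_doy & doy <= scenario$snow_end_doy
  }
  dat <- .with_seed(seed, {
    e_surf <- stats::rnorm(n, 0, 0.15)
    # under snow the sensor is thermally buffered: a slowly drifting
    # daily level (sd under_snow_sd) plus small fast jitter, not white
    # noise at the sample scale
    day_level <- stats::rnorm(367, 0, scenario$under_snow_sd)
    e_snow <- day_level[doy] + stats::rnorm(n, 0, 0.03)
    e_swc <- stats::rnorm(n, 0, 0.004)
    list(e_surf = e_surf, e_snow = e_snow, e_swc = e_swc)
  })
  free_surf <- season + (scenario$free_amplitude / 2) * diurnal + dat$e_surf
  t_surface <- ifelse(snow, dat$e_snow, free_surf)
  t_air <- season + (scenario$free_amplitude * 0.6) * diurnal + dat$e_surf
  t_soil <- ifelse(snow, 0.5 * dat$e_snow,
                   0.8 * season + 0.5 * diurnal + 0.5 * dat$e_surf)
  swc <- 0.30 + dat$e_swc
  if (!scenario$no_snow) {
    since_melt <- doy - scenario$snow_end_doy
    pulse <- ifelse(since_melt >= 1,
                    scenario$melt_swc_pulse * exp(-(since_melt - 1) / 30), 0)
    swc <- swc + pulse
  }
  out <- data.frame(timestamp = ts, t_air_15cm = t_air,
                    t_surface_2cm = t_surface, t_soil_8cm = t_soil,
                    swc = pmin(1, pmax(0, swc)))
  attr(out, "truth") <- scenario
  out
}
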
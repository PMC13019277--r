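## Acetylene-inhibition partitioning of the net CH4 flux.
##
## Identity: F_net = P_soil - C_soil - C_atm, with C_soil = P_soil when
## total oxidation is at least P_soil (which holds whenever F_net <= 0).
## The post-incubation flux, measured after 2 h under ~10 % vol acetylene
## (a methane-monooxygenase inhibitor), estimates P_soil — a lower bound,
## since complete inhibition cannot be verified in the field.

#' Acetylene headspace volume fraction from calcium carbide hydrolysis
#'
#' Complete hydrolysis CaC2 + 2 H2O -> C2H2 + Ca(OH)2 produces one mole
#' of acetylene per mole of carbide. The volume (mole) fraction in the
#' chamber headspace follows from the ideal gas law:
#' \eqn{x = (m / M_{CaC_2}) / (P V / (R T))}.
#'
#' With the field protocol (1.23 g CaC2 into an opaque 10 cm chamber on
#' a collar with 5 cm headspace, i.e. a cylinder of radius 0.10 m and
#' height 0.15 m) at 283 K and 90 kPa this gives approximately 10 % vol.
#'
#' @param mass_cac2_g Calcium carbide mass in g (default 1.23).
#' @param headspace_m3 Chamber headspace volume in m^3 (default
#'   `pi * 0.10^2 * 0.15`).
#' @param temp_k Headspace temperature in K (default 283).
#' @param pressure_pa Headspace pressure in Pa (default 90000).
#' @return Acetylene volume fraction (dimensionless).
#' @examples
#' acetylene_fraction()  # ~ 0.106
#' @export
acetylene_fraction <- function(mass_cac2_g = 1.23,
                               headspace_m3 = pi * 0.10^2 * 0.15,
                               temp_k = 283, pressure_pa = 90000) {
  stopifnot(mass_cac2_g > 0, headspace_m3 > 0, temp_k > 0, pressure_pa > 0)
  m_cac2 <- 64.10  # g mol^-1
  n_c2h2 <- mass_cac2_g / m_cac2
  n_air <- pressure_pa * headspace_m3 / (.R_GAS * temp_k)
  n_c2h2 / n_air
}

#' Estimate gross soil CH4 production from a post-inhibition closure
#'
#' The post-incubation flux is accepted as P_soil only when its closure
#' regression has R-squared of at least `r2_cutoff` (default 0.8); below
#' that the production estimate is undefined
#' (flag `P_UNDEFINED_LOW_R2`). A negative post-inhibition flux — an
#' incomplete-inhibition artefact, since production cannot be negative —
#' is clamped to 0 with flag `NEGATIVE_POST_FLUX`.
#'
#' @param post_series Post-incubation closure series (see
#'   [closure_flux()] for required fields).
#' @param r2_cutoff R-squared acceptance threshold on the post closure.
#' @param deadband_s Deadband passed to the closure fit.
#' @return List with `p_soil` (mg C m^-2 d^-1 or `NA` when undefined),
#'   `flux` (the raw post flux), `r2` and `flags`.
#' @export
estimate_production <- function(post_series, r2_cutoff = 0.8,
                                deadband_s = 30) {
  est <- closure_flux(post_series, deadband_s = deadband_s)
  flags <- character(0)
  if (nzchar(est$qc_flags)) flags <- strsplit(est$qc_flags, ",")[[1]]
  if (is.na(est$flux) || is.na(est$r2) || est$r2 < r2_cutoff) {
    return(list(p_soil = NA_real_, flux = est$flux, r2 = est$r2,
                flags = c(flags, "P_UNDEFINED_LOW_R2")))
  }
  p <- est$flux
  if (p < 0) {
    flags <- c(flags, "NEGATIVE_POST_FLUX")
    p <- 0
  }
  list(p_soil = p, flux = est$flux, r2 = est$r2, flags = flags)
}

#' Partition a net flux into production and two oxidation components
#'
#' Given the net flux F_net and the (post-inhibition) gross production
#' P_soil, solves the identity F_net = P_soil - C_soil - C_atm under the
#' assumption that soil-derived CH4 is oxidised before atmospheric CH4:
#'
#' * `f_net <= 0`: total oxidation (`p_soil - f_net`) is at least
#'   `p_soil`, so all production is consumed (`c_soil = p_soil`) and the
#'   remainder is atmospheric uptake (`c_atm = -f_net`);
#' * `0 < f_net <= p_soil`: part of the production escapes;
#'   `c_soil = p_soil - f_net`, `c_atm = 0` (atmospheric uptake cannot
#'   be resolved from two measurements when the soil is a net source);
#' * `f_net > p_soil`: inconsistent with the identity (net emission
#'   exceeding gross production); both components set to 0 with flag
#'   `INCONSISTENT_FNET_GT_P`.
#'
#' @param f_net Net flux in mg C m^-2 d^-1 (negative = uptake).
#' @param p_soil Gross production, `>= 0`, or `NA` if undefined.
#' @param extra_flags Flags to carry through (e.g. from
#'   [estimate_production()]).
#' @return A one-row data.frame (`partition_result`): `f_net`, `p_soil`,
#'   `c_soil`, `c_atm`, `total_oxidation`, `flags` (comma-joined).
#' @examples
#' partition_fluxes(-5, 2)  # c_soil = 2, c_atm = 5
#' partition_fluxes(5, 8)   # c_soil = 3, c_atm = 0
#' @export
partition_fluxes <- function(f_net, p_soil, extra_flags = character(0)) {
  if (is.na(p_soil)) {
    return(data.frame(f_net = f_net, p_soil = NA_real_, c_soil = NA_real_,
                      c_atm = NA_real_, total_oxidation = NA_real_,
                      flags = paste(extra_flags, collapse = ","),
                      stringsAsFactors = FALSE))
  }
  stopifnot(p_soil >= 0)
  flags <- extra_flags
  if (f_net <= 0) {
    c_soil <- p_soil
    c_atm <- -f_net
  } else if (f_net <= p_soil) {
    c_soil <- p_soil - f_net
    c_atm <- 0
  } else {
    c_soil <- 0
    c_atm <- 0
    flags <- c(flags, "INCONSISTENT_FNET_GT_P")
  }
  data.frame(f_net = f_net, p_soil = p_soil, c_soil = c_soil,
             c_atm = c_atm, total_oxidation = c_soil + c_atm,
             flags = paste(flags, collapse = ","), stringsAsFactors = FALSE)
}

#' Partition a campaign of pre/post inhibition closure pairs
#'
#' For every plot: the pre-incubation closure gives F_net (no R-squared
#' cutoff — valid near-zero fluxes must be kept), the post-incubation
#' closure gives P_soil via [estimate_production()] (R-squared cutoff
#' applied), and [partition_fluxes()] solves for the components. Plots
#' whose production is undefined appear in the output with `f_net` only.
#'
#' Group summaries (mean and standard error per community x treatment of
#' each component) and an exact Wilcoxon signed-rank test of
#' `total_oxidation > 0` per group are returned alongside.
#'
#' @param pairs A list of elements, each with `pre` and `post` closure
#'   series plus identifying fields `plot_id`, `community`, `treatment`
#'   (either on the element or on the series).
#' @param r2_cutoff Post-incubation R-squared cutoff (default 0.8).
#' @param deadband_s Closure deadband in seconds.
#' @return List with `plots` (per-plot partition table), `summary`
#'   (per-group means and SEs with the one-sided oxidation p-value) and
#'   `excluded` (character vector of plot ids lacking a usable pair).
#' @export
partition_campaign <- function(pairs, r2_cutoff = 0.8, deadband_s = 30) {
  rows <- list()
  excluded <- character(0)
  for (i in seq_along(pairs)) {
    el <- pairs[[i]]
    id <- el$plot_id %||% sprintf("pair-%03d", i)
    if (is.null(el$pre) || is.null(el$post)) {
      excluded <- c(excluded, id)
      next
    }
    pre <- closure_flux(el$pre, deadband_s = deadband_s)
    prod <- estimate_production(el$post, r2_cutoff = r2_cutoff,
                                deadband_s = deadband_s)
    res <- partition_fluxes(pre$flux, prod$p_soil,
                            extra_flags = prod$flags)
    res$plot_id <- id
    res$community <- el$community %||% NA_character_
    res$treatment <- el$treatment %||% NA_character_
    rows[[length(rows) + 1]] <- res
  }
  plots <- if (length(rows)) do.call(rbind, rows) else
    data.frame(f_net = numeric(0), p_soil = numeric(0), c_soil = numeric(0),
               c_atm = numeric(0), total_oxidation = numeric(0),
               flags = character(0), plot_id = character(0),
               community = character(0), treatment = character(0),
               stringsAsFactors = FALSE)
  summary <- NULL
  if (nrow(plots)) {
    key <- interaction(plots$community, plots$treatment, drop = TRUE)
    summary <- do.call(rbind, lapply(levels(key), function(g) {
      sub <- plots[key == g, , drop = FALSE]
      comp_mean <- function(v) mean(v, na.rm = TRUE)
      tox <- sub$total_oxidation[!is.na(sub$total_oxidation)]
      p_ox <- if (length(tox) >= 1 && any(tox != 0)) {
        wilcoxon_signed_rank(tox, sides = "greater")$p
      } else NA_real_
      data.frame(community = sub$community[1], treatment = sub$treatment[1],
                 n = nrow(sub),
                 f_net_mean = comp_mean(sub$f_net), f_net_se = .se(sub$f_net),
                 p_soil_mean = comp_mean(sub$p_soil),
                 p_soil_se = .se(sub$p_soil),
                 c_soil_mean = comp_mean(sub$c_soil),
                 c_soil_se = .se(sub$c_soil),
                 c_atm_mean = comp_mean(sub$c_atm), c_atm_se = .se(sub$c_atm),
                 oxidation_p = p_ox, stringsAsFactors = FALSE)
    }))
  }
  list(plots = plots, summary = summary, excluded = excluded)
}
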
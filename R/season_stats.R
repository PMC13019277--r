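## Seasonal treatment-effect statistics on time-normalised fluxes.

#' Arcsinh-transform and standardize a group of fluxes
#'
#' Applies the inverse hyperbolic sine
#' \eqn{y = \ln(x + \sqrt{x^2 + 1})} — defined for negative and positive
#' fluxes alike, approximately logarithmic in |x| for large |x| — and
#' z-scores the result with the sample (n-1) standard deviation. Called
#' on all fluxes of one measurement occasion and plant community, across
#' both treatments, this removes the seasonal level and spread so that
#' treatment effect sizes are comparable across occasions.
#'
#' @param values Numeric fluxes of one occasion x community group
#'   (both treatments pooled); at least 2 non-missing values.
#' @return List with `z` (standardized values; exactly mean 0, sd 1) and
#'   `flagged` (TRUE when the transformed group has zero variance, in
#'   which case `z` is all `NA`).
#' @examples
#' arcsinh_standardize(c(-1, 1))$z  # -0.707, +0.707
#' @export
arcsinh_standardize <- function(values) {
  ok <- !is.na(values)
  if (sum(ok) < 2) stop("need at least 2 non-missing values", call. = FALSE)
  y <- asinh(values)
  s <- stats::sd(y[ok])
  if (!is.finite(s) || s == 0) {
    return(list(z = rep(NA_real_, length(values)), flagged = TRUE))
  }
  list(z = (y - mean(y[ok])) / s, flagged = FALSE)
}

#' Hedges'-corrected standardized mean difference (treatment effect size)
#'
#' Cohen's d of OTC minus Ambient with Hedges' small-sample correction:
#' \eqn{d = (\bar{x}_{OTC} - \bar{x}_{Amb}) / s_{pooled}} with the
#' pooled standard deviation on \eqn{n_1 + n_2 - 2} degrees of freedom,
#' \eqn{J = 1 - 3/(4(n_1+n_2-2) - 1)} and \eqn{g = J d}. The sampling
#' variance uses the standard large-sample SMD formula
#' \eqn{var(g) = 1/n_1 + 1/n_2 + g^2 / (2(n_1+n_2))}.
#'
#' With the package's sign convention (negative flux = uptake), a
#' negative g on (normalized) fluxes means increased oxidation capacity
#' under warming — more uptake, less emission, or both.
#'
#' @param ambient,otc Numeric values per arm (n >= 2 each).
#' @return List with `g`, `d`, `j`, `var_g`, `n_ambient`, `n_otc` and
#'   `flagged` (TRUE with `NA` g when the pooled sd is zero).
#' @examples
#' hedges_g(c(1, 2, 3), c(2, 3, 4))$g  # 0.8
#' @export
hedges_g <- function(ambient, otc) {
  ambient <- ambient[!is.na(ambient)]
  otc <- otc[!is.na(otc)]
  n1 <- length(ambient)
  n2 <- length(otc)
  if (n1 < 2 || n2 < 2) stop("need at least 2 values per arm", call. = FALSE)
  df <- n1 + n2 - 2
  s_pooled <- sqrt(((n1 - 1) * stats::var(ambient) +
                      (n2 - 1) * stats::var(otc)) / df)
  if (!is.finite(s_pooled) || s_pooled == 0) {
    return(list(g = NA_real_, d = NA_real_, j = NA_real_, var_g = NA_real_,
                n_ambient = n1, n_otc = n2, flagged = TRUE))
  }
  d <- (mean(otc) - mean(ambient)) / s_pooled
  j <- 1 - 3 / (4 * df - 1)
  g <- j * d
  var_g <- 1 / n1 + 1 / n2 + g^2 / (2 * (n1 + n2))
  list(g = g, d = d, j = j, var_g = var_g, n_ambient = n1, n_otc = n2,
       flagged = FALSE)
}

#' Effect sizes per occasion and community on normalized fluxes
#'
#' For every occasion x community cell with both treatments present:
#' pool the fluxes of both arms, normalize with
#' [arcsinh_standardize()] (or use raw fluxes when `normalized = FALSE`),
#' then compute [hedges_g()] of OTC vs Ambient.
#'
#' @param table Campaign table with `f_net`, `community`, `treatment`,
#'   `occasion`.
#' @param normalized Standardize within each cell first (default TRUE).
#' @return data.frame with one row per occasion x community: `g`,
#'   `var_g`, `n_ambient`, `n_otc`, `flagged`.
#' @export
effect_size_table <- function(table, normalized = TRUE) {
  key <- interaction(table$occasion, table$community, drop = TRUE)
  out <- lapply(levels(key), function(k) {
    sub <- table[key == k, , drop = FALSE]
    arms <- split(seq_len(nrow(sub)), sub$treatment)
    if (!all(c("Ambient", "OTC") %in% names(arms))) return(NULL)
    x <- sub$f_net
    flagged_norm <- FALSE
    if (normalized) {
      st <- arcsinh_standardize(x)
      x <- st$z
      flagged_norm <- st$flagged
    }
    if (flagged_norm || sum(!is.na(x[arms$Ambient])) < 2 ||
        sum(!is.na(x[arms$OTC])) < 2) {
      return(data.frame(occasion = sub$occasion[1],
                        community = sub$community[1], g = NA_real_,
                        var_g = NA_real_, n_ambient = length(arms$Ambient),
                        n_otc = length(arms$OTC), flagged = TRUE,
                        stringsAsFactors = FALSE))
    }
    es <- hedges_g(x[arms$Ambient], x[arms$OTC])
    data.frame(occasion = sub$occasion[1], community = sub$community[1],
               g = es$g, var_g = es$var_g, n_ambient = es$n_ambient,
               n_otc = es$n_otc, flagged = es$flagged,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Wilcoxon signed-rank test against a point null
#'
#' Tests whether a sample is symmetrically distributed around `null`
#' (here: whether fluxes differ from zero). Exact zeros (after
#' subtracting the null) are dropped; ties in |x| are mid-ranked. For
#' `n <= exact_limit` (default 20) the p-value is exact, from the full
#' distribution of the positive-rank sum over all 2^n equally likely
#' sign assignments; above that a normal approximation with continuity
#' and tie correction is used.
#'
#' @param values Numeric sample.
#' @param null Hypothesised centre (default 0).
#' @param sides `"two"` (default), `"greater"` (centre above null) or
#'   `"less"`.
#' @param exact_limit Largest n for exact enumeration (default 20).
#' @return List with `statistic` (W+, the sum of ranks of positive
#'   differences), `p`, `n` (nonzero differences) and `exact`.
#' @examples
#' wilcoxon_signed_rank(c(1, 2, 3, 4, 5))$p  # 0.0625 exactly
#' @export
wilcoxon_signed_rank <- function(values, null = 0, sides = "two",
                                 exact_limit = 20) {
  sides <- match.arg(sides, c("two", "greater", "less"))
  d <- values[!is.na(values)] - null
  d <- d[d != 0]
  n <- length(d)
  if (n < 1) stop("all values equal the null; test undefined", call. = FALSE)
  r <- rank(abs(d))
  w <- sum(r[d > 0])
  if (n <= exact_limit) {
    # distribution of W+ over all 2^n sign assignments, by dynamic
    # programming on 2*rank (integers even with midranks)
    k2 <- as.integer(round(2 * r))
    smax <- sum(k2)
    counts <- numeric(smax + 1)
    counts[1] <- 1
    for (k in k2) {
      shifted <- c(numeric(k), counts[seq_len(smax + 1 - k)])
      counts <- counts + shifted
    }
    total <- 2^n
    w2 <- as.integer(round(2 * w))
    p_le <- sum(counts[seq_len(w2 + 1)]) / total
    p_ge <- sum(counts[(w2 + 1):(smax + 1)]) / total
    p <- switch(sides,
                two = min(1, 2 * min(p_le, p_ge)),
                greater = p_ge,
                less = p_le)
    return(list(statistic = w, p = p, n = n, exact = TRUE))
  }
  mu <- n * (n + 1) / 4
  ties <- table(r)
  sigma2 <- n * (n + 1) * (2 * n + 1) / 24 - sum(ties^3 - ties) / 48
  sigma <- sqrt(sigma2)
  z_ge <- (w - mu - 0.5) / sigma
  z_le <- (w - mu + 0.5) / sigma
  p <- switch(sides,
              two = min(1, 2 * min(stats::pnorm(z_le),
                                   stats::pnorm(z_ge, lower.tail = FALSE))),
              greater = stats::pnorm(z_ge, lower.tail = FALSE),
              less = stats::pnorm(z_le))
  list(statistic = w, p = p, n = n, exact = FALSE)
}

#' Seasonal percent change in net flux under warming
#'
#' Per occasion, the treatment means over plots are compared as
#' \deqn{\Delta\% = 100\,(\bar{F}_{Amb} - \bar{F}_{OTC}) / |\bar{F}_{Amb}|}
#' so that positive values always denote increased oxidation capacity:
#' an uptake increase when both means are negative, an emission
#' reduction when the ambient mean is positive. The seasonal summary is
#' the mean and standard error of the per-occasion values.
#'
#' Occasions whose ambient mean is closer to zero than `floor` are
#' excluded (the ratio is unstable there) and reported.
#'
#' @param table Campaign table with `f_net`, `treatment`, `occasion`,
#'   filtered to one community.
#' @param community Optional community label to subset on.
#' @param floor Minimum |ambient mean| for an occasion to enter
#'   (default 0.05 mg C m^-2 d^-1).
#' @return List with `mean_pct`, `se_pct`, `direction` (`"uptake
#'   increase"`, `"emission reduction"` or `"mixed"`), `per_occasion`
#'   data.frame and `excluded_occasions`.
#' @export
percent_change <- function(table, community = NULL, floor = 0.05) {
  if (!is.null(community)) table <- table[table$community == community, ]
  occ <- sort(unique(table$occasion))
  rows <- list()
  excluded <- table$occasion[0]
  for (o in seq_along(occ)) {
    sub <- table[table$occasion == occ[o], ]
    m_amb <- mean(sub$f_net[sub$treatment == "Ambient"], na.rm = TRUE)
    m_otc <- mean(sub$f_net[sub$treatment == "OTC"], na.rm = TRUE)
    if (!is.finite(m_amb) || !is.finite(m_otc)) next
    if (abs(m_amb) < floor) {
      excluded <- c(excluded, occ[o])
      next
    }
    rows[[length(rows) + 1]] <- data.frame(
      occasion = occ[o], mean_ambient = m_amb, mean_otc = m_otc,
      pct = 100 * (m_amb - m_otc) / abs(m_amb))
  }
  if (length(rows) < 3) {
    stop("need both treatments on at least 3 occasions above the floor",
         call. = FALSE)
  }
  per <- do.call(rbind, rows)
  dir <- if (all(per$mean_ambient < 0) && all(per$mean_otc < 0)) {
    "uptake increase"
  } else if (all(per$mean_ambient > 0)) {
    "emission reduction"
  } else "mixed"
  list(mean_pct = mean(per$pct), se_pct = .se(per$pct), direction = dir,
       per_occasion = per, excluded_occasions = excluded)
}

#' Arrhenius-based Q10 of CH4 uptake
#'
#' Regresses \eqn{\ln(-F_{net})} of the uptake observations on
#' \eqn{x = 1000 / T_K}. The slope m gives the apparent activation
#' energy \eqn{E_a = -1000 R m} (J mol^-1) and
#' \deqn{Q_{10} = \exp\!\left(\frac{E_a \cdot 10}
#'       {R\, T_{ref} (T_{ref} + 10)}\right)}
#' with temperatures in K and `t_ref` defaulting to the mean observed
#' soil temperature of the subset.
#'
#' @param f_net Net fluxes, all strictly negative (uptake only).
#' @param t_soil Soil temperatures in C, same length.
#' @param t_ref Reference temperature in C (default `mean(t_soil)`).
#' @return List: `slope` (per 1000/K), `slope_p`, `ea` (J mol^-1),
#'   `q10`, `t_ref`, `r2`, `n`, `significant` (slope_p < 0.05).
#' @export
q10_estimate <- function(f_net, t_soil, t_ref = NULL) {
  ok <- !is.na(f_net) & !is.na(t_soil)
  f_net <- f_net[ok]
  t_soil <- t_soil[ok]
  if (any(f_net >= 0)) {
    stop("q10_estimate requires uptake observations only (f_net < 0)",
         call. = FALSE)
  }
  if (length(f_net) < 5 || diff(range(t_soil)) < 2) {
    stop("need at least 5 uptake observations spanning at least 2 C",
         call. = FALSE)
  }
  if (is.null(t_ref)) t_ref <- mean(t_soil)
  x <- 1000 / (t_soil + .T0K)
  y <- log(-f_net)
  fit <- stats::lm(y ~ x)
  sm <- summary(fit)
  m <- unname(stats::coef(fit)[2])
  slope_p <- sm$coefficients[2, 4]
  ea <- -1000 * .R_GAS * m
  t_ref_k <- t_ref + .T0K
  q10 <- exp(ea * 10 / (.R_GAS * t_ref_k * (t_ref_k + 10)))
  list(slope = m, slope_p = slope_p, ea = ea, q10 = q10, t_ref = t_ref,
       r2 = sm$r.squared, n = length(f_net),
       significant = is.finite(slope_p) && slope_p < 0.05)
}

#' Quadratic response of CH4 uptake to soil water content
#'
#' Least-squares fit of \eqn{F_{net} = a\,SWC^2 + b\,SWC + c} to the
#' uptake observations. With a > 0 the parabola opens upward and its
#' vertex \eqn{-b/(2a)} is the soil water content of maximal uptake
#' (most negative flux).
#'
#' @param f_net Net fluxes (uptake rows, `f_net < 0`).
#' @param swc Volumetric soil water content in `[0, 1]`, same length.
#' @return List with `a`, `b`, `c`, `vertex` (`NA` unless a > 0), `r2`,
#'   `n`.
#' @export
swc_response <- function(f_net, swc) {
  ok <- !is.na(f_net) & !is.na(swc)
  f_net <- f_net[ok]
  swc <- swc[ok]
  stopifnot(all(swc >= 0 & swc <= 1))
  if (length(f_net) < 4) stop("need at least 4 rows", call. = FALSE)
  X <- cbind(1, swc, swc^2)
  if (qr(X)$rank < 3) stop("rank-deficient design (constant swc?)",
                           call. = FALSE)
  fit <- stats::lm(f_net ~ swc + I(swc^2))
  co <- unname(stats::coef(fit))
  a <- co[3]
  b <- co[2]
  cc <- co[1]
  vertex <- if (a > 0) -b / (2 * a) else NA_real_
  list(a = a, b = b, c = cc, vertex = vertex,
       r2 = summary(fit)$r.squared, n = length(f_net))
}

#' Assemble a model-ready table for mixed-model analysis
#'
#' Joins the cumulative covariates and transformed responses (via
#' [covariate_accumulate()] if not already present) and optionally
#' restricts to the uptake subset: communities in `exclude_communities`
#' dropped and only `f_net < 0` rows kept, to focus on oxidation-driven
#' net uptake without concurrent methanogenesis. Model fitting itself
#' (lme4 etc.) is deliberately left to the caller.
#'
#' @param table Campaign table; must contain `plot_id`, `community`,
#'   `treatment`, `occasion`, `f_net`, `t_soil`, `swc`.
#' @param uptake_only Apply the uptake filter (default FALSE).
#' @param exclude_communities Communities dropped under the uptake
#'   filter (default `"TT"`, the net-emitting community).
#' @param covariates Optional extra covariate columns that must be
#'   present; a missing one raises an error naming it.
#' @return The filtered, augmented data.frame.
#' @export
build_model_table <- function(table, uptake_only = FALSE,
                              exclude_communities = "TT",
                              covariates = character(0)) {
  required <- c("plot_id", "community", "treatment", "occasion",
                "f_net", "t_soil", "swc", covariates)
  missing_cols <- setdiff(required, names(table))
  if (length(missing_cols)) {
    stop("missing required column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  if (!all(c("cum_t_soil", "cum_swc") %in% names(table))) {
    table <- covariate_accumulate(table)
  }
  if (uptake_only) {
    table <- table[!(table$community %in% exclude_communities), ,
                   drop = FALSE]
    table <- table[!is.na(table$f_net) & table$f_net < 0, , drop = FALSE]
  }
  table
}
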
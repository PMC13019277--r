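test_that("arcsinh standardization is exact and flags degenerate groups", {
  z <- arcsinh_standardize(c(-1, 1))$z
  expect_equal(z, c(-1, 1) / sqrt(2), tolerance = 1e-12)

  deg <- arcsinh_standardize(c(0, 0, 0))
  expect_true(deg$flagged)
  expect_true(all(is.na(deg$z)))

  set.seed(2)
  for (i in 1:50) {
    x <- rnorm(sample(4:20, 1), sd = runif(1, 0.1, 10))
    st <- arcsinh_standardize(x)
    expect_equal(mean(st$z), 0, tolerance = 1e-12)
    expect_equal(sd(st$z), 1, tolerance = 1e-12)
  }
  expect_error(arcsinh_standardize(1), "at least 2")
})

test_that("Hedges g matches the worked pair and the brute-force oracle", {
  es <- hedges_g(c(1, 2, 3), c(2, 3, 4))
  expect_equal(es$d, 1)
  expect_equal(es$j, 0.8)
  expect_equal(es$g, 0.8)

  expect_equal(hedges_g(c(1, 2), c(1, 2))$g, 0)
  # antisymmetry under arm swap
  expect_equal(hedges_g(c(2, 3, 4), c(1, 2, 3))$g, -0.8)

  same <- hedges_g(c(1, 1, 1), c(1, 1, 1))
  expect_true(same$flagged)
  expect_true(is.na(same$g))

  set.seed(13)
  for (i in 1:1000) {
    a <- rnorm(sample(2:10, 1))
    b <- rnorm(sample(2:10, 1), mean = runif(1, -2, 2))
    expect_equal(hedges_g(a, b)$g, hedges_oracle(a, b), tolerance = 1e-12)
  }
})

test_that("effect sizes per occasion use pooled-standardized fluxes", {
  set.seed(40)
  tab <- expand.grid(plot = 1:5, treatment = c("Ambient", "OTC"),
                     occasion = as.Date(c("2017-06-05", "2017-06-19")),
                     community = "HD", stringsAsFactors = FALSE)
  tab$plot_id <- sprintf("%s-%d", tab$treatment, tab$plot)
  tab$f_net <- rnorm(nrow(tab), mean = ifelse(tab$treatment == "OTC",
                                              -2.4, -1), sd = 0.2)
  es <- effect_size_table(tab)
  expect_equal(nrow(es), 2)
  expect_true(all(es$g < 0))  # more uptake under warming: negative g
  expect_true(all(es$n_ambient == 5 & es$n_otc == 5))

  # manual recomputation for one occasion
  sub <- tab[tab$occasion == tab$occasion[1], ]
  z <- arcsinh_standardize(sub$f_net)$z
  manual <- hedges_g(z[sub$treatment == "Ambient"],
                     z[sub$treatment == "OTC"])$g
  expect_equal(es$g[es$occasion == sub$occasion[1]], manual,
               tolerance = 1e-12)
})

test_that("exact signed-rank p-values match full enumeration", {
  expect_equal(wilcoxon_signed_rank(c(1, 2, 3, 4, 5))$p, 0.0625)
  expect_equal(wilcoxon_signed_rank(c(-2, 2))$p, 1)

  set.seed(8)
  for (n in c(3, 5, 8, 10, 12)) {
    for (rep in 1:5) {
      x <- round(rnorm(n, 0.3), 1)  # rounding induces |x| ties
      x <- x[x != 0]
      if (length(x) < 2) next
      for (sides in c("two", "greater", "less")) {
        expect_equal(wilcoxon_signed_rank(x, sides = sides)$p,
                     wilcox_enum_oracle(x, sides = sides),
                     tolerance = 1e-12,
                     info = paste("n =", length(x), sides))
      }
    }
  }
  expect_error(wilcoxon_signed_rank(c(0, 0)), "undefined")
})

test_that("large-sample signed-rank approximation tracks the exact branch", {
  set.seed(9)
  x <- rnorm(25, 0.4)
  approx <- wilcoxon_signed_rank(x)            # n > 20: normal approx
  exact <- wilcoxon_signed_rank(x, exact_limit = 30)
  expect_false(approx$exact)
  expect_true(exact$exact)
  expect_equal(approx$p, exact$p, tolerance = 0.02)
})

make_pc_table <- function(amb_mean, otc_mean, n_occ = 4, sd = 0) {
  occ <- as.Date("2017-06-05") + 14 * (seq_len(n_occ) - 1)
  tab <- expand.grid(plot = 1:5, treatment = c("Ambient", "OTC"),
                     occasion = occ, stringsAsFactors = FALSE)
  tab$community <- "HD"
  tab$plot_id <- sprintf("%s-%d", tab$treatment, tab$plot)
  mu <- ifelse(tab$treatment == "Ambient", amb_mean, otc_mean)
  tab$f_net <- mu + if (sd > 0) rnorm(nrow(tab), 0, sd) else 0
  tab
}

test_that("percent change reproduces the worked uptake and emission cases", {
  same <- percent_change(make_pc_table(-1, -1))
  expect_equal(same$mean_pct, 0)

  up <- percent_change(make_pc_table(-1.0, -2.4))
  expect_equal(up$mean_pct, 140)
  expect_equal(up$se_pct, 0)
  expect_equal(up$direction, "uptake increase")

  down <- percent_change(make_pc_table(1.0, 0.088))
  expect_equal(down$mean_pct, 91.2, tolerance = 1e-9)
  expect_equal(down$direction, "emission reduction")
})

test_that("percent change excludes near-zero ambient occasions", {
  tab <- make_pc_table(-1.0, -2.4)
  # push one occasion's ambient mean under the floor
  occ1 <- tab$occasion == tab$occasion[1] & tab$treatment == "Ambient"
  tab$f_net[occ1] <- 0.01
  res <- percent_change(tab, floor = 0.05)
  expect_equal(length(res$excluded_occasions), 1)
  expect_equal(nrow(res$per_occasion), 3)
  expect_equal(res$mean_pct, 140)

  expect_error(percent_change(make_pc_table(-1, -2, n_occ = 2)),
               "3 occasions")
})

test_that("Q10 estimation inverts Arrhenius-generated rates", {
  r_gas <- 8.314
  ea <- log(2) * r_gas * 283.15 * 293.15 / 10  # Q10 = 2 at 10 C
  set.seed(77)
  t_soil <- runif(60, 2, 18)
  rate <- 1e8 * exp(-ea / (r_gas * (t_soil + 273.15)))

  noiseless <- q10_estimate(-rate, t_soil, t_ref = 10)
  expect_equal(noiseless$q10, 2, tolerance = 1e-9)
  expect_equal(noiseless$ea, ea, tolerance = 1e-6)
  expect_equal(noiseless$r2, 1, tolerance = 1e-12)
  expect_true(noiseless$significant)

  # temperature-independent rates: slope 0, Q10 exactly 1
  flat <- q10_estimate(rep(-1.5, 10) * exp(rnorm(10, 0, 1e-14)),
                       seq(3, 15, length.out = 10))
  expect_equal(flat$q10, 1, tolerance = 1e-6)

  expect_error(q10_estimate(c(-1, -2, 1, -1, -2), runif(5, 2, 18)),
               "uptake")
  expect_error(q10_estimate(rep(-1, 5), rep(10, 5) + runif(5, 0, 0.5)),
               "spanning")
})

test_that("quadratic SWC response recovers known coefficients", {
  swc <- seq(0.05, 0.95, length.out = 30)
  y <- 2.5 * swc^2 - 1.8 * swc + 0.1  # vertex at 0.36
  # exact data: summary.lm warns about the perfect fit, which is the point
  fit <- suppressWarnings(swc_response(y, swc))
  expect_equal(c(fit$a, fit$b, fit$c), c(2.5, -1.8, 0.1), tolerance = 1e-10)
  expect_equal(fit$vertex, 0.36, tolerance = 1e-10)

  lin <- suppressWarnings(swc_response(-1 + 0.5 * swc, swc))
  expect_equal(lin$a, 0, tolerance = 1e-10)
  expect_true(is.na(suppressWarnings(
    swc_response(-(swc - 0.5)^2, swc))$vertex))  # a < 0

  expect_error(swc_response(c(-1, -2, -1), c(0.1, 0.2, 0.3)), "at least 4")
  expect_error(swc_response(rep(-1, 6), rep(0.3, 6)), "rank")
})

test_that("uptake is maximal below 0.4 SWC in the default campaign", {
  sim <- simulate_campaign(scenario_config(seed = 21))
  tt <- sim$truth
  up <- tt[tt$f_net_true < 0, ]
  fit <- swc_response(up$f_net_true, up$swc)
  expect_gt(fit$a, 0)
  expect_lt(fit$vertex, 0.4)
})

test_that("model-table assembly filters and validates as specified", {
  sim <- simulate_campaign(scenario_config(seed = 3))
  tab <- merge(sim$table, sim$truth[c("plot_id", "occasion")],
               by = c("plot_id", "occasion"))
  tab <- tab[order(tab$plot_id, tab$occasion), ]

  full <- build_model_table(tab)
  expect_true(all(c("cum_t_soil", "cum_swc", "f_net_nsqrt",
                    "f_net_slog") %in% names(full)))
  expect_equal(nrow(full), nrow(tab))

  up <- build_model_table(tab, uptake_only = TRUE)
  expect_false("TT" %in% up$community)
  expect_true(all(up$f_net < 0))
  expect_equal(nrow(up),
               sum(tab$community != "TT" & !is.na(tab$f_net) &
                     tab$f_net < 0))

  expect_error(build_model_table(tab[setdiff(names(tab), "swc")]), "swc")
  expect_error(build_model_table(tab, covariates = "k_tbi"), "k_tbi")
})
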
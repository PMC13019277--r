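test_that("fit_slope handles exact, constant and deadband-pulse series", {
  t <- 0:239
  exact <- list(t = t, ch4 = 1.9 + 0.001 * t)
  f <- fit_slope(exact)
  expect_equal(f$slope, 0.001, tolerance = 1e-12)
  expect_equal(f$r2, 1)
  expect_equal(f$n_used, sum(t > 30))

  flat <- fit_slope(list(t = t, ch4 = rep(1.9, 240)))
  expect_equal(flat$slope, 0)
  expect_equal(flat$r2, 0)  # zero-variance convention

  # pulse confined to the deadband leaves the post-deadband fit untouched
  pulse <- 0.05 * exp(-t / 5) * (t <= 30)
  s <- list(t = t, ch4 = 2 - 1e-4 * t + pulse)
  expect_equal(fit_slope(s)$slope, -1e-4, tolerance = 1e-12)
  full_fit <- ols_oracle(t, s$ch4)
  expect_gt(abs(full_fit$slope - (-1e-4)), 1e-7)

  short <- fit_slope(list(t = 0:40, ch4 = rnorm(41)))
  expect_true("SHORT_SERIES" %in% short$flags)
  expect_true(is.na(short$slope))
})

test_that("fit_slope matches the closed-form OLS oracle on random series", {
  set.seed(101)
  for (i in 1:200) {
    n <- sample(60:240, 1)
    t <- sort(runif(n, 0, 300))
    t <- t[!duplicated(t)]
    y <- 2 + rnorm(1, 0, 1e-3) * t + rnorm(length(t), 0, 0.01)
    keep <- t > 30
    if (sum(keep) < 30) next
    f <- fit_slope(list(t = t, ch4 = y))
    o <- ols_oracle(t[keep], y[keep])
    expect_equal(f$slope, o$slope, tolerance = 1e-10)
    expect_lt(abs(f$r2 - o$r2), 1e-10)
    expect_equal(f$slope_se, o$se, tolerance = 1e-8)
  }
})

test_that("barometric pressure behaves as documented", {
  expect_equal(elevation_to_pressure(0, 10), 101325)
  expect_equal(elevation_to_pressure(981, 10) / 1000, 90.0, tolerance = 1e-3)
  expect_lt(elevation_to_pressure(2000, 10), elevation_to_pressure(981, 10))
  expect_error(elevation_to_pressure(6000, 10), "elevation")
})

test_that("ppm-to-flux conversion matches the hand-derived example", {
  expect_equal(ppm_slope_to_flux(0, 10, 90000, 0.25), 0)
  f <- ppm_slope_to_flux(-1e-4, 10, 90000, 0.25)
  expect_equal(f, -0.992, tolerance = 5e-4)
  expect_equal(f, flux_oracle(-1e-4, 10, 90000, 0.25), tolerance = 1e-12)
  # linear in headspace height
  expect_equal(ppm_slope_to_flux(-1e-4, 10, 90000, 0.50), 2 * f)
  expect_error(ppm_slope_to_flux(1, 10, 90000, 0), "h_eff")
  expect_error(ppm_slope_to_flux(1, 10, -1, 0.25), "pressure")
})

test_that("flux conversion and its inversion are mutually inverse", {
  set.seed(7)
  for (i in 1:50) {
    flux <- runif(1, -10, 10)
    temp <- runif(1, -5, 25)
    p <- runif(1, 80000, 102000)
    h <- runif(1, 0.1, 0.4)
    s <- flux_to_ppm_slope(flux, temp, p, h)
    expect_equal(ppm_slope_to_flux(s, temp, p, h), flux, tolerance = 1e-12)
  }
})

test_that("replicate averaging follows the arithmetic-mean convention", {
  est <- data.frame(flux = c(-1, -2, -3), r2 = c(0.9, 0.95, 0.85),
                    qc_flags = c("", "", ""))
  avg <- average_collar(est)
  expect_equal(avg$flux, -2)
  expect_equal(avg$r2, 0.9)

  one <- average_collar(est[2, ])
  expect_equal(one$flux, -2)
  expect_equal(one$n_reps, 1L)

  mix <- average_collar(data.frame(flux = c(-1, -1, 4), r2 = rep(0.9, 3),
                                   qc_flags = c("", "IMPUTED", "")))
  expect_equal(mix$flux, 2 / 3, tolerance = 1e-12)
  expect_equal(mix$qc_flags, "IMPUTED")

  none <- average_collar(est[0, ])
  expect_true(is.na(none$flux))
  expect_error(average_collar(rbind(est, est)), "at most 3")
})

make_qc_table <- function(flux, r2, community = "HD") {
  data.frame(plot_id = sprintf("p%02d", seq_along(flux)),
             community = community, treatment = "Ambient",
             occasion = as.Date("2017-06-05"), f_net = flux, r2 = r2,
             stringsAsFactors = FALSE)
}

test_that("qc screening retains high-R2 rows and removes 3-sigma outliers", {
  clean <- make_qc_table(c(-1, -1.1, -0.9, -1, -1.05), rep(0.95, 5))
  res <- qc_filter(clean)
  expect_equal(res$retained, clean)
  expect_equal(nrow(res$rejected), 0)

  # worked example: the +9 low-R2 row is a gross outlier of its group
  tab <- make_qc_table(c(-1, -1.1, -0.9, -1, 9), c(0.9, 0.9, 0.9, 0.9, 0.3))
  res <- qc_filter(tab)
  expect_equal(res$rejected$f_net, 9)
  expect_match(res$rejected$qc_flags, "OUTLIER_3SIGMA")
  expect_equal(sort(res$retained$f_net), sort(tab$f_net[1:4]))

  # low R2 alone is not grounds for removal
  tab2 <- make_qc_table(c(-1, -1.1, -0.9, -1, -0.95),
                        c(0.9, 0.9, 0.9, 0.9, 0.3))
  expect_equal(nrow(qc_filter(tab2)$rejected), 0)

  # high-R2 outliers are always retained
  tab3 <- make_qc_table(c(-1, -1.1, -0.9, -1, 9), rep(0.95, 5))
  expect_equal(nrow(qc_filter(tab3)$rejected), 0)

  tiny <- make_qc_table(c(-1, 5), c(0.3, 0.3))
  expect_warning(res <- qc_filter(tiny), "fewer than 3")
  expect_equal(nrow(res$retained), 2)
})

test_that("qc screening is idempotent", {
  tab <- make_qc_table(c(-1, -1.1, -0.9, -1, 9), c(0.9, 0.9, 0.9, 0.9, 0.3))
  first <- qc_filter(tab)$retained
  second <- qc_filter(first)$retained
  expect_equal(second, first)

  set.seed(11)
  big <- make_qc_table(rnorm(40, -1, 0.3), runif(40, 0.2, 1))
  first <- qc_filter(big)$retained
  expect_equal(qc_filter(first)$retained, first)
})

test_that("imputation fills 1-2 gaps with the group mean and nothing else", {
  tab <- data.frame(plot_id = sprintf("p%d", 1:5), community = "HD",
                    treatment = "Ambient", occasion = as.Date("2017-06-05"),
                    f_net = c(-1, -2, -3, NA, NA), stringsAsFactors = FALSE)
  out <- impute_missing(tab)
  expect_equal(out$f_net[4:5], c(-2, -2))
  expect_equal(out$qc_flags[4:5], c("IMPUTED", "IMPUTED"))
  expect_equal(out$f_net[1:3], tab$f_net[1:3])  # untouched

  tab3 <- tab
  tab3$f_net[3] <- NA  # three missing: left alone
  out3 <- impute_missing(tab3)
  expect_equal(sum(is.na(out3$f_net)), 3)

  complete <- tab
  complete$f_net <- -(1:5)
  expect_equal(impute_missing(complete)$f_net, complete$f_net)
})

test_that("imputation preserves the group mean", {
  set.seed(4)
  for (i in 1:20) {
    vals <- rnorm(5)
    vals[sample(5, sample(1:2, 1))] <- NA
    tab <- data.frame(plot_id = sprintf("p%d", 1:5), community = "MD",
                      treatment = "OTC", occasion = as.Date("2018-07-01"),
                      f_net = vals, stringsAsFactors = FALSE)
    out <- impute_missing(tab)
    expect_false(anyNA(out$f_net))
    expect_equal(mean(out$f_net), mean(vals, na.rm = TRUE),
                 tolerance = 1e-12)
  }
})

test_that("seasonal accumulation and response transforms", {
  tab <- data.frame(plot_id = "p1", community = "HD", treatment = "Ambient",
                    occasion = as.Date(c("2017-06-05", "2017-06-19",
                                         "2017-07-03")),
                    f_net = c(-4, 0, 2), t_soil = c(5, 6, 7),
                    swc = c(0.1, 0.2, 0.3), stringsAsFactors = FALSE)
  out <- covariate_accumulate(tab)
  expect_equal(out$cum_t_soil, c(5, 11, 18))
  expect_equal(out$cum_swc, c(0.1, 0.3, 0.6))
  expect_equal(out$f_net_nsqrt, c(-2, 0, NA_real_))
  expect_equal(out$f_net_slog, sign(tab$f_net) * log1p(abs(tab$f_net)))

  single <- covariate_accumulate(tab[1, ])
  expect_equal(single$cum_t_soil, single$t_soil)

  shuffled <- tab[c(3, 1, 2), ]
  expect_error(covariate_accumulate(shuffled), "ordered")
})
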
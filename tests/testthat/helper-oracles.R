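# Independent oracles the implementation is checked against.
# These deliberately use different code paths than the package.

# reference OLS through R's QR-based fitter — an independent code path
# from the package's centered-sums arithmetic
ols_oracle <- function(t, y) {
  fit <- stats::lm(y ~ t)
  sm <- summary(fit)
  list(slope = unname(coef(fit)[2]),
       r2 = if (var(y) > 0) sm$r.squared else 0,
       se = sm$coefficients[2, 2])
}

# signed-rank p by explicit enumeration of all 2^n sign assignments
wilcox_enum_oracle <- function(x, sides = "two") {
  d <- x[x != 0]
  n <- length(d)
  r <- rank(abs(d))
  w_obs <- sum(r[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(FALSE, TRUE)), n)))
  w_all <- apply(signs, 1, function(s) sum(r[s]))
  p_le <- mean(w_all <= w_obs)
  p_ge <- mean(w_all >= w_obs)
  switch(sides,
         two = min(1, 2 * min(p_le, p_ge)),
         greater = p_ge,
         less = p_le)
}

# direct SMD recomputation
hedges_oracle <- function(a, b) {
  n1 <- length(a); n2 <- length(b)
  sp <- sqrt((sum((a - mean(a))^2) + sum((b - mean(b))^2)) / (n1 + n2 - 2))
  d <- (mean(b) - mean(a)) / sp
  (1 - 3 / (4 * (n1 + n2 - 2) - 1)) * d
}

# reference unit conversion, written out from scratch
flux_oracle <- function(slope_ppm_s, temp_c, pressure_pa, h_m) {
  mol_per_m3 <- pressure_pa / (8.314 * (temp_c + 273.15))
  mol_ch4_per_m2_s <- slope_ppm_s * 1e-6 * mol_per_m3 * h_m
  mol_ch4_per_m2_s * 12.011 * 1000 * 86400
}
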
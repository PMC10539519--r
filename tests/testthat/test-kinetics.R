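test_that("initial rates convert slopes with the NADH extinction", {
  tr <- make_linear_trace(6.220e-3)
  ir <- initial_rate(tr$time_s, tr$a340)
  expect_equal(ir$rate, 1.0e-6, tolerance = 1e-9)
  # trace with late curvature: early-segment rate matches the generator
  tr2 <- make_linear_trace(6.220e-3, curvature = 100)
  ir2 <- initial_rate(tr2$time_s, tr2$a340)
  expect_equal(ir2$rate, 1.0e-6, tolerance = 0.01)
  expect_lt(ir2$n_points, length(tr2$time_s))
  # flat trace
  tr0 <- make_linear_trace(0)
  expect_equal(initial_rate(tr0$time_s, tr0$a340)$rate, 0)
  # path length scales the conversion
  expect_equal(initial_rate(tr$time_s, tr$a340, path = 0.5)$rate, 2.0e-6,
               tolerance = 1e-9)
})

test_that("no linear phase raises a diagnostic error", {
  set.seed(1)
  t <- seq(0, 240, 12)
  y <- sin(t / 15) + rnorm(length(t), 0, 0.5)
  expect_error(initial_rate(t, y), "no linear phase")
})

test_that("Michaelis-Menten parameters are recovered from noiseless data", {
  d <- make_kinetics_series(kcat = 9.0, km = 0.27, enzyme_conc = 1e-8)
  fit <- fit_michaelis_menten(d)
  expect_equal(fit$kcat, 9.0, tolerance = 1e-6)
  expect_equal(fit$km, 0.27, tolerance = 1e-6)
  expect_equal(fit$kcat_over_km, 9.0 / 0.27e-3, tolerance = 1e-6)
  # saturation: v0/vmax -> 1 for [S] >> KM
  expect_equal(predict(fit, 270) / fit$vmax, 1, tolerance = 1e-2)
  # duplicating the dataset leaves the estimates unchanged
  d2 <- rate_dataset(rep(d$substrate_conc, 2), rep(d$v0, 2),
                     enzyme_conc = d$enzyme_conc)
  fit2 <- fit_michaelis_menten(d2)
  expect_equal(coef(fit2)[c("kcat", "km")], coef(fit)[c("kcat", "km")],
               tolerance = 1e-8)
})

test_that("substrate inhibition is recovered and peaks at sqrt(KM*Ki)", {
  d <- make_kinetics_series(kcat = 1, km = 0.5, ki = 5, enzyme_conc = 1,
                            concs = exp(seq(log(0.01), log(40),
                                            length.out = 14)))
  fit <- fit_substrate_inhibition(d)
  expect_equal(fit$vmax, 1, tolerance = 1e-6)
  expect_equal(fit$km, 0.5, tolerance = 1e-6)
  expect_equal(fit$ki, 5, tolerance = 1e-6)
  # calculus oracle: dv/dS = 0 at sqrt(KM*Ki) on the fitted curve
  s_star <- optimize(function(s) -predict(fit, s), c(0.01, 40))$minimum
  expect_equal(s_star, sqrt(fit$km * fit$ki), tolerance = 1e-3)
  # generated curve is non-monotone
  expect_lt(d$v0[length(d$v0)], max(d$v0))
})

test_that("substrate-inhibition fit nests Michaelis-Menten", {
  d <- make_kinetics_series(kcat = 9, km = 0.27, enzyme_conc = 1e-8)
  mm <- fit_michaelis_menten(d)
  # huge Ki in the generator: the SI fit reproduces the MM parameters
  dsi <- make_kinetics_series(kcat = 9, km = 0.27, ki = 1e9,
                              enzyme_conc = 1e-8)
  expect_warning(si <- fit_substrate_inhibition(dsi), "no post-peak")
  expect_equal(si$kcat, mm$kcat, tolerance = 1e-3)
  expect_equal(si$km, mm$km, tolerance = 1e-3)
})

test_that("seeded noisy replicates recover parameters within 5% median", {
  n_rep <- 200
  err_mm <- matrix(NA_real_, n_rep, 2)
  err_si <- matrix(NA_real_, n_rep, 3)
  for (r in seq_len(n_rep)) {
    d <- make_kinetics_series(kcat = 9, km = 0.27, enzyme_conc = 1e-8,
                              noise = 0.02, seed = 500 + r)
    f <- fit_michaelis_menten(d)
    err_mm[r, ] <- abs(c(f$kcat - 9, f$km - 0.27) / c(9, 0.27))
    d2 <- make_kinetics_series(kcat = 1, km = 0.5, ki = 5, enzyme_conc = 1,
                               concs = exp(seq(log(0.01), log(40),
                                               length.out = 14)),
                               noise = 0.02, seed = 9000 + r)
    f2 <- suppressWarnings(fit_substrate_inhibition(d2))
    err_si[r, ] <- abs(c(f2$vmax - 1, f2$km - 0.5, f2$ki - 5) /
                         c(1, 0.5, 5))
  }
  expect_lt(max(apply(err_mm, 2, median)), 0.05)
  expect_lt(max(apply(err_si, 2, median)), 0.05)
})

test_that("the linear-regime estimator matches kcat/KM at low substrate", {
  # exactly linear data through the origin
  d <- rate_dataset(c(0.001, 0.002, 0.004), 33000 * 1e-8 *
                      c(0.001, 0.002, 0.004) * 1e-3, enzyme_conc = 1e-8)
  expect_equal(efficiency_linear_regime(d), 33000, tolerance = 1e-9)
  # full MM data restricted to [S] <= KM/20
  km <- 0.27
  d2 <- make_kinetics_series(kcat = 9, km = km, enzyme_conc = 1e-8,
                             concs = seq(km / 100, km / 20,
                                         length.out = 6))
  eff <- efficiency_linear_regime(d2)
  expect_equal(eff, 9 / (km * 1e-3), tolerance = 0.05)
  # guards
  d3 <- d; d3$enzyme_conc <- 0
  expect_error(efficiency_linear_regime(d3), "> 0")
  expect_error(efficiency_linear_regime(d, max_conc = 0.0015), "at least 3")
})

test_that("selectivity is the printed efficiency ratio and is reciprocal", {
  sel <- selectivity_metrics(33000, 22000)
  expect_equal(sel$selectivity, 1.5, tolerance = 1e-12)
  v <- selectivity_metrics(41000, 2200)
  expect_equal(signif(v$selectivity, 2), 19)
  ab <- selectivity_metrics(1234, 777)$selectivity
  ba <- selectivity_metrics(777, 1234)$selectivity
  expect_equal(ab * ba, 1, tolerance = 1e-12)
  eq <- selectivity_metrics(5, 5, reference = c(phe = 5, asp = 5))
  expect_equal(eq$selectivity, 1)
  expect_equal(eq$fold_switch, 1)
  expect_error(selectivity_metrics(0, 5), "> 0")
})
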
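test_that("Lorentzian area matches numerical integration", {
  pk <- lorentzian_peak(center = -61.6, hwhm = 0.08, amplitude = 40)
  num <- integrate(function(x) confdesign:::lorentzian_curve(x, pk$center,
                                                             pk$hwhm,
                                                             pk$amplitude),
                   -Inf, Inf, rel.tol = 1e-10)$value
  expect_equal(num, pk$area, tolerance = 1e-3)
  # the slow 1/x^2 tails hold ~1.3% of the area beyond +/-50 half-widths
  num50 <- integrate(function(x) confdesign:::lorentzian_curve(x, pk$center,
                                                               pk$hwhm,
                                                               pk$amplitude),
                     pk$center - 50 * pk$hwhm, pk$center + 50 * pk$hwhm,
                     rel.tol = 1e-10)$value
  expect_equal(num50 / pk$area, 2 / pi * atan(50), tolerance = 1e-6)
  expect_error(lorentzian_peak(0, -1, 1), "hwhm")
  expect_error(lorentzian_peak(0, 1, -1), "amplitude")
})

test_that("noiseless two-Lorentzian spectra are deconvoluted exactly", {
  vh <- make_vant_hoff_series(spectra = TRUE)
  s <- vh$spectra[[3]]
  dec <- deconvolute_two_lorentzians(s)
  centers <- sort(vapply(dec$peaks, `[[`, numeric(1), "center"))
  expect_equal(centers, c(-61.6, -60.4), tolerance = 1e-6)
  expect_equal(vapply(dec$peaks, `[[`, numeric(1), "hwhm"),
               c(0.08, 0.08), tolerance = 1e-5)
  expect_lt(dec$residual_norm, 1e-6)
  # populations recover the generating equilibrium constant
  pp <- populations_from_peaks(dec$peaks[[1]], dec$peaks[[2]])
  expect_equal(pp$keq, vh$series$keq[3], tolerance = 1e-4)
  expect_equal(pp$p_closed + pp$p_open, 1, tolerance = 1e-12)
})

test_that("single-peak input flags a degenerate second component", {
  x <- seq(-63, -59, length.out = 400)
  y <- confdesign:::lorentzian_curve(x, -61, 0.1, 50)
  dec <- deconvolute_two_lorentzians(spectrum1d(x, y, 298))
  expect_true(dec$degenerate)
})

test_that("two Lorentzians never fit worse than one (nested models)", {
  vh <- make_vant_hoff_series(spectra = TRUE, spectrum_noise = 0.01)
  s <- vh$spectra[[1]]
  dec <- deconvolute_two_lorentzians(s)
  one <- minpack.lm::nlsLM(
    y ~ exp(la) * exp(lw)^2 / ((x - m)^2 + exp(lw)^2) + b0,
    data = data.frame(x = s$ppm, y = s$intensity),
    start = list(m = s$ppm[which.max(s$intensity)], la = log(max(s$intensity)),
                 lw = log(0.1), b0 = 0))
  expect_lte(dec$residual_norm, sqrt(sum(residuals(one)^2)) + 1e-9)
})

test_that("population ratios behave as area ratios", {
  a <- lorentzian_peak(-61.6, 0.1, 30)
  b <- lorentzian_peak(-60.4, 0.1, 10)
  pp <- populations_from_peaks(a, b)
  expect_equal(pp$keq, 3, tolerance = 1e-12)       # upfield = closed
  pp2 <- populations_from_peaks(a, b, closed = "downfield")
  expect_equal(pp2$keq, 1 / 3, tolerance = 1e-12)
  eq <- populations_from_peaks(lorentzian_peak(0, 1, 1),
                               lorentzian_peak(5, 1, 1))
  expect_equal(eq$keq, 1, tolerance = 1e-12)
})

test_that("noiseless van't Hoff data are recovered to 1e-6 relative", {
  truth <- c(dh_ref = -9.9, ds_ref = -0.032, dcp = 0.972)
  vh <- make_vant_hoff_series(truth[1], truth[2], truth[3],
                              temperatures = seq(278, 308, 5))
  fit <- fit_vant_hoff(vh$series$temperature, vh$series$keq)
  expect_equal(coef(fit), truth, tolerance = 1e-6)
  # dCp = 0 data: the linear fit slope equals -dH/R exactly
  vh0 <- make_vant_hoff_series(-8, -0.02, 0)
  lin <- fit_vant_hoff(vh0$series$temperature, vh0$series$keq,
                       model = "linear")
  expect_equal(lin$dh_ref, -8, tolerance = 1e-9)
  expect_equal(lin$ds_ref, -0.02, tolerance = 1e-9)
  expect_equal(lin$dcp, 0)
  # nonlinear fit never has larger residuals on curved data (nesting)
  fitl <- fit_vant_hoff(vh$series$temperature, vh$series$keq,
                        model = "linear")
  expect_lte(sum(residuals(fit$fit)^2), sum(residuals(fitl$fit)^2) + 1e-12)
})

test_that("fit input validation and temperature units work", {
  expect_error(fit_vant_hoff(c(278, 288, 298), c(1, 2, 3)),
               "at least 4")
  vh <- make_vant_hoff_series()
  fitC <- fit_vant_hoff(vh$series$temperature - 273.15, vh$series$keq,
                        celsius = TRUE)
  expect_equal(fitC$dh_ref, -9.9, tolerance = 1e-6)
})

test_that("Gibbs energy matches -RT ln Keq and its closed form", {
  p <- list(dh_ref = -9.9, ds_ref = -0.032, dcp = 0.972, t_ref = 298)
  # at T_ref: dH - T dS
  expect_equal(gibbs_at_temperature(p, 298),
               p$dh_ref - 298 * p$ds_ref, tolerance = 1e-12)
  # identity with the equilibrium-constant form at arbitrary T
  R <- 1.9872e-3
  for (T in c(278, 285, 298, 303, 310)) {
    k <- keq_from_thermo(T, p$dh_ref, p$ds_ref, p$dcp, p$t_ref)
    expect_equal(gibbs_at_temperature(p, T), -R * T * log(k),
                 tolerance = 1e-9)
  }
})

test_that("noisy round trips land within 95% confidence bounds", {
  # 1% multiplicative noise on Keq; joint 95%-CI coverage over replicates
  truth <- c(dh_ref = -9.9, ds_ref = -0.032, dcp = 0.972)
  n_rep <- 500
  n_cover <- 0
  for (rep in seq_len(n_rep)) {
    vh <- make_vant_hoff_series(truth[1], truth[2], truth[3],
                                noise = 0.01, seed = 10000 + rep)
    fit <- fit_vant_hoff(vh$series$temperature, vh$series$keq)
    est <- coef(fit)
    ok <- abs(est - truth) <= fit$ci95[names(est)]
    if (all(ok)) n_cover <- n_cover + 1
  }
  expect_gte(n_cover / n_rep, 0.90)
})
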
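#' Lorentzian peak
#'
#' `L(x) = amplitude * hwhm^2 / ((x - center)^2 + hwhm^2)`; the area
#' under the curve is `pi * amplitude * hwhm`.
#'
#' @param center peak position, ppm.
#' @param hwhm half width at half maximum, ppm (> 0).
#' @param amplitude peak height, intensity units (>= 0).
#' @return object of class `LorentzianPeak` with an `area` field.
#' @export
lorentzian_peak <- function(center, hwhm, amplitude) {
  if (hwhm <= 0) stop("hwhm must be > 0")
  if (amplitude < 0) stop("amplitude must be >= 0")
  structure(list(center = center, hwhm = hwhm, amplitude = amplitude,
                 area = pi * amplitude * hwhm), class = "LorentzianPeak")
}

lorentzian_curve <- function(x, center, hwhm, amplitude)
  amplitude * hwhm^2 / ((x - center)^2 + hwhm^2)

#' 1-D spectrum container
#'
#' @param ppm chemical-shift axis (strictly monotone).
#' @param intensity intensities (finite).
#' @param temperature kelvin.
#' @return object of class `Spectrum1D`.
#' @export
spectrum1d <- function(ppm, intensity, temperature) {
  d <- diff(ppm)
  if (!(all(d > 0) || all(d < 0))) stop("ppm axis must be strictly monotone")
  if (!all(is.finite(intensity))) stop("non-finite intensities")
  structure(list(ppm = as.numeric(ppm), intensity = as.numeric(intensity),
                 temperature = temperature), class = "Spectrum1D")
}

#' Two-Lorentzian deconvolution of a 1-D spectrum
#'
#' Nonlinear least-squares fit of two Lorentzian peaks plus a constant
#' baseline. Widths and amplitudes are fitted on a log scale, so
#' negative values are impossible by construction. Peaks are returned
#' ordered by center, descending (downfield first).
#'
#' @param s [spectrum1d()].
#' @param init optional list with `centers` (length 2); by default the
#'   two highest well-separated local maxima are used.
#' @return list with `peaks` (list of two [lorentzian_peak()], ordered
#'   by center descending), `baseline`, `residual_norm`, `degenerate`
#'   flag, `fit` (the underlying `nls.lm` object).
#' @export
deconvolute_two_lorentzians <- function(s, init = NULL) {
  x <- s$ppm; y <- s$intensity
  if (length(x) < 20) stop("need at least 20 axis points")
  if (is.null(init)) init <- list(centers = pick_two_peaks(x, y))
  c1 <- init$centers[1]; c2 <- init$centers[2]
  span <- abs(diff(range(x)))
  w0 <- log(span / 50)
  a0 <- log(max(max(y) * 0.8, 1e-8))
  model_fn <- function(p) {
    exp(p[["la1"]]) * exp(p[["lw1"]])^2 /
      ((x - p[["m1"]])^2 + exp(p[["lw1"]])^2) +
    exp(p[["la2"]]) * exp(p[["lw2"]])^2 /
      ((x - p[["m2"]])^2 + exp(p[["lw2"]])^2) + p[["b0"]]
  }
  start <- c(m1 = c1, la1 = a0, lw1 = w0, m2 = c2, la2 = a0, lw2 = w0,
             b0 = 0)
  # Levenberg-Marquardt on the residuals; the direct nls.lm interface
  # tolerates a degenerate (vanishing) second component, which a
  # one-peak spectrum legitimately produces.
  fit <- minpack.lm::nls.lm(par = start, fn = function(p) y - model_fn(p),
                            control = minpack.lm::nls.lm.control(
                              maxiter = 500))
  if (fit$info == 0 || fit$info == 9)
    stop("two-Lorentzian fit failed to converge: ", fit$message)
  p <- fit$par
  pk <- list(lorentzian_peak(p[["m1"]], exp(p[["lw1"]]), exp(p[["la1"]])),
             lorentzian_peak(p[["m2"]], exp(p[["lw2"]]), exp(p[["la2"]])))
  ord <- order(-vapply(pk, `[[`, numeric(1), "center"))
  pk <- pk[ord]
  res <- sqrt(fit$deviance)
  degenerate <- min(vapply(pk, `[[`, numeric(1), "area")) <
    0.01 * max(vapply(pk, `[[`, numeric(1), "area"))
  list(peaks = pk, baseline = unname(p["b0"]), residual_norm = res,
       degenerate = degenerate, fit = fit)
}

# two largest local maxima separated by at least 5% of the axis span
pick_two_peaks <- function(x, y) {
  n <- length(y)
  loc <- which(y[2:(n - 1)] >= y[1:(n - 2)] & y[2:(n - 1)] >= y[3:n]) + 1
  if (length(loc) == 0) loc <- which.max(y)
  loc <- loc[order(-y[loc])]
  c1 <- x[loc[1]]
  minsep <- 0.05 * abs(diff(range(x)))
  c2 <- NA
  for (l in loc[-1]) if (abs(x[l] - c1) >= minsep) { c2 <- x[l]; break }
  if (is.na(c2)) c2 <- c1 + minsep * 2
  c(c1, c2)
}

#' Populations and equilibrium constant from two fitted peaks
#'
#' Integrated areas give the relative populations of the two
#' conformational states; their ratio is the equilibrium constant. The
#' closed-state peak is identified by configuration (default: the more
#' upfield peak, i.e. lower ppm), never inferred silently.
#'
#' @param peak_a,peak_b [lorentzian_peak()] objects.
#' @param closed `"upfield"` (default) or `"downfield"`.
#' @return list with `p_closed`, `p_open`, `keq`
#'   (`= p_closed / p_open`).
#' @export
populations_from_peaks <- function(peak_a, peak_b,
                                   closed = c("upfield", "downfield")) {
  closed <- match.arg(closed)
  areas <- c(peak_a$area, peak_b$area)
  if (sum(areas) <= 0) stop("zero total area")
  centers <- c(peak_a$center, peak_b$center)
  icl <- if (closed == "upfield") which.min(centers) else which.max(centers)
  p <- areas / sum(areas)
  list(p_closed = p[icl], p_open = p[-icl][1],
       keq = p[icl] / p[-icl][1])
}

#' Equilibrium constant from two-state thermodynamic parameters
#'
#' Forward form of the nonlinear van't Hoff relation:
#' `ln Keq = -dH_ref/R * (1/T) + dS_ref/R
#'           - dCp/R * ((T - T_ref)/T + ln(T_ref/T))`.
#'
#' @param temperature kelvin (vectorized).
#' @param dh_ref kcal/mol at `t_ref`.
#' @param ds_ref kcal/mol/K at `t_ref`.
#' @param dcp kcal/mol/K (0 recovers the linear van't Hoff form).
#' @param t_ref reference temperature, kelvin (default 298).
#' @return Keq values.
#' @export
keq_from_thermo <- function(temperature, dh_ref, ds_ref, dcp = 0,
                            t_ref = 298) {
  stopifnot(all(temperature > 0), t_ref > 0)
  R <- GAS_CONSTANT_KCAL
  lnk <- -dh_ref / R / temperature + ds_ref / R -
    dcp / R * ((temperature - t_ref) / temperature +
                 log(t_ref / temperature))
  exp(lnk)
}

#' Van't Hoff fit of temperature-dependent equilibrium constants
#'
#' Least-squares fit in `ln Keq` space. The nonlinear (dCp != 0) van't
#' Hoff relation is linear in the parameters (dH_ref, dS_ref, dCp) once
#' expressed in its basis functions, so the fit is an exact linear
#' least-squares solve; the linear model simply drops the dCp term.
#' Uncertainties come from the fit covariance.
#'
#' @param temperature kelvin (or degrees Celsius if `celsius = TRUE`).
#' @param keq equilibrium constants (> 0), direction of closing.
#' @param t_ref reference temperature, kelvin (default 298).
#' @param model `"nonlinear"` (default) or `"linear"`.
#' @param celsius logical; interpret `temperature` as Celsius.
#' @return object of class `vant_hoff_fit`: list with `dh_ref`, `ds_ref`,
#'   `dcp`, `se` (named standard errors), `ci95` (95% confidence
#'   half-widths, the reported uncertainties), `df_residual`, `t_ref`,
#'   `model`, `observations`, `fit` (the lm object).
#' @export
fit_vant_hoff <- function(temperature, keq, t_ref = 298,
                          model = c("nonlinear", "linear"),
                          celsius = FALSE) {
  model <- match.arg(model)
  if (celsius) temperature <- temperature + 273.15
  stopifnot(all(temperature > 0), all(keq > 0))
  npar <- if (model == "nonlinear") 3 else 2
  if (length(unique(temperature)) < npar + 1)
    stop("need at least ", npar + 1, " distinct temperatures for the ",
         model, " fit")
  R <- GAS_CONSTANT_KCAL
  lnk <- log(keq)
  x1 <- 1 / temperature
  x2 <- (temperature - t_ref) / temperature + log(t_ref / temperature)
  fit <- if (model == "nonlinear") lm(lnk ~ x1 + x2) else lm(lnk ~ x1)
  cf <- coef(fit)
  if (anyNA(cf)) stop("singular design: temperatures do not identify the fit")
  # noiseless inputs fit perfectly; the zero-variance warning is benign
  se_raw <- sqrt(diag(suppressWarnings(vcov(fit))))
  dh <- -R * cf[["x1"]]
  ds <- R * cf[["(Intercept)"]]
  dcp <- if (model == "nonlinear") -R * cf[["x2"]] else 0
  se <- c(dh_ref = R * se_raw[["x1"]],
          ds_ref = R * se_raw[["(Intercept)"]],
          dcp = if (model == "nonlinear") R * se_raw[["x2"]] else NA_real_)
  dfres <- stats::df.residual(fit)
  # reported uncertainty: half-width of the 95% confidence interval
  ci95 <- stats::qt(0.975, dfres) * se
  structure(list(dh_ref = dh, ds_ref = ds, dcp = dcp, se = se,
                 ci95 = ci95, df_residual = dfres,
                 t_ref = t_ref, model = model,
                 observations = data.frame(temperature = temperature,
                                           keq = keq),
                 fit = fit),
            class = "vant_hoff_fit")
}

#' @export
print.vant_hoff_fit <- function(x, ...) {
  cat(sprintf("Two-state van't Hoff fit (%s, T_ref = %g K)\n", x$model,
              x$t_ref))
  cat(sprintf("  dH_ref = %.4g +/- %.2g kcal/mol\n", x$dh_ref,
              x$se["dh_ref"]))
  cat(sprintf("  dS_ref = %.4g +/- %.2g kcal/mol/K\n", x$ds_ref,
              x$se["ds_ref"]))
  if (x$model == "nonlinear")
    cat(sprintf("  dCp    = %.4g +/- %.2g kcal/mol/K\n", x$dcp,
                x$se["dcp"]))
  invisible(x)
}

#' @export
coef.vant_hoff_fit <- function(object, ...)
  c(dh_ref = object$dh_ref, ds_ref = object$ds_ref, dcp = object$dcp)

#' @export
predict.vant_hoff_fit <- function(object, temperature, ...)
  keq_from_thermo(temperature, object$dh_ref, object$ds_ref, object$dcp,
                  object$t_ref)

#' Gibbs free energy of closing at a temperature
#'
#' `dG(T) = dH_ref + dCp (T - T_ref) - T [dS_ref + dCp ln(T/T_ref)]`,
#' algebraically identical to `-RT ln Keq` with Keq from the nonlinear
#' van't Hoff relation.
#'
#' @param x a `vant_hoff_fit` or a list/vector with `dh_ref`, `ds_ref`,
#'   `dcp`, `t_ref`.
#' @param temperature kelvin (vectorized).
#' @return kcal/mol (direction of closing).
#' @export
gibbs_at_temperature <- function(x, temperature) {
  stopifnot(all(temperature > 0))
  p <- as.list(x)[c("dh_ref", "ds_ref", "dcp", "t_ref")]
  if (is.null(p$dcp)) p$dcp <- 0
  if (is.null(p$t_ref)) p$t_ref <- 298
  with(p, dh_ref + dcp * (temperature - t_ref) -
         temperature * (ds_ref + dcp * log(temperature / t_ref)))
}
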
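#' Initial rate from an absorbance trace
#'
#' Detects the linear phase of an A340 kinetic trace (expanding window
#' from the start, keeping the longest window whose linear fit has
#' R^2 >= `r2_threshold`) and converts its slope to a molar rate via
#' the NADH extinction coefficient and the optical path length. The
#' slope itself is evaluated over the early half of the detected phase:
#' R^2 is a weak curvature detector, so the tail of the detected window
#' can already bend and would otherwise bias the slope low.
#'
#' @param time_s time points, seconds.
#' @param a340 absorbance at 340 nm.
#' @param eps extinction coefficient, 1/(M cm); default 6220 (NADH).
#' @param path optical path length, cm (default 1).
#' @param r2_threshold linear-phase R^2 threshold (default 0.995).
#' @param min_points minimum points in the linear phase (default 5).
#' @return list with `rate` (M/s), `n_points` (linear-phase length),
#'   `r_squared`, `slope` (absorbance/s).
#' @export
initial_rate <- function(time_s, a340, eps = 6220, path = 1,
                         r2_threshold = 0.995, min_points = 5) {
  stopifnot(length(time_s) == length(a340), length(time_s) >= min_points)
  n <- length(time_s)
  best <- NULL
  for (end in seq(min_points, n)) {
    tt <- time_s[1:end]; yy <- a340[1:end]
    f <- lm(yy ~ tt)
    ss_res <- sum(residuals(f)^2)
    ss_tot <- sum((yy - mean(yy))^2)
    r2 <- if (ss_tot < 1e-20) 1 else 1 - ss_res / ss_tot
    if (r2 >= r2_threshold)
      best <- list(end = end, slope = coef(f)[["tt"]], r2 = r2)
  }
  if (is.null(best))
    stop("no linear phase found (R^2 threshold ", r2_threshold,
         ", minimum ", min_points, " points)")
  nfit <- max(min_points, ceiling(best$end / 2))
  f <- lm(a340[1:nfit] ~ time_s[1:nfit])
  slope <- coef(f)[[2]]
  list(rate = slope / (eps * path), n_points = best$end,
       n_slope_points = nfit, r_squared = best$r2, slope = slope)
}

#' Rate dataset
#'
#' @param substrate_conc substrate concentrations, mM.
#' @param v0 initial rates (M/s, or 1/s if normalized by enzyme
#'   concentration).
#' @param enzyme_conc total enzyme concentration, M.
#' @param substrate substrate identity label.
#' @return object of class `RateDataset`.
#' @export
rate_dataset <- function(substrate_conc, v0, enzyme_conc = 1,
                         substrate = "substrate") {
  stopifnot(length(substrate_conc) == length(v0),
            all(substrate_conc >= 0), all(is.finite(v0)))
  structure(list(substrate_conc = as.numeric(substrate_conc),
                 v0 = as.numeric(v0), enzyme_conc = enzyme_conc,
                 substrate = substrate), class = "RateDataset")
}

#' Michaelis-Menten fit
#'
#' Nonlinear least squares of `v0 = vmax [S] / (KM + [S])`;
#' `kcat = vmax / [E0]` and `kcat/KM` is derived with first-order error
#' propagation from the fit covariance.
#'
#' @param d [rate_dataset()].
#' @return object of class `kinetics_fit` with `kcat` (1/s), `km` (mM),
#'   `ki` (NA), `kcat_over_km` (1/(M s)), `se` (standard errors),
#'   `model`, `fit`.
#' @export
fit_michaelis_menten <- function(d) {
  s <- d$substrate_conc; v <- d$v0
  if (length(unique(s[s > 0])) < 4)
    warning("fewer than 4 distinct nonzero concentrations; fit may be ",
            "ill-conditioned")
  vmax0 <- max(v) * 1.2
  km0 <- max(s[which(v >= max(v) / 2)][1], min(s[s > 0]))
  df <- data.frame(s = s, v = v)
  fit <- minpack.lm::nlsLM(v ~ vmax * s / (km + s), data = df,
                           start = list(vmax = vmax0, km = km0),
                           lower = c(0, 1e-12),
                           control = minpack.lm::nls.lm.control(maxiter = 200))
  finish_kinetics_fit(fit, d, model = "michaelis_menten")
}

#' Substrate-inhibition fit
#'
#' Nonlinear least squares of
#' `v0 = vmax [S] / (KM + [S] + [S]^2 / Ki)`. With `Ki` fixed very
#' large, this reduces to the Michaelis-Menten model. On the fitted
#' curve the rate maximum lies at `[S] = sqrt(KM * Ki)`.
#'
#' @param d [rate_dataset()].
#' @return `kinetics_fit` with `ki` (mM) populated.
#' @export
fit_substrate_inhibition <- function(d) {
  s <- d$substrate_conc; v <- d$v0
  peak <- which.max(v)
  if (peak == length(v))
    warning("no post-peak rate decline detected; consider the plain ",
            "Michaelis-Menten model")
  vmax0 <- max(v) * 1.5
  km0 <- max(s[which(v >= max(v) / 2)][1], min(s[s > 0]))
  ki0 <- max(s[peak]^2 / max(km0, 1e-6), max(s))
  df <- data.frame(s = s, v = v)
  fit <- minpack.lm::nlsLM(v ~ vmax * s / (km + s + s^2 / ki), data = df,
                           start = list(vmax = vmax0, km = km0, ki = ki0),
                           lower = c(0, 1e-12, 1e-12),
                           control = minpack.lm::nls.lm.control(maxiter = 500))
  finish_kinetics_fit(fit, d, model = "substrate_inhibition")
}

finish_kinetics_fit <- function(fit, d, model) {
  cf <- coef(fit)
  se <- tryCatch(sqrt(diag(vcov(fit))), error = function(e)
    setNames(rep(NA_real_, length(cf)), names(cf)))
  vmax <- cf[["vmax"]]; km <- cf[["km"]]
  kcat <- vmax / d$enzyme_conc
  # kcat/KM in 1/(M s): km is in mM -> factor 1e-3
  eff <- kcat / (km * 1e-3)
  # first-order propagation for the ratio (covariance included if available)
  vc <- tryCatch(vcov(fit), error = function(e) NULL)
  se_eff <- NA_real_
  if (!is.null(vc) && all(c("vmax", "km") %in% rownames(vc))) {
    g <- c(1 / (d$enzyme_conc * km * 1e-3),
           -vmax / (d$enzyme_conc * km^2 * 1e-3))
    se_eff <- sqrt(max(0, t(g) %*% vc[c("vmax", "km"), c("vmax", "km")] %*% g))
  }
  structure(list(kcat = kcat, km = km,
                 ki = if ("ki" %in% names(cf)) cf[["ki"]] else NA_real_,
                 vmax = vmax, kcat_over_km = eff,
                 se = c(vmax = unname(se["vmax"]), km = unname(se["km"]),
                        ki = if ("ki" %in% names(se)) unname(se["ki"])
                             else NA_real_,
                        kcat_over_km = se_eff),
                 enzyme_conc = d$enzyme_conc, substrate = d$substrate,
                 model = model, fit = fit),
            class = "kinetics_fit")
}

#' @export
print.kinetics_fit <- function(x, ...) {
  cat(sprintf("Steady-state kinetics fit (%s) for %s\n", x$model,
              x$substrate))
  cat(sprintf("  kcat     = %.4g 1/s\n", x$kcat))
  cat(sprintf("  KM       = %.4g mM\n", x$km))
  if (!is.na(x$ki)) cat(sprintf("  Ki       = %.4g mM\n", x$ki))
  cat(sprintf("  kcat/KM  = %.4g 1/(M s)\n", x$kcat_over_km))
  invisible(x)
}

#' @export
coef.kinetics_fit <- function(object, ...)
  c(kcat = object$kcat, km = object$km, ki = object$ki,
    kcat_over_km = object$kcat_over_km)

#' @export
predict.kinetics_fit <- function(object, substrate_conc, ...) {
  s <- substrate_conc
  if (object$model == "substrate_inhibition")
    object$vmax * s / (object$km + s + s^2 / object$ki)
  else object$vmax * s / (object$km + s)
}

#' Catalytic efficiency from the linear low-substrate regime
#'
#' For `[S] << KM` the rate law reduces to
#' `v0 = (kcat/KM) [E0] [S]`; the efficiency is the origin-constrained
#' slope of `v0` vs `[S]` divided by the enzyme concentration.
#'
#' @param d [rate_dataset()] (v0 in M/s, concentrations in mM).
#' @param max_conc use only points with `[S]` at or below this (mM);
#'   default: all points.
#' @return kcat/KM in 1/(M s).
#' @export
efficiency_linear_regime <- function(d, max_conc = Inf) {
  if (d$enzyme_conc <= 0) stop("enzyme concentration must be > 0")
  keep <- d$substrate_conc <= max_conc & d$substrate_conc > 0
  if (sum(keep) < 3) stop("need at least 3 points with [S] <= ", max_conc)
  s <- d$substrate_conc[keep] * 1e-3    # mM -> M
  v <- d$v0[keep]
  slope <- sum(s * v) / sum(s * s)      # least squares through the origin
  slope / d$enzyme_conc
}

#' Substrate selectivity and fold switch
#'
#' Selectivity is the ratio of catalytic efficiencies
#' `(kcat/KM)_phe / (kcat/KM)_asp`; when a reference enzyme's
#' efficiency pair is supplied the fold switch is the ratio of the two
#' selectivities. Accepts `kinetics_fit` objects or raw efficiencies.
#'
#' @param phe,asp `kinetics_fit` objects or numeric efficiencies for
#'   the two substrates.
#' @param reference optional `c(phe = , asp = )` efficiencies of a
#'   reference enzyme (e.g. wild type).
#' @return list with `selectivity` and `fold_switch` (NA without a
#'   reference).
#' @export
selectivity_metrics <- function(phe, asp, reference = NULL) {
  eff <- function(x) if (inherits(x, "kinetics_fit")) x$kcat_over_km
                     else as.numeric(x)
  e1 <- eff(phe); e2 <- eff(asp)
  if (e1 <= 0 || e2 <= 0) stop("efficiencies must be > 0")
  sel <- e1 / e2
  fold <- NA_real_
  if (!is.null(reference)) {
    rsel <- reference[["phe"]] / reference[["asp"]]
    if (rsel <= 0) stop("reference efficiencies must be > 0")
    fold <- sel / rsel
  }
  list(selectivity = sel, fold_switch = fold)
}
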
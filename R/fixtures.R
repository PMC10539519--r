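# Synthetic-data generators: every analysis module is testable on these
# without downloads. All generators are bit-deterministic under a fixed
# seed (seed-scoped RNG; the caller's RNG stream is untouched).

BB_GEOM <- list(n_ca = 1.458, ca_c = 1.525, c_n = 1.329, c_o = 1.231,
                ang_n_ca_c = 111.0, ang_ca_c_n = 116.6, ang_c_n_ca = 121.7,
                ang_ca_c_o = 120.8)

#' Ideal polyalanine scaffold
#'
#' Builds an ideal-geometry backbone (N, CA, C, O per residue) with the
#' given phi/psi, defaulting to an alpha-helix. Used as the template for
#' hinge, ensemble and design fixtures; no Ramachandran realism beyond
#' the fixed dihedrals is claimed.
#'
#' @param n_res number of residues.
#' @param phi,psi backbone dihedrals, degrees.
#' @param chain chain id.
#' @param id structure id.
#' @return A [new_structure()] of ALA residues.
#' @export
make_toy_structure <- function(n_res, phi = -60, psi = -40, chain = "A",
                               id = "toy") {
  g <- BB_GEOM
  # first residue placed explicitly
  atoms <- list()
  N1 <- c(0, 0, 0)
  CA1 <- c(g$n_ca, 0, 0)
  C1 <- CA1 + g$ca_c * c(cos((180 - g$ang_n_ca_c) * pi / 180),
                         sin((180 - g$ang_n_ca_c) * pi / 180), 0)
  xyz <- list(list(N = N1, CA = CA1, C = C1))
  if (n_res > 1) for (r in 2:n_res) {
    prev <- xyz[[r - 1]]
    # psi of previous residue sets N, omega=180 sets CA, phi sets C
    N <- place_atom(prev$N, prev$CA, prev$C, g$c_n, g$ang_ca_c_n, psi)
    CA <- place_atom(prev$CA, prev$C, N, g$n_ca, g$ang_c_n_ca, 180)
    C <- place_atom(prev$C, N, CA, g$ca_c, g$ang_n_ca_c, phi)
    xyz[[r]] <- list(N = N, CA = CA, C = C)
  }
  rows <- list()
  serial <- 0
  for (r in seq_len(n_res)) {
    res <- xyz[[r]]
    # carbonyl O: anti to the next N (dihedral psi + 180 about CA-C)
    O <- place_atom(res$N, res$CA, res$C, g$c_o, g$ang_ca_c_o, psi + 180)
    for (nm in c("N", "CA", "C", "O")) {
      serial <- serial + 1
      p <- if (nm == "O") O else res[[nm]]
      rows[[serial]] <- data.frame(
        serial = serial, name = nm, element = substr(nm, 1, 1),
        resname = "ALA", chain = chain, resno = r, ins = "", alt = "",
        occ = 1, x = p[1], y = p[2], z = p[3], b = 0, ligand = FALSE,
        stringsAsFactors = FALSE)
    }
  }
  new_structure(id, do.call(rbind, rows))
}

#' Two-conformation hinge fixture with a known screw motion
#'
#' Builds a two-domain polyalanine scaffold and a "closed" copy in which
#' the moving domain is rotated by exactly the requested angle about the
#' given axis (plus an optional axis-parallel translation), so hinge
#' geometry code can be validated against construction.
#'
#' @param angle rotation angle, degrees, in (0, 180).
#' @param axis rotation axis direction (default z).
#' @param n_res total residues (default 12; split fixed/hinge/moving).
#' @param point point on the axis (default: CA of the hinge residue).
#' @param translation axis-parallel translation, Angstrom (default 0).
#' @return list with `open`, `closed` (Structures) and `partition`
#'   ([domain_partition()]).
#' @export
make_toy_hinge_pair <- function(angle, axis = c(0, 0, 1), n_res = 12,
                                point = NULL, translation = 0) {
  stopifnot(angle > 0, angle < 180, n_res >= 9)
  open_s <- make_toy_structure(n_res, id = "hinge_open")
  nf <- max(3, floor(n_res / 2) - 1)
  hinge <- nf + 1
  moving <- (nf + 2):n_res
  part <- domain_partition(fixed = 1:nf, moving = moving, hinge = hinge,
                           chain = "A")
  if (is.null(point)) {
    ca <- select_atoms(open_s, atom_selection(resno_ranges = c(hinge, hinge),
                                              atom_class = "CA"))
    point <- as.numeric(coords(open_s, ca))
  }
  axis <- axis / sqrt(sum(axis^2))
  R <- rotation_about_axis(axis, angle)
  closed_s <- open_s
  closed_s$id <- "hinge_closed"
  idx <- select_atoms(closed_s,
                      atom_selection(resno_ranges = c(min(moving), max(moving)),
                                     atom_class = "all"))
  X <- coords(closed_s, idx)
  Xr <- sweep(sweep(X, 2, point) %*% t(R), 2, point + translation * axis, `+`)
  closed_s$atoms[idx, c("x", "y", "z")] <- Xr
  list(open = open_s, closed = closed_s, partition = part)
}

#' Toy rotamer-design problem with a known optimum
#'
#' Random symmetric singles/pairs energy matrices; the global minimum is
#' computed and stored by an exhaustive enumeration that is independent
#' of [brute_force_gmec()].
#'
#' @param n_pos positions.
#' @param n_choices choices per position (scalar or vector).
#' @param seed integer seed.
#' @return object of class `ToyDesignProblem`: list with `m`
#'   ([energy_matrices()]), `gmec_assign`, `gmec_energy`, `seed`.
#' @export
make_toy_design_problem <- function(n_pos, n_choices, seed = 1) {
  nc <- rep_len(n_choices, n_pos)
  if (prod(nc) > 1e6) stop("search space exceeds the oracle bound")
  mats <- with_seed(seed, {
    singles <- lapply(nc, function(n) round(stats::rnorm(n, 0, 2), 6))
    pairs <- vector("list", n_pos)
    for (i in seq_len(n_pos)) {
      pairs[[i]] <- vector("list", n_pos)
      if (i < n_pos) for (j in (i + 1):n_pos)
        pairs[[i]][[j]] <- matrix(round(stats::rnorm(nc[i] * nc[j]), 6),
                                  nc[i], nc[j])
    }
    list(singles = singles, pairs = pairs)
  })
  choices <- lapply(nc, function(n)
    data.frame(aa = rep("ALA", n), rot = seq_len(n), chi1 = NA, chi2 = NA,
               chi3 = NA, chi4 = NA, stringsAsFactors = FALSE))
  m <- energy_matrices(data.frame(chain = "A", resno = seq_len(n_pos)),
                       choices, mats$singles, mats$pairs)
  # independent recursive enumeration (not brute_force_gmec)
  best_e <- Inf; best_a <- NULL
  assign <- integer(n_pos)
  rec <- function(pos) {
    if (pos > n_pos) {
      e <- 0
      for (i in seq_len(n_pos)) e <- e + mats$singles[[i]][assign[i]]
      if (n_pos >= 2)
        for (i in seq_len(n_pos - 1)) for (j in (i + 1):n_pos)
          e <- e + mats$pairs[[i]][[j]][assign[i], assign[j]]
      if (e < best_e) { best_e <<- e; best_a <<- assign }
      return()
    }
    for (r in seq_len(nc[pos])) { assign[pos] <<- r; rec(pos + 1) }
  }
  rec(1)
  structure(list(m = m, gmec_assign = best_a, gmec_energy = best_e,
                 seed = seed), class = "ToyDesignProblem")
}

#' Synthetic variable-temperature equilibrium series
#'
#' Generates Keq(T) from the two-state van't Hoff relation (forward
#' direction) with optional multiplicative lognormal noise, and
#' optionally renders two-Lorentzian spectra whose peak areas realize
#' the corresponding state populations. Default generating parameters
#' are the closed-stabilized variant values dH = -9.9 kcal/mol,
#' dS = -0.032 kcal/mol/K, dCp = 0.972 kcal/mol/K at T_ref = 298 K,
#' observed at 5-35 degrees C in 5-degree steps.
#'
#' @param dh,ds,dcp generating parameters (kcal/mol, kcal/mol/K).
#' @param t_ref reference temperature, K.
#' @param temperatures kelvin vector.
#' @param noise multiplicative noise sd on Keq (0 = noiseless).
#' @param seed integer seed.
#' @param spectra logical; also render synthetic spectra.
#' @param centers ppm centers `c(closed, open)`; closed is upfield.
#' @param hwhm peak half-widths, ppm.
#' @param spectrum_noise additive intensity noise sd (fraction of max).
#' @return list with `series` (data.frame temperature, keq), `params`,
#'   and (if requested) `spectra` (list of [spectrum1d()]).
#' @export
make_vant_hoff_series <- function(dh = -9.9, ds = -0.032, dcp = 0.972,
                                  t_ref = 298,
                                  temperatures = 273.15 + seq(5, 35, 5),
                                  noise = 0, seed = 1, spectra = FALSE,
                                  centers = c(-61.6, -60.4),
                                  hwhm = c(0.08, 0.08),
                                  spectrum_noise = 0) {
  stopifnot(all(temperatures > 0))
  keq <- keq_from_thermo(temperatures, dh, ds, dcp, t_ref)
  if (noise > 0)
    keq <- with_seed(seed, keq * exp(stats::rnorm(length(keq), 0, noise)))
  out <- list(series = data.frame(temperature = temperatures, keq = keq),
              params = list(dh_ref = dh, ds_ref = ds, dcp = dcp,
                            t_ref = t_ref))
  if (spectra) {
    ppm <- seq(min(centers) - 1, max(centers) + 1, length.out = 600)
    out$spectra <- lapply(seq_along(temperatures), function(i) {
      p_closed <- keq[i] / (1 + keq[i])
      areas <- c(p_closed, 1 - p_closed)
      amp <- areas / (pi * hwhm)
      y <- lorentzian_curve(ppm, centers[1], hwhm[1], amp[1]) +
        lorentzian_curve(ppm, centers[2], hwhm[2], amp[2])
      if (spectrum_noise > 0)
        y <- y + with_seed(seed + i, stats::rnorm(length(ppm), 0,
                                                  spectrum_noise * max(y)))
      spectrum1d(ppm, y, temperatures[i])
    })
  }
  out
}

#' Synthetic steady-state rate data
#'
#' Rates from the Michaelis-Menten or substrate-inhibition model with
#' optional multiplicative Gaussian noise. Default parameters are the
#' published-scale l-Phe values kcat = 9.0 1/s, KM = 0.27 mM, over the
#' assayed 0.002-40 mM substrate range.
#'
#' @param kcat 1/s.
#' @param km mM.
#' @param ki mM; NA (default) for plain Michaelis-Menten.
#' @param enzyme_conc M (default 1e-8).
#' @param concs substrate concentrations, mM.
#' @param noise multiplicative rate noise sd (0 = noiseless).
#' @param seed integer seed.
#' @return [rate_dataset()] with attribute `params`.
#' @export
make_kinetics_series <- function(kcat = 9.0, km = 0.27, ki = NA,
                                 enzyme_conc = 1e-8,
                                 concs = exp(seq(log(0.002), log(40),
                                                 length.out = 12)),
                                 noise = 0, seed = 1) {
  stopifnot(kcat > 0, km > 0, is.na(ki) || ki > 0)
  vmax <- kcat * enzyme_conc
  v <- if (is.na(ki)) vmax * concs / (km + concs)
       else vmax * concs / (km + concs + concs^2 / ki)
  if (noise > 0)
    v <- with_seed(seed, v * (1 + stats::rnorm(length(v), 0, noise)))
  d <- rate_dataset(concs, v, enzyme_conc)
  attr(d, "params") <- list(kcat = kcat, km = km, ki = ki)
  d
}

#' Synthetic linear absorbance trace
#'
#' A340 trace with a linear initial phase and optional late exponential
#' curvature (substrate depletion), for validating linear-phase
#' detection.
#'
#' @param slope initial slope, absorbance/s.
#' @param duration seconds.
#' @param dt sampling interval, seconds (default 12, plate-reader like).
#' @param curvature seconds; time constant of the late flattening that
#'   starts after `linear_until` (Inf = perfectly linear).
#' @param linear_until seconds; end of the strictly linear phase
#'   (default `duration / 3`).
#' @param noise additive absorbance noise sd.
#' @param seed integer seed.
#' @return data.frame with `time_s`, `a340`.
#' @export
make_linear_trace <- function(slope, duration = 600, dt = 12,
                              curvature = Inf, linear_until = duration / 3,
                              noise = 0, seed = 1) {
  t <- seq(0, duration, dt)
  a <- if (is.finite(curvature)) {
    ifelse(t <= linear_until, slope * t,
           slope * (linear_until +
                      curvature * (1 - exp(-(t - linear_until) / curvature))))
  } else slope * t
  if (noise > 0)
    a <- a + with_seed(seed, stats::rnorm(length(t), 0, noise))
  data.frame(time_s = t, a340 = a)
}
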
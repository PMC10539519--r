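COULOMB_K <- 332.0637      # kcal A / (mol e^2)
CLASH_CAP <- 100           # kcal/mol, cap for sub-floor contacts
CLASH_FLOOR <- 0.5         # A; below this a contact is capped

ff_cache <- new.env(parent = emptyenv())

#' Load the nonbonded parameter tables
#'
#' The package ships a small self-consistent parameter table (Lennard-Jones
#' radii and well depths, partial charges by atom class, hydrogen-bond
#' donor/acceptor typing, occlusion-solvation parameters) plus a
#' secondary-structure propensity table, both plain-text and versioned.
#' These are stand-ins calibrated for internal consistency, not a
#' published force field; absolute design energies are therefore only
#' meaningful relative to one another.
#'
#' @param version table version string (default `"v1"`).
#' @return object of class `ForceFieldTables`: list with `params`
#'   (data.frame), `ss` (propensity data.frame), `version`,
#'   `lj_radius_scale` (0.9), `hb_depth` (8.0 kcal/mol), `hb_r0`
#'   (2.8 A), `dielectric` (10), `dielectric_model`
#'   (`"distance"`), `solv_length` (3.5 A), `cutoff` (8 A).
#' @export
load_ff_tables <- function(version = "v1") {
  key <- version
  if (!is.null(ff_cache[[key]])) return(ff_cache[[key]])
  pfile <- system.file("extdata", paste0("ff_params_", version, ".csv"),
                       package = "confdesign")
  sfile <- system.file("extdata", paste0("ss_propensity_", version, ".csv"),
                       package = "confdesign")
  if (pfile == "" || sfile == "") stop("unknown parameter version: ", version)
  params <- read.csv(pfile, comment.char = "#", stringsAsFactors = FALSE)
  ss <- read.csv(sfile, comment.char = "#", stringsAsFactors = FALSE)
  if (any(params$lj_radius <= 0)) stop("nonpositive LJ radius in table")
  ff <- structure(list(params = params, ss = ss, version = version,
                       lj_radius_scale = 0.9, hb_depth = 8.0, hb_r0 = 2.8,
                       dielectric = 10, dielectric_model = "distance",
                       solv_length = 3.5, cutoff = 8.0),
                  class = "ForceFieldTables")
  ff_cache[[key]] <- ff
  ff
}

# Resolve parameter rows for atoms: by name first, element fallback.
ff_lookup <- function(ff, names, elements) {
  p <- ff$params
  byname <- match(names, p$key[p$class == "name"])
  rown <- which(p$class == "name")[byname]
  byel <- match(elements, p$key[p$class == "element"])
  rowe <- which(p$class == "element")[byel]
  row <- ifelse(is.na(rown), rowe, rown)
  if (anyNA(row))
    stop("no parameters for atom type(s): ",
         paste(unique(elements[is.na(row)]), collapse = ", "))
  p[row, , drop = FALSE]
}

#' Lennard-Jones 12-6 energy
#'
#' 12-6 van der Waals term with per-atom radii scaled by 0.9 before
#' combination (arithmetic-mean combined radius, geometric-mean well
#' depth). The minimum value is exactly `-eps_ij` at `r = R0_ij`.
#'
#' @param type_i,type_j single-row parameter data.frames (from
#'   [ff_lookup] via [build_energy_matrices()]) or atom name strings.
#' @param r distance, Angstrom (> 0); vectorized.
#' @param ff [load_ff_tables()] object.
#' @return energy in kcal/mol; contacts below the clash floor are capped
#'   at +100 kcal/mol.
#' @export
lj_energy <- function(type_i, type_j, r, ff = load_ff_tables()) {
  pi_ <- resolve_type(type_i, ff); pj <- resolve_type(type_j, ff)
  if (any(r <= 0)) stop("r must be > 0")
  r0 <- (pi_$lj_radius * ff$lj_radius_scale +
         pj$lj_radius * ff$lj_radius_scale) / 2 * 2
  eps <- sqrt(pi_$lj_eps * pj$lj_eps)
  e <- eps * ((r0 / r)^12 - 2 * (r0 / r)^6)
  ifelse(r < CLASH_FLOOR, CLASH_CAP, pmin(e, CLASH_CAP))
}

resolve_type <- function(x, ff) {
  if (is.data.frame(x)) return(x)
  ff_lookup(ff, x, x)
}

#' Direction-dependent hydrogen-bond energy
#'
#' Hybrid 12-10 distance dependence
#' `D0 * (5 (R0/R)^12 - 6 (R0/R)^10)` with well depth `D0 = 8.0`
#' kcal/mol and equilibrium donor-acceptor distance `R0 = 2.8` A,
#' multiplied by an angular factor `cos^4(theta_DHA)` that is zero for
#' donor-hydrogen-acceptor angles below 90 degrees.
#'
#' @param r donor-acceptor distance, Angstrom.
#' @param theta_dha donor-hydrogen-acceptor angle, degrees (180 = linear).
#' @param ff [load_ff_tables()].
#' @return energy in kcal/mol (<= 0).
#' @export
hbond_energy <- function(r, theta_dha = 180, ff = load_ff_tables()) {
  if (any(r <= 0)) stop("r must be > 0")
  f <- ifelse(theta_dha < 90, 0, cos(theta_dha * pi / 180)^4)
  rr <- ff$hb_r0 / r
  pmax(ff$hb_depth * (5 * rr^12 - 6 * rr^10), -ff$hb_depth) * f
}

#' Coulomb electrostatic energy with distance-dependent dielectric
#'
#' `E = 332.0637 q_i q_j / (eps(r) r)` with `eps(r) = 10 r` by default
#' (distance-dependent dielectric of 10), or a constant dielectric of 10
#' when the tables are configured with `dielectric_model = "constant"`.
#'
#' @param q_i,q_j partial charges, elementary charge units.
#' @param r distance, Angstrom (> 0); vectorized.
#' @param ff [load_ff_tables()].
#' @return energy in kcal/mol; capped at +/-100 below the clash floor.
#' @export
coulomb_energy <- function(q_i, q_j, r, ff = load_ff_tables()) {
  if (any(r <= 0)) stop("r must be > 0")
  eps_r <- if (ff$dielectric_model == "distance") ff$dielectric * r
           else ff$dielectric
  e <- COULOMB_K * q_i * q_j / (eps_r * r)
  ifelse(r < CLASH_FLOOR, sign(e) * CLASH_CAP, pmax(pmin(e, CLASH_CAP),
                                                    -CLASH_CAP))
}

#' Occlusion-based solvation penalty
#'
#' Per-atom desolvation penalty: the atom's penalty coefficient times
#' the occluded volume contributed by its neighbors, with a Gaussian
#' distance kernel `exp(-(r/L)^2)` (correlation length `L = 3.5` A).
#' The term is pairwise-decomposable, so it enters the singles and pairs
#' energy matrices like the other nonbonded terms.
#'
#' @param coeff penalty coefficient of the occluded atom (kcal/mol/A^3).
#' @param neighbor_refvol reference volumes of the neighbors (A^3).
#' @param r distances to the neighbors, Angstrom.
#' @param ff [load_ff_tables()].
#' @return penalty in kcal/mol (>= 0 for positive coefficients).
#' @export
solvation_penalty <- function(coeff, neighbor_refvol, r,
                              ff = load_ff_tables()) {
  if (length(r) == 0) return(0)
  sum(coeff * neighbor_refvol * exp(-(r / ff$solv_length)^2))
}

#' Secondary-structure propensity
#'
#' Position-additive table lookup: energy of placing a residue type at a
#' position whose backbone phi/psi fall in a secondary-structure class.
#'
#' @param residue_type 3-letter code(s).
#' @param ss_class `"helix"`, `"strand"` or `"other"`; vectorized.
#' @param ff [load_ff_tables()].
#' @return energy in kcal/mol; 0 with a warning for unknown types.
#' @export
ss_propensity <- function(residue_type, ss_class, ff = load_ff_tables()) {
  stopifnot(all(ss_class %in% c("helix", "strand", "other")))
  n <- max(length(residue_type), length(ss_class))
  residue_type <- rep_len(toupper(residue_type), n)
  ss_class <- rep_len(ss_class, n)
  i <- match(residue_type, ff$ss$resname)
  if (anyNA(i))
    warning("no propensity entry for: ",
            paste(unique(residue_type[is.na(i)]), collapse = ", "))
  out <- numeric(n)
  ok <- !is.na(i)
  if (any(ok))
    out[ok] <- mapply(function(row, cls) ff$ss[[cls]][row], i[ok],
                      ss_class[ok])
  out
}

#' Secondary-structure class from backbone dihedrals
#'
#' Coarse phi/psi classification: `helix` for phi in (-100, -30) and
#' psi in (-80, -5); `strand` for phi in (-180, -80) and psi in
#' (80, 180) or psi in (-180, -170); otherwise `other`.
#'
#' @param phi,psi backbone dihedrals in degrees (NA allowed -> "other").
#' @return character vector of classes.
#' @export
ss_class_from_phipsi <- function(phi, psi) {
  out <- rep("other", length(phi))
  ok <- !is.na(phi) & !is.na(psi)
  hel <- ok & phi > -100 & phi < -30 & psi > -80 & psi < -5
  str <- ok & phi > -180 & phi < -80 & (psi > 80 | psi < -170)
  out[hel] <- "helix"
  out[str & !hel] <- "strand"
  out
}
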
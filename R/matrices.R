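#' Energy matrices over (amino acid, rotamer) choices
#'
#' Container for the singles (rotamer vs template) and pairs (rotamer vs
#' rotamer at distinct positions) design energies, in kcal/mol. The
#' constant template-template energy is excluded, matching the design
#' energy definition (pairwise nonbonded energies only, no bonded terms,
#' entropy, or unfolded-state reference).
#'
#' @param positions data.frame with columns `chain`, `resno`.
#' @param choices list (one per position) of data.frames with columns
#'   `aa`, `rot`, `chi1`..`chi4`.
#' @param singles list of numeric vectors, `singles[[i]][r]`.
#' @param pairs nested list, `pairs[[i]][[j]]` an `n_i x n_j` matrix for
#'   `i < j`.
#' @return object of class `EnergyMatrices`.
#' @export
energy_matrices <- function(positions, choices, singles, pairs) {
  k <- nrow(positions)
  stopifnot(length(choices) == k, length(singles) == k)
  for (i in seq_len(k))
    stopifnot(nrow(choices[[i]]) == length(singles[[i]]))
  for (i in seq_len(k)) for (j in seq_len(k)) if (i < j) {
    p <- pairs[[i]][[j]]
    stopifnot(nrow(p) == length(singles[[i]]),
              ncol(p) == length(singles[[j]]))
    if (!all(is.finite(p))) stop("non-finite pair energies at (", i, ",",
                                 j, ")")
  }
  structure(list(positions = positions, choices = choices,
                 singles = singles, pairs = pairs),
            class = "EnergyMatrices")
}

#' @export
print.EnergyMatrices <- function(x, ...) {
  nc <- vapply(x$singles, length, integer(1))
  cat(sprintf("EnergyMatrices: %d positions, choices per position: %s\n",
              nrow(x$positions), paste(nc, collapse = ", ")))
  invisible(x)
}

n_choices <- function(m) vapply(m$singles, length, integer(1))

pair_entry <- function(m, i, j, r, s) {
  if (i < j) m$pairs[[i]][[j]][r, s] else m$pairs[[j]][[i]][s, r]
}

#' Total energy of a rotamer assignment
#'
#' Sum of the chosen singles plus all distinct-position pair energies.
#'
#' @param m [energy_matrices()].
#' @param assign integer vector, one choice index per position.
#' @return kcal/mol.
#' @export
assignment_energy <- function(m, assign) {
  k <- nrow(m$positions)
  stopifnot(length(assign) == k)
  e <- 0
  for (i in seq_len(k)) e <- e + m$singles[[i]][assign[i]]
  if (k >= 2)
    for (i in seq_len(k - 1)) for (j in (i + 1):k)
      e <- e + m$pairs[[i]][[j]][assign[i], assign[j]]
  e
}

# Restrict matrices to choices whose amino acid matches seq (3-letter
# codes, one per position). Returns matrices + original index map.
restrict_to_sequence <- function(m, seq) {
  k <- nrow(m$positions)
  stopifnot(length(seq) == k)
  idx <- vector("list", k)
  for (i in seq_len(k)) {
    idx[[i]] <- which(m$choices[[i]]$aa == seq[i])
    if (length(idx[[i]]) == 0)
      stop("no rotamers for ", seq[i], " at position ", i)
  }
  choices <- lapply(seq_len(k), function(i)
    m$choices[[i]][idx[[i]], , drop = FALSE])
  singles <- lapply(seq_len(k), function(i) m$singles[[i]][idx[[i]]])
  pairs <- vector("list", k)
  for (i in seq_len(k)) {
    pairs[[i]] <- vector("list", k)
    if (i < k) for (j in (i + 1):k)
      pairs[[i]][[j]] <- m$pairs[[i]][[j]][idx[[i]], idx[[j]], drop = FALSE]
  }
  list(m = energy_matrices(m$positions, choices, singles, pairs),
       index_map = idx)
}

# Pairwise nonbonded energy between two atom tables (columns name,
# element, x, y, z), with LJ + Coulomb + hydrogen-bond + occlusion
# solvation terms, 8 A cutoff, per-contact clash capping. H-bonds are
# evaluated between donor/acceptor-typed heavy-atom pairs at ideal
# proxy-hydrogen geometry (angular factor 1).
nonbonded_energy <- function(at1, at2, ff = load_ff_tables()) {
  if (nrow(at1) == 0 || nrow(at2) == 0) return(0)
  p1 <- ff_lookup(ff, at1$name, at1$element)
  p2 <- ff_lookup(ff, at2$name, at2$element)
  X1 <- as.matrix(at1[, c("x", "y", "z")])
  X2 <- as.matrix(at2[, c("x", "y", "z")])
  d2 <- outer(rowSums(X1^2), rowSums(X2^2), `+`) - 2 * X1 %*% t(X2)
  d <- sqrt(pmax(d2, 1e-12))
  within <- which(d < ff$cutoff, arr.ind = TRUE)
  if (nrow(within) == 0) return(0)
  i <- within[, 1]; j <- within[, 2]; r <- d[within]
  e <- lj_energy(p1[i, ], p2[j, ], r, ff) +
    coulomb_energy(p1$charge[i], p2$charge[j], r, ff)
  hb <- (p1$donor[i] == 1 & p2$acceptor[j] == 1) |
        (p2$donor[j] == 1 & p1$acceptor[i] == 1)
  hbi <- hb & r < 3.5
  if (any(hbi)) e[hbi] <- e[hbi] + hbond_energy(r[hbi], 180, ff)
  solv <- p1$solv_coeff[i] * p2$solv_refvol[j] *
            exp(-(r / ff$solv_length)^2) +
          p2$solv_coeff[j] * p1$solv_refvol[i] *
            exp(-(r / ff$solv_length)^2)
  e <- e + solv
  sum(pmin(e, CLASH_CAP))
}

backbone_frame <- function(s, chain, resno) {
  a <- s$atoms
  rows <- which(a$chain == chain & a$resno == resno & !a$ligand &
                  a$name %in% c("N", "CA", "C"))
  if (length(rows) < 3)
    stop("missing backbone N/CA/C at ", chain, ":", resno)
  xyz <- as.matrix(a[rows, c("x", "y", "z")])
  rownames(xyz) <- a$name[rows]
  xyz[c("N", "CA", "C"), , drop = FALSE]
}

phi_psi <- function(s, chain, resno) {
  a <- s$atoms
  get1 <- function(rn, nm) {
    r <- which(a$chain == chain & a$resno == rn & a$name == nm & !a$ligand)
    if (length(r) == 0) return(NULL)
    as.numeric(a[r[1], c("x", "y", "z")])
  }
  N <- get1(resno, "N"); CA <- get1(resno, "CA"); C <- get1(resno, "C")
  Cm <- get1(resno - 1, "C"); Np <- get1(resno + 1, "N")
  phi <- if (!is.null(Cm)) dihedral(Cm, N, CA, C) else NA_real_
  psi <- if (!is.null(Np)) dihedral(N, CA, C, Np) else NA_real_
  c(phi = phi, psi = psi)
}

#' Build singles/pairs design energy matrices
#'
#' For each design position and candidate amino acid, side-chain
#' rotamers from the library are built on the template backbone. The
#' singles energy of a choice is its nonbonded energy against the
#' template (with the designed side chains removed, excluding its own
#' residue and adjacent-residue backbone atoms) plus the
#' secondary-structure propensity of the amino acid at that position;
#' pair energies are the nonbonded energies between rotamer atoms at
#' distinct positions. Steric clashes are capped, keeping all entries
#' finite.
#'
#' @param template Structure providing backbone and context atoms.
#' @param positions data.frame with columns `chain`, `resno` (design
#'   positions).
#' @param lib [load_rotamer_library()]; default the bundled mini library.
#' @param alphabet character vector of candidate 3-letter codes (default
#'   all 19 designable types: proline excluded).
#' @param ff [load_ff_tables()].
#' @return An [energy_matrices()] object.
#' @export
build_energy_matrices <- function(template, positions,
                                  lib = load_rotamer_library(),
                                  alphabet = setdiff(DESIGN_ALPHABET, "GLY"),
                                  ff = load_ff_tables()) {
  k <- nrow(positions)
  a <- template$atoms
  # template context: everything except designed side chains
  design_key <- paste(positions$chain, positions$resno)
  atom_key <- paste(a$chain, a$resno)
  is_design_sc <- atom_key %in% design_key &
    !(a$name %in% c("N", "CA", "C", "O")) & !a$ligand
  context <- a[!is_design_sc, , drop = FALSE]

  choices <- vector("list", k)
  rot_atoms <- vector("list", k)   # list of per-choice atom tables
  singles <- vector("list", k)
  for (i in seq_len(k)) {
    ch <- positions$chain[i]; rn <- positions$resno[i]
    bb <- backbone_frame(template, ch, rn)
    pp <- phi_psi(template, ch, rn)
    ss <- ss_class_from_phipsi(pp["phi"], pp["psi"])
    ch_rows <- list(); at_list <- list(); en <- numeric(0)
    # exclusion: own residue + adjacent backbone
    excl <- (context$chain == ch & context$resno == rn) |
      (context$chain == ch & abs(context$resno - rn) == 1 &
         context$name %in% c("N", "CA", "C", "O"))
    ctx <- context[!excl, , drop = FALSE]
    for (aa in alphabet) {
      rots <- get_rotamers(lib, aa, pp["phi"], pp["psi"])
      nch <- n_chi(aa)
      for (r in seq_len(nrow(rots))) {
        chi <- if (nch > 0)
          as.numeric(rots[r, paste0("chi", seq_len(nch))]) else numeric(0)
        sc <- tryCatch(build_sidechain(aa, chi, bb), error = function(e) NULL)
        if (is.null(sc)) next   # unbuildable rotamer: excluded
        at <- data.frame(name = rownames(sc),
                         element = substr(rownames(sc), 1, 1),
                         x = sc[, 1], y = sc[, 2], z = sc[, 3],
                         stringsAsFactors = FALSE)
        e <- nonbonded_energy(at, ctx, ff) +
          suppressWarnings(ss_propensity(aa, ss, ff))
        ch_rows[[length(ch_rows) + 1]] <-
          data.frame(aa = aa, rot = r,
                     chi1 = if (nch >= 1) chi[1] else NA,
                     chi2 = if (nch >= 2) chi[2] else NA,
                     chi3 = if (nch >= 3) chi[3] else NA,
                     chi4 = if (nch >= 4) chi[4] else NA,
                     stringsAsFactors = FALSE)
        at_list[[length(at_list) + 1]] <- at
        en <- c(en, min(e, CLASH_CAP))
      }
    }
    if (length(en) == 0) stop("no buildable rotamers at position ", i)
    choices[[i]] <- do.call(rbind, ch_rows)
    rot_atoms[[i]] <- at_list
    singles[[i]] <- en
  }
  pairs <- vector("list", k)
  for (i in seq_len(k)) {
    pairs[[i]] <- vector("list", k)
    if (i < k) for (j in (i + 1):k) {
      pm <- matrix(0, length(singles[[i]]), length(singles[[j]]))
      for (r in seq_along(rot_atoms[[i]]))
        for (s2 in seq_along(rot_atoms[[j]]))
          pm[r, s2] <- min(nonbonded_energy(rot_atoms[[i]][[r]],
                                            rot_atoms[[j]][[s2]], ff),
                           CLASH_CAP)
      pairs[[i]][[j]] <- pm
    }
  }
  energy_matrices(positions, choices, singles, pairs)
}
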
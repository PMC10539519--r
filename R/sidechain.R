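# Internal-coordinate side-chain templates. Each atom is placed by NeRF
# construction from three previously placed atoms (a, b, c): bond length
# to c, bond angle b-c-x, and a dihedral a-b-c-x that is either a fixed
# value or chi_k plus an offset (for branch atoms sharing a chi torsion).
# Ideal bond lengths/angles; heavy atoms only.
sc_atom <- function(name, a, b, c, bond, angle, chi = NA, offset = 0,
                    fixed = NA) {
  list(name = name, refs = c(a, b, c), bond = bond, angle = angle,
       chi = chi, offset = offset, fixed = fixed)
}

CB_ENTRY <- sc_atom("CB", "C", "N", "CA", 1.53, 110.5, fixed = -122.6)

SIDECHAIN_TEMPLATES <- list(
  ALA = list(CB_ENTRY),
  SER = list(CB_ENTRY,
    sc_atom("OG",  "N", "CA", "CB", 1.417, 110.5, chi = 1)),
  CYS = list(CB_ENTRY,
    sc_atom("SG",  "N", "CA", "CB", 1.808, 114.4, chi = 1)),
  VAL = list(CB_ENTRY,
    sc_atom("CG1", "N", "CA", "CB", 1.527, 110.5, chi = 1),
    sc_atom("CG2", "N", "CA", "CB", 1.527, 110.5, chi = 1, offset = 122.3)),
  THR = list(CB_ENTRY,
    sc_atom("OG1", "N", "CA", "CB", 1.433, 109.5, chi = 1),
    sc_atom("CG2", "N", "CA", "CB", 1.521, 110.5, chi = 1, offset = -120.0)),
  ILE = list(CB_ENTRY,
    sc_atom("CG1", "N", "CA", "CB", 1.530, 110.4, chi = 1),
    sc_atom("CG2", "N", "CA", "CB", 1.521, 110.5, chi = 1, offset = -122.0),
    sc_atom("CD1", "CA", "CB", "CG1", 1.513, 113.9, chi = 2)),
  LEU = list(CB_ENTRY,
    sc_atom("CG",  "N", "CA", "CB", 1.530, 116.3, chi = 1),
    sc_atom("CD1", "CA", "CB", "CG", 1.521, 110.7, chi = 2),
    sc_atom("CD2", "CA", "CB", "CG", 1.521, 110.7, chi = 2, offset = 122.5)),
  ASP = list(CB_ENTRY,
    sc_atom("CG",  "N", "CA", "CB", 1.516, 112.6, chi = 1),
    sc_atom("OD1", "CA", "CB", "CG", 1.249, 118.4, chi = 2),
    sc_atom("OD2", "CA", "CB", "CG", 1.249, 118.4, chi = 2, offset = 180)),
  ASN = list(CB_ENTRY,
    sc_atom("CG",  "N", "CA", "CB", 1.516, 112.6, chi = 1),
    sc_atom("OD1", "CA", "CB", "CG", 1.231, 120.8, chi = 2),
    sc_atom("ND2", "CA", "CB", "CG", 1.328, 116.4, chi = 2, offset = 180)),
  GLU = list(CB_ENTRY,
    sc_atom("CG",  "N", "CA", "CB", 1.530, 114.1, chi = 1),
    sc_atom("CD",  "CA", "CB", "CG", 1.516, 112.6, chi = 2),
    sc_atom("OE1", "CB", "CG", "CD", 1.249, 118.4, chi = 3),
    sc_atom("OE2", "CB", "CG", "CD", 1.249, 118.4, chi = 3, offset = 180)),
  GLN = list(CB_ENTRY,
    sc_atom("CG",  "N", "CA", "CB", 1.530, 114.1, chi = 1),
    sc_atom("CD",  "CA", "CB", "CG", 1.516, 112.6, chi = 2),
    sc_atom("OE1", "CB", "CG", "CD", 1.231, 120.8, chi = 3),
    sc_atom("NE2", "CB", "CG", "CD", 1.328, 116.4, chi = 3, offset = 180)),
  MET = list(CB_ENTRY,
    sc_atom("CG",  "N", "CA", "CB", 1.530, 114.1, chi = 1),
    sc_atom("SD",  "CA", "CB", "CG", 1.803, 112.7, chi = 2),
    sc_atom("CE",  "CB", "CG", "SD", 1.791, 100.9, chi = 3)),
  LYS = list(CB_ENTRY,
    sc_atom("CG",  "N", "CA", "CB", 1.530, 114.1, chi = 1),
    sc_atom("CD",  "CA", "CB", "CG", 1.530, 111.3, chi = 2),
    sc_atom("CE",  "CB", "CG", "CD", 1.530, 111.3, chi = 3),
    sc_atom("NZ",  "CG", "CD", "CE", 1.489, 111.9, chi = 4)),
  ARG = list(CB_ENTRY,
    sc_atom("CG",  "N", "CA", "CB", 1.530, 114.1, chi = 1),
    sc_atom("CD",  "CA", "CB", "CG", 1.530, 111.3, chi = 2),
    sc_atom("NE",  "CB", "CG", "CD", 1.461, 112.0, chi = 3),
    sc_atom("CZ",  "CG", "CD", "NE", 1.329, 124.2, chi = 4),
    sc_atom("NH1", "CD", "NE", "CZ", 1.326, 120.0, fixed = 0),
    sc_atom("NH2", "CD", "NE", "CZ", 1.326, 120.0, fixed = 180)),
  HIS = list(CB_ENTRY,
    sc_atom("CG",  "N", "CA", "CB", 1.497, 113.8, chi = 1),
    sc_atom("ND1", "CA", "CB", "CG", 1.378, 122.7, chi = 2),
    sc_atom("CD2", "CA", "CB", "CG", 1.356, 131.0, chi = 2, offset = 180),
    sc_atom("CE1", "CB", "CG", "ND1", 1.321, 109.0, fixed = 180),
    sc_atom("NE2", "CB", "CG", "CD2", 1.374, 107.0, fixed = 180)),
  PHE = list(CB_ENTRY,
    sc_atom("CG",  "N", "CA", "CB", 1.508, 113.8, chi = 1),
    sc_atom("CD1", "CA", "CB", "CG", 1.391, 120.8, chi = 2),
    sc_atom("CD2", "CA", "CB", "CG", 1.391, 120.8, chi = 2, offset = 180),
    sc_atom("CE1", "CB", "CG", "CD1", 1.391, 120.0, fixed = 180),
    sc_atom("CE2", "CB", "CG", "CD2", 1.391, 120.0, fixed = 180),
    sc_atom("CZ",  "CG", "CD1", "CE1", 1.391, 120.0, fixed = 0)),
  TYR = list(CB_ENTRY,
    sc_atom("CG",  "N", "CA", "CB", 1.512, 113.8, chi = 1),
    sc_atom("CD1", "CA", "CB", "CG", 1.391, 120.8, chi = 2),
    sc_atom("CD2", "CA", "CB", "CG", 1.391, 120.8, chi = 2, offset = 180),
    sc_atom("CE1", "CB", "CG", "CD1", 1.391, 120.0, fixed = 180),
    sc_atom("CE2", "CB", "CG", "CD2", 1.391, 120.0, fixed = 180),
    sc_atom("CZ",  "CG", "CD1", "CE1", 1.391, 120.0, fixed = 0),
    sc_atom("OH",  "CD1", "CE1", "CZ", 1.377, 120.0, fixed = 180)),
  TRP = list(CB_ENTRY,
    sc_atom("CG",  "N", "CA", "CB", 1.498, 113.6, chi = 1),
    sc_atom("CD1", "CA", "CB", "CG", 1.365, 126.9, chi = 2),
    sc_atom("CD2", "CA", "CB", "CG", 1.433, 126.6, chi = 2, offset = 180),
    sc_atom("NE1", "CB", "CG", "CD1", 1.374, 110.1, fixed = 180),
    sc_atom("CE2", "CB", "CG", "CD2", 1.409, 107.3, fixed = 180),
    sc_atom("CE3", "CB", "CG", "CD2", 1.398, 133.9, fixed = 0),
    sc_atom("CZ2", "CG", "CD2", "CE2", 1.394, 122.4, fixed = 180),
    sc_atom("CZ3", "CG", "CD2", "CE3", 1.382, 118.6, fixed = 180),
    sc_atom("CH2", "CD2", "CE2", "CZ2", 1.368, 117.5, fixed = 0))
)

# chi-defining atom chains per residue type: chi_k is the dihedral over
# atoms k..k+3 of the chain.
CHI_CHAINS <- list(
  SER = c("N", "CA", "CB", "OG"),
  CYS = c("N", "CA", "CB", "SG"),
  VAL = c("N", "CA", "CB", "CG1"),
  THR = c("N", "CA", "CB", "OG1"),
  ILE = c("N", "CA", "CB", "CG1", "CD1"),
  LEU = c("N", "CA", "CB", "CG", "CD1"),
  ASP = c("N", "CA", "CB", "CG", "OD1"),
  ASN = c("N", "CA", "CB", "CG", "OD1"),
  GLU = c("N", "CA", "CB", "CG", "CD", "OE1"),
  GLN = c("N", "CA", "CB", "CG", "CD", "OE1"),
  MET = c("N", "CA", "CB", "CG", "SD", "CE"),
  LYS = c("N", "CA", "CB", "CG", "CD", "CE", "NZ"),
  ARG = c("N", "CA", "CB", "CG", "CD", "NE", "CZ"),
  HIS = c("N", "CA", "CB", "CG", "ND1"),
  PHE = c("N", "CA", "CB", "CG", "CD1"),
  TYR = c("N", "CA", "CB", "CG", "CD1"),
  TRP = c("N", "CA", "CB", "CG", "CD1")
)

#' Number of chi angles per residue type
#' @param restype 3-letter code(s).
#' @return integer vector.
#' @export
n_chi <- function(restype) {
  vapply(toupper(restype), function(r) {
    if (r %in% c("ALA", "GLY")) 0L
    else if (is.null(CHI_CHAINS[[r]])) stop("unknown residue type: ", r)
    else length(CHI_CHAINS[[r]]) - 3L
  }, integer(1), USE.NAMES = FALSE)
}

#' Build side-chain coordinates for a rotamer
#'
#' Places side-chain heavy atoms on a backbone by sequential torsion
#' construction with ideal bond lengths and angles. Re-measuring the chi
#' angles from the built coordinates returns the inputs (up to numeric
#' precision); construction is deterministic.
#'
#' @param residue_type 3-letter code (GLY returns an empty matrix).
#' @param chi numeric vector of chi angles, degrees; length must equal
#'   [n_chi()] of the type.
#' @param backbone 3 x 3 matrix with rownames `N`, `CA`, `C`.
#' @return matrix of side-chain atom coordinates with atom-name rownames.
#' @export
build_sidechain <- function(residue_type, chi, backbone) {
  residue_type <- toupper(residue_type)
  if (residue_type == "GLY")
    return(matrix(numeric(0), ncol = 3,
                  dimnames = list(character(0), c("x", "y", "z"))))
  tmpl <- SIDECHAIN_TEMPLATES[[residue_type]]
  if (is.null(tmpl)) stop("unknown residue type: ", residue_type)
  need <- c("N", "CA", "C")
  if (!all(need %in% rownames(backbone)))
    stop("backbone must provide atoms N, CA, C")
  nchi <- n_chi(residue_type)
  chi <- as.numeric(chi)
  if (length(chi) != nchi)
    stop(residue_type, " needs ", nchi, " chi angle(s), got ", length(chi))
  placed <- backbone[need, , drop = FALSE]
  out <- matrix(NA_real_, nrow = length(tmpl), ncol = 3,
                dimnames = list(vapply(tmpl, `[[`, "", "name"),
                                c("x", "y", "z")))
  for (atom in tmpl) {
    dih <- if (!is.na(atom$fixed)) atom$fixed
           else wrap_angle(chi[atom$chi] + atom$offset)
    xyz <- place_atom(placed[atom$refs[1], ], placed[atom$refs[2], ],
                      placed[atom$refs[3], ], atom$bond, atom$angle, dih)
    placed <- rbind(placed, matrix(xyz, 1, 3,
                                   dimnames = list(atom$name, NULL)))
    out[atom$name, ] <- xyz
  }
  out
}

#' Measure chi angles from coordinates
#'
#' @param residue_type 3-letter code.
#' @param xyz coordinate matrix with atom-name rownames covering the
#'   backbone (N, CA) and side-chain atoms of the chi chains.
#' @return numeric vector of chi angles in degrees.
#' @export
measure_chi <- function(residue_type, xyz) {
  residue_type <- toupper(residue_type)
  chain <- CHI_CHAINS[[residue_type]]
  if (is.null(chain)) return(numeric(0))
  if (!all(chain %in% rownames(xyz)))
    stop("missing atoms for chi measurement: ",
         paste(setdiff(chain, rownames(xyz)), collapse = ", "))
  k <- length(chain) - 3
  vapply(seq_len(k), function(i)
    dihedral(xyz[chain[i], ], xyz[chain[i + 1], ],
             xyz[chain[i + 2], ], xyz[chain[i + 3], ]), numeric(1))
}
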
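#' @importFrom stats lm coef vcov sd setNames quantile predict residuals
#' @importFrom utils read.csv write.csv combn
NULL

#' Structure objects
#'
#' A `Structure` is the coordinate model used throughout the package:
#' an ordered atom table (one row per atom, author numbering, coordinates
#' in Angstrom) plus an identifier and an optional author-to-design
#' numbering map. Protein atoms and retained HETATM cofactors (e.g. PLP)
#' are kept in the same table, distinguished by the `ligand` column.
#'
#' @param id character identifier.
#' @param atoms data.frame with columns `serial`, `name`, `element`,
#'   `resname`, `chain`, `resno`, `ins`, `alt`, `occ`, `x`, `y`, `z`,
#'   `b`, `ligand`.
#' @param numbering_map optional data.frame with columns `author`,
#'   `design` relating author residue numbers to design numbering.
#' @return An object of class `Structure`.
#' @export
new_structure <- function(id, atoms, numbering_map = NULL) {
  req <- c("serial", "name", "element", "resname", "chain", "resno",
           "ins", "alt", "occ", "x", "y", "z", "b", "ligand")
  miss <- setdiff(req, names(atoms))
  if (length(miss) > 0)
    stop("atoms table is missing columns: ", paste(miss, collapse = ", "))
  if (!all(is.finite(atoms$x)) || !all(is.finite(atoms$y)) ||
      !all(is.finite(atoms$z)))
    stop("non-finite coordinates in atoms table")
  if (any(atoms$occ < 0 | atoms$occ > 1, na.rm = TRUE))
    stop("occupancy outside [0,1]")
  rownames(atoms) <- NULL
  structure(list(id = id, atoms = atoms, numbering_map = numbering_map),
            class = "Structure")
}

#' @export
print.Structure <- function(x, ...) {
  prot <- x$atoms[!x$atoms$ligand, ]
  nres <- nrow(unique(prot[, c("chain", "resno", "ins")]))
  cat(sprintf("Structure '%s': %d atoms, %d residues, %d chain(s)",
              x$id, nrow(x$atoms), nres, length(unique(x$atoms$chain))))
  if (any(x$atoms$ligand))
    cat(sprintf(", %d ligand atoms", sum(x$atoms$ligand)))
  cat("\n")
  invisible(x)
}

#' Coordinates of a Structure as an n x 3 matrix
#' @param s Structure.
#' @param idx optional row indices into the atom table.
#' @return numeric matrix with columns x, y, z.
#' @export
coords <- function(s, idx = NULL) {
  a <- s$atoms
  if (!is.null(idx)) a <- a[idx, , drop = FALSE]
  as.matrix(a[, c("x", "y", "z")])
}

`coords<-` <- function(s, idx = NULL, value) {
  if (is.null(idx)) idx <- seq_len(nrow(s$atoms))
  s$atoms[idx, c("x", "y", "z")] <- value
  s
}

WATER_RESNAMES <- c("HOH", "WAT", "DOD", "H2O")

#' Read a PDB file
#'
#' Parses fixed-column ATOM/HETATM records. Alternate locations are
#' collapsed according to `alt_loc_policy`; waters are discarded unless
#' `keep_waters`; other HETATM groups (cofactors such as PLP) are kept
#' and flagged as ligand atoms.
#'
#' @param path path to a PDB file.
#' @param alt_loc_policy `"highest_occupancy"` (default: keep the
#'   conformer with highest occupancy, ties broken alphabetically by
#'   alt-loc code) or `"first"`.
#' @param keep_waters logical; keep water molecules (default FALSE).
#' @return A [new_structure()] object.
#' @export
read_pdb <- function(path, alt_loc_policy = c("highest_occupancy", "first"),
                     keep_waters = FALSE) {
  alt_loc_policy <- match.arg(alt_loc_policy)
  if (!file.exists(path)) stop("no such file: ", path)
  if (file.size(path) == 0) stop("empty PDB file: ", path)
  pdb <- tryCatch(bio3d::read.pdb(path, verbose = FALSE, rm.alt = FALSE),
                  error = function(e) stop("PDB parse error in '", path,
                                           "': ", conditionMessage(e)))
  at <- pdb$atom
  if (nrow(at) == 0) stop("no ATOM/HETATM records in ", path)
  atoms <- data.frame(
    serial  = at$eleno,
    name    = at$elety,
    element = ifelse(is.na(at$elesy) | at$elesy == "",
                     substr(trimws(at$elety), 1, 1), trimws(at$elesy)),
    resname = at$resid,
    chain   = ifelse(is.na(at$chain), " ", at$chain),
    resno   = at$resno,
    ins     = ifelse(is.na(at$insert), "", at$insert),
    alt     = ifelse(is.na(at$alt), "", at$alt),
    occ     = ifelse(is.na(at$o), 1, at$o),
    x = at$x, y = at$y, z = at$z,
    b = ifelse(is.na(at$b), 0, at$b),
    ligand  = at$type == "HETATM",
    stringsAsFactors = FALSE
  )
  if (!keep_waters)
    atoms <- atoms[!(atoms$resname %in% WATER_RESNAMES), , drop = FALSE]
  atoms <- collapse_alt_locs(atoms, alt_loc_policy)
  new_structure(id = sub("\\.(pdb|ent)$", "", basename(path)), atoms = atoms)
}

collapse_alt_locs <- function(atoms, policy) {
  has_alt <- atoms$alt != ""
  if (!any(has_alt)) return(atoms)
  key <- paste(atoms$chain, atoms$resno, atoms$ins, atoms$name, sep = "\r")
  keep <- rep(TRUE, nrow(atoms))
  for (k in unique(key[has_alt])) {
    rows <- which(key == k)
    if (length(rows) < 2) next
    if (policy == "first") {
      keep[rows[-1]] <- FALSE
    } else {
      ord <- order(-atoms$occ[rows], atoms$alt[rows])
      keep[rows[-ord[1]]] <- FALSE
    }
  }
  out <- atoms[keep, , drop = FALSE]
  out$alt <- ""
  rownames(out) <- NULL
  out
}

#' Write a Structure as a PDB file
#'
#' Standard fixed 8.3 coordinate columns via bio3d. Ligand atoms are
#' written as HETATM records.
#'
#' @param s Structure.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_pdb <- function(s, path) {
  a <- s$atoms
  bio3d::write.pdb(
    file = path,
    type = ifelse(a$ligand, "HETATM", "ATOM"),
    eleno = a$serial, elety = a$name, resid = a$resname,
    chain = ifelse(a$chain == " ", "", a$chain), resno = a$resno,
    insert = ifelse(a$ins == "", " ", a$ins),
    xyz = as.vector(t(coords(s))), o = a$occ, b = a$b,
    elesy = a$element
  )
  invisible(path)
}

BACKBONE_NAMES <- c("N", "CA", "C", "O")

#' Atom selections
#'
#' An `AtomSelection` filters atoms by chain, residue-number ranges and
#' atom class. Selections applied to two structures with shared topology
#' yield order-matched atom lists. The string form used in configuration
#' files is `"chain:from-to:class"`, e.g. `"A:355-365:CA"`; chain `"*"`
#' matches all chains, class is one of `all`, `heavy`, `backbone`, `CA`.
#'
#' @param chain chain identifier or `"*"` for all chains.
#' @param resno_ranges NULL (all residues) or a 2-column matrix/list of
#'   `c(from, to)` ranges (inclusive, author numbering).
#' @param atom_class `"heavy"` (all non-hydrogen, default), `"all"`,
#'   `"backbone"` (N, CA, C, O) or `"CA"`.
#' @return An object of class `AtomSelection`.
#' @export
atom_selection <- function(chain = "*", resno_ranges = NULL,
                           atom_class = c("heavy", "all", "backbone", "CA")) {
  atom_class <- match.arg(atom_class)
  if (!is.null(resno_ranges)) {
    if (is.numeric(resno_ranges) && length(resno_ranges) == 2)
      resno_ranges <- matrix(resno_ranges, nrow = 1)
    if (is.list(resno_ranges))
      resno_ranges <- do.call(rbind, resno_ranges)
    stopifnot(ncol(resno_ranges) == 2)
  }
  structure(list(chain = chain, resno_ranges = resno_ranges,
                 atom_class = atom_class), class = "AtomSelection")
}

#' Parse a selection string
#'
#' @param x selection string `"chain:from-to[,from-to...]:class"`, e.g.
#'   `"A:355-365:CA"`. Use `"*"` for all chains and an empty middle field
#'   for all residues.
#' @return An [atom_selection()] object.
#' @export
parse_selection <- function(x) {
  parts <- strsplit(x, ":", fixed = TRUE)[[1]]
  if (length(parts) != 3)
    stop("selection string must have 3 ':'-separated fields: ", x)
  ranges <- NULL
  if (nzchar(parts[2])) {
    ranges <- do.call(rbind, lapply(strsplit(parts[2], ",")[[1]], function(r) {
      ft <- as.integer(strsplit(r, "-", fixed = TRUE)[[1]])
      if (length(ft) == 1) ft <- c(ft, ft)
      ft
    }))
  }
  cls <- switch(parts[3], all = "all", heavy = "heavy",
                backbone = "backbone", CA = "CA",
                stop("unknown atom class: ", parts[3]))
  atom_selection(chain = parts[1], resno_ranges = ranges, atom_class = cls)
}

#' Indices of atoms matched by a selection
#'
#' @param s Structure.
#' @param sel [atom_selection()] object (default: all heavy atoms).
#' @param include_ligand logical; include HETATM ligand atoms.
#' @return integer vector of row indices into `s$atoms`, in table order.
#' @export
select_atoms <- function(s, sel = atom_selection(), include_ligand = FALSE) {
  a <- s$atoms
  ok <- rep(TRUE, nrow(a))
  if (!include_ligand) ok <- ok & !a$ligand
  if (sel$chain != "*") ok <- ok & a$chain == sel$chain
  if (!is.null(sel$resno_ranges)) {
    inr <- rep(FALSE, nrow(a))
    for (i in seq_len(nrow(sel$resno_ranges)))
      inr <- inr | (a$resno >= sel$resno_ranges[i, 1] &
                    a$resno <= sel$resno_ranges[i, 2])
    ok <- ok & inr
  }
  ok <- ok & switch(sel$atom_class,
    all      = TRUE,
    heavy    = a$element != "H",
    backbone = a$name %in% BACKBONE_NAMES,
    CA       = a$name == "CA")
  which(ok)
}

#' Match selected atoms between two structures
#'
#' Atoms are matched by (chain, resno, ins, name). Errors if any selected
#' atom of `a` has no counterpart in `b`.
#' @noRd
match_atoms <- function(a, b, sel) {
  ia <- select_atoms(a, sel)
  ib <- select_atoms(b, sel)
  keya <- with(a$atoms[ia, ], paste(chain, resno, ins, name, sep = "\r"))
  keyb <- with(b$atoms[ib, ], paste(chain, resno, ins, name, sep = "\r"))
  m <- match(keya, keyb)
  if (anyNA(m)) {
    bad <- ia[which(is.na(m))[1]]
    stop("topology mismatch: atom ", a$atoms$name[bad], " of residue ",
         a$atoms$chain[bad], ":", a$atoms$resno[bad],
         " has no counterpart in second structure")
  }
  list(a = ia, b = ib[m])
}

#' Residue table of a Structure
#'
#' @param s Structure.
#' @param include_ligand logical.
#' @return data.frame with one row per residue (chain, resno, ins, resname).
#' @export
residues <- function(s, include_ligand = FALSE) {
  a <- s$atoms
  if (!include_ligand) a <- a[!a$ligand, , drop = FALSE]
  u <- unique(a[, c("chain", "resno", "ins", "resname")])
  rownames(u) <- NULL
  u
}
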
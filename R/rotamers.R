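DESIGN_ALPHABET <- c("ALA", "ARG", "ASN", "ASP", "CYS", "GLN", "GLU",
                     "GLY", "HIS", "ILE", "LEU", "LYS", "MET", "PHE",
                     "SER", "THR", "TRP", "TYR", "VAL")
# proline is excluded from the designable alphabet; glycine carries no
# side chain and is handled rotamer-free.

AA1 <- c(ALA = "A", ARG = "R", ASN = "N", ASP = "D", CYS = "C", GLN = "Q",
         GLU = "E", GLY = "G", HIS = "H", ILE = "I", LEU = "L", LYS = "K",
         MET = "M", PHE = "F", PRO = "P", SER = "S", THR = "T", TRP = "W",
         TYR = "Y", VAL = "V")
AA3 <- setNames(names(AA1), AA1)

#' Load a backbone-dependent rotamer library
#'
#' Reads a Dunbrack-style whitespace text format: one rotamer per line,
#' columns `restype phi psi prob chi1 sig1 chi2 sig2 chi3 sig3 chi4
#' sig4` with `-` for absent chi angles and `#` comment lines. With
#' `expand = TRUE` each rotamer is expanded around chi1 and chi2 by
#' +/-1 standard deviation: a rotamer with one chi angle becomes 3
#' variants, one with two or more becomes 9 (chi3/chi4 are not
#' expanded).
#'
#' @param path library file; default the bundled mini library.
#' @param expand logical (default TRUE).
#' @return object of class `RotamerLibrary`: data.frame `rotamers` with
#'   columns restype, phi, psi, prob, nchi, chi1..chi4, sig1..sig4,
#'   base_id, variant; plus `expanded` flag.
#' @export
load_rotamer_library <- function(path = NULL, expand = TRUE) {
  if (is.null(path))
    path <- system.file("extdata", "rotlib_mini.txt", package = "confdesign")
  lines <- readLines(path)
  keep <- which(!grepl("^\\s*(#|$)", lines))
  rows <- vector("list", length(keep))
  for (k in seq_along(keep)) {
    ln <- keep[k]
    f <- strsplit(trimws(lines[ln]), "\\s+")[[1]]
    if (length(f) != 12)
      stop("malformed rotamer library line ", ln, ": expected 12 fields, got ",
           length(f))
    num <- suppressWarnings(as.numeric(f[2:4]))
    if (anyNA(num))
      stop("malformed rotamer library line ", ln, ": non-numeric phi/psi/prob")
    chis <- suppressWarnings(as.numeric(ifelse(f[5:12] == "-", NA, f[5:12])))
    rows[[k]] <- data.frame(restype = toupper(f[1]), phi = num[1],
                            psi = num[2], prob = num[3],
                            chi1 = chis[1], sig1 = chis[2],
                            chi2 = chis[3], sig2 = chis[4],
                            chi3 = chis[5], sig3 = chis[6],
                            chi4 = chis[7], sig4 = chis[8],
                            stringsAsFactors = FALSE)
  }
  rot <- do.call(rbind, rows)
  rot$nchi <- rowSums(!is.na(rot[, c("chi1", "chi2", "chi3", "chi4")]))
  if (any(rot$sig1 < 0 | rot$sig2 < 0 | rot$sig3 < 0 | rot$sig4 < 0,
          na.rm = TRUE))
    stop("negative chi standard deviation in library")
  rot$base_id <- seq_len(nrow(rot))
  rot$variant <- 1L
  if (expand) rot <- expand_rotamers(rot)
  rownames(rot) <- NULL
  structure(list(rotamers = rot, expanded = expand),
            class = "RotamerLibrary")
}

wrap_angle <- function(a) {
  a <- (a + 180) %% 360 - 180
  ifelse(a == -180, 180, a)
}

expand_rotamers <- function(rot) {
  out <- vector("list", nrow(rot))
  for (i in seq_len(nrow(rot))) {
    r <- rot[i, , drop = FALSE]
    d1 <- if (!is.na(r$chi1)) c(0, -r$sig1, r$sig1) else 0
    d2 <- if (!is.na(r$chi2)) c(0, -r$sig2, r$sig2) else 0
    grid <- expand.grid(d1 = d1, d2 = d2)
    v <- r[rep(1, nrow(grid)), , drop = FALSE]
    if (!is.na(r$chi1)) v$chi1 <- wrap_angle(r$chi1 + grid$d1)
    if (!is.na(r$chi2)) v$chi2 <- wrap_angle(r$chi2 + grid$d2)
    v$variant <- seq_len(nrow(grid))
    out[[i]] <- v
  }
  do.call(rbind, out)
}

#' Rotamers available for a residue type at a backbone bin
#'
#' Backbone-dependent lookup: picks the (phi, psi) bin of the library
#' nearest to the query backbone dihedrals for that residue type.
#'
#' @param lib [load_rotamer_library()] object.
#' @param restype 3-letter code (GLY returns a single chi-free row).
#' @param phi,psi backbone dihedrals, degrees (NA allowed).
#' @return data.frame of rotamer rows.
#' @export
get_rotamers <- function(lib, restype, phi = -60, psi = -40) {
  restype <- toupper(restype)
  if (restype == "GLY")
    return(data.frame(restype = "GLY", phi = NA, psi = NA, prob = 1,
                      chi1 = NA, sig1 = NA, chi2 = NA, sig2 = NA,
                      chi3 = NA, sig3 = NA, chi4 = NA, sig4 = NA,
                      nchi = 0, base_id = 0L, variant = 1L))
  rows <- lib$rotamers[lib$rotamers$restype == restype, , drop = FALSE]
  if (nrow(rows) == 0) stop("no library rotamers for ", restype)
  if (is.na(phi)) phi <- -60
  if (is.na(psi)) psi <- -40
  bins <- unique(rows[, c("phi", "psi")])
  d2 <- (wrap_angle(bins$phi - phi))^2 + (wrap_angle(bins$psi - psi))^2
  b <- bins[which.min(d2), ]
  out <- rows[rows$phi == b$phi & rows$psi == b$psi, , drop = FALSE]
  rownames(out) <- NULL
  out
}
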
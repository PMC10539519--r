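# Shared helpers for building small fixtures in code.

toy_backbone_frame <- function() {
  matrix(c(0, 0, 0, 1.458, 0, 0, 2.0, 1.4, 0), 3, 3, byrow = TRUE,
         dimnames = list(c("N", "CA", "C"), NULL))
}

# minimal 3-atom single-residue PDB file
write_mini_pdb <- function(path) {
  lines <- c(
    "ATOM      1  N   ALA A   1       0.000   0.000   0.000  1.00  0.00           N",
    "ATOM      2  CA  ALA A   1       1.458   0.000   0.000  1.00  0.00           C",
    "ATOM      3  C   ALA A   1       2.009   1.421   0.000  1.00  0.00           C",
    "END")
  writeLines(lines, path)
  path
}

# independent recursive GMEC enumerator (second oracle, kept separate
# from both brute_force_gmec and the fixture generator's enumerator)
enumerate_gmec_oracle <- function(m) {
  nc <- vapply(m$singles, length, integer(1))
  k <- length(nc)
  best <- list(e = Inf, a = NULL)
  a <- integer(k)
  rec <- function(pos) {
    if (pos > k) {
      e <- assignment_energy(m, a)
      if (e < best$e) best <<- list(e = e, a = a)
      return()
    }
    for (r in seq_len(nc[pos])) {
      a[pos] <<- r
      rec(pos + 1)
    }
  }
  rec(1)
  best
}

# global rigid motion applied to a Structure
transform_structure <- function(s, rotation, translation) {
  s$atoms[, c("x", "y", "z")] <-
    sweep(coords(s) %*% t(rotation), 2, translation, `+`)
  s
}
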
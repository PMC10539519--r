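#' Published aspartate aminotransferase reference tables
#'
#' Convenience loaders for the published per-variant reference values
#' bundled with the package: the conformational-equilibrium table
#' (Boltzmann-weighted design energies and two-state thermodynamic
#' parameters of closing) and the steady-state kinetics table (KM,
#' kcat, kcat/KM for the l-Asp and l-Phe donor substrates). These are
#' inputs for worked examples and consistency checks, not outputs of
#' this package.
#'
#' @return data.frame keyed by `enzyme`.
#' @export
aat_equilibrium_table <- function() {
  read.csv(system.file("extdata", "aat_variant_equilibrium.csv",
                       package = "confdesign"), comment.char = "#")
}

#' @rdname aat_equilibrium_table
#' @export
aat_kinetics_table <- function() {
  read.csv(system.file("extdata", "aat_variant_kinetics.csv",
                       package = "confdesign"), comment.char = "#")
}
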
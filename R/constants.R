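# physical constants and element data

# CODATA-style conversion factors used throughout: input geometries are in
# Angstrom, all internal linear algebra is in atomic units (Bohr / Hartree),
# reported excitation energies are in eV.
BOHR_PER_ANGSTROM <- 1.8897261246
HARTREE_EV <- 27.211386
KBOLTZ_HARTREE <- 3.1668115634e-6  # Hartree / Kelvin

ELEMENTS <- c(
  "H", "He", "Li", "Be", "B", "C", "N", "O", "F", "Ne",
  "Na", "Mg", "Al", "Si", "P", "S", "Cl", "Ar",
  "K", "Ca", "Sc", "Ti", "V", "Cr", "Mn", "Fe", "Co", "Ni", "Cu", "Zn",
  "Ga", "Ge", "As", "Se", "Br", "Kr"
)

element_number <- function(symbol) {
  z <- match(symbol, ELEMENTS)
  if (anyNA(z)) {
    bad <- unique(symbol[is.na(z)])
    stop(errorCondition(
      sprintf("unknown element symbol(s): %s", paste(bad, collapse = ", ")),
      class = c("coox_unknown_element", "coox_error")
    ))
  }
  z
}
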
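# Built-in Gaussian basis sets for the compiled backend.
#
# The backend ships the standard STO-3G minimal basis (Hehre/Stewart/Pople
# contractions) for the elements the fixture molecules need.  Basis labels are
# resolved here; anything else is rejected, matching the backend contract that
# basis handling is the engine's responsibility.

# exponents / coefficients for normalized primitives; "sp" shells share
# exponents between the 2s and 2p contractions
.sto3g <- list(
  H = list(list(l = 0,
                exps = c(3.425250914, 0.6239137298, 0.1688554040),
                coefs = c(0.1543289673, 0.5353281423, 0.4446345422))),
  He = list(list(l = 0,
                 exps = c(6.362421394, 1.158922999, 0.3136497915),
                 coefs = c(0.1543289673, 0.5353281423, 0.4446345422))),
  C = list(list(l = 0,
                exps = c(71.61683735, 13.04509632, 3.530512160),
                coefs = c(0.1543289673, 0.5353281423, 0.4446345422)),
           list(l = 0,
                exps = c(2.941249355, 0.6834830964, 0.2222899159),
                coefs = c(-0.09996722919, 0.3995128261, 0.7001154689)),
           list(l = 1,
                exps = c(2.941249355, 0.6834830964, 0.2222899159),
                coefs = c(0.1559162750, 0.6076837186, 0.3919573931))),
  N = list(list(l = 0,
                exps = c(99.10616896, 18.05231239, 4.885660238),
                coefs = c(0.1543289673, 0.5353281423, 0.4446345422)),
           list(l = 0,
                exps = c(3.780455879, 0.8784966449, 0.2857143744),
                coefs = c(-0.09996722919, 0.3995128261, 0.7001154689)),
           list(l = 1,
                exps = c(3.780455879, 0.8784966449, 0.2857143744),
                coefs = c(0.1559162750, 0.6076837186, 0.3919573931))),
  O = list(list(l = 0,
                exps = c(130.7093214, 23.80886605, 6.443608313),
                coefs = c(0.1543289673, 0.5353281423, 0.4446345422)),
           list(l = 0,
                exps = c(5.033151319, 1.169596125, 0.3803889600),
                coefs = c(-0.09996722919, 0.3995128261, 0.7001154689)),
           list(l = 1,
                exps = c(5.033151319, 1.169596125, 0.3803889600),
                coefs = c(0.1559162750, 0.6076837186, 0.3919573931))),
  F = list(list(l = 0,
                exps = c(166.6791340, 30.36081233, 8.216820672),
                coefs = c(0.1543289673, 0.5353281423, 0.4446345422)),
           list(l = 0,
                exps = c(6.464803249, 1.502281245, 0.4885884864),
                coefs = c(-0.09996722919, 0.3995128261, 0.7001154689)),
           list(l = 1,
                exps = c(6.464803249, 1.502281245, 0.4885884864),
                coefs = c(0.1559162750, 0.6076837186, 0.3919573931)))
)

double_factorial <- function(n) if (n <= 1) 1 else prod(seq(n, 1, by = -2))

# normalization of a primitive Cartesian Gaussian of type (l,0,0)
.prim_norm <- function(a, l) {
  (2 * a / pi)^0.75 * (4 * a)^(l / 2) / sqrt(double_factorial(2 * l - 1))
}

# final primitive coefficients: tabulated coefficient x primitive norm,
# rescaled so the contracted (l,0,0) function has unit self-overlap
.contract <- function(exps, coefs, l) {
  cn <- coefs * vapply(exps, .prim_norm, numeric(1), l = l)
  self <- 0
  for (i in seq_along(exps)) {
    for (j in seq_along(exps)) {
      p <- exps[i] + exps[j]
      self <- self + cn[i] * cn[j] * (pi / p)^1.5 *
        double_factorial(2 * l - 1) / (2 * p)^l
    }
  }
  cn / sqrt(self)
}

#' Assemble the shell list for a molecule
#'
#' @param molecule a [molecule_spec()]
#' @param basis basis label; `"sto-3g"` (alias `"minimal"`) is built in
#' @return a list of shells (angular momentum, atom index, exponents and
#'   fully normalized contraction coefficients) in backend layout
#' @keywords internal
build_basis <- function(molecule, basis = "sto-3g") {
  label <- tolower(basis)
  if (!label %in% c("sto-3g", "minimal")) {
    stop(errorCondition(
      sprintf("basis '%s' is not available in the built-in backend (use 'sto-3g')",
              basis),
      class = c("coox_unknown_basis", "coox_error")
    ))
  }
  shells <- list()
  for (iat in seq_along(molecule$atoms)) {
    sym <- molecule$atoms[iat]
    if (is.null(.sto3g[[sym]])) {
      stop(errorCondition(
        sprintf("no built-in STO-3G parameters for element '%s'", sym),
        class = c("coox_unknown_basis", "coox_error")
      ))
    }
    for (sh in .sto3g[[sym]]) {
      shells[[length(shells) + 1L]] <- list(
        l = sh$l, atom = iat - 1L, exps = sh$exps,
        coefs = .contract(sh$exps, sh$coefs, sh$l)
      )
    }
  }
  shells
}

# flatten a shell list into the argument vectors of the compiled kernels
.shell_args <- function(shells) {
  list(
    l = vapply(shells, function(s) as.integer(s$l), integer(1)),
    atom = vapply(shells, function(s) as.integer(s$atom), integer(1)),
    nprim = vapply(shells, function(s) length(s$exps), integer(1)),
    exps = unlist(lapply(shells, function(s) s$exps)),
    coefs = unlist(lapply(shells, function(s) s$coefs))
  )
}
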
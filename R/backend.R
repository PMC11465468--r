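# backend adapter: atomic-orbital integrals, Fock builds, derivative
# contractions.  The compiled McMurchie-Davidson engine is the only place
# integrals live; everything above talks to it through build_context() /
# build_fock() / gradient_terms(), so a different engine honouring the same
# contract could be swapped in.

#' Build the atomic-orbital context for a molecule
#'
#' Evaluates overlap, core Hamiltonian, nuclear repulsion and (optionally)
#' the full two-electron integral tensor for the requested basis.
#'
#' @param molecule a [molecule_spec()]
#' @param config a [run_config()] (functional/basis labels)
#' @param with_eri keep the two-electron tensor (needed for SCF)
#' @return an object of class `coox_context`
#' @export
build_context <- function(molecule, config = run_config(), with_eri = TRUE) {
  if (!tolower(config$functional) %in% c("hf", "rhf", "uhf", "hartree-fock")) {
    stop(errorCondition(
      sprintf("functional '%s' is not available in the built-in backend (use 'hf')",
              config$functional),
      class = c("coox_unknown_functional", "coox_error")
    ))
  }
  shells <- build_basis(molecule, config$basis)
  sa <- .shell_args(shells)
  xyz <- molecule$coords * BOHR_PER_ANGSTROM
  z <- molecule$atomic_numbers
  ints <- cxx_ao_integrals(sa$l, sa$atom, sa$nprim, sa$exps, sa$coefs,
                           xyz, as.numeric(z), with_eri)
  n <- ints$n_ao

  ev <- eigen(ints$S, symmetric = TRUE)
  if (min(ev$values) <= 0) {
    stop(errorCondition("overlap matrix is not positive definite",
                        class = c("coox_backend_error", "coox_error")))
  }
  if (min(ev$values) < 1e-9) {
    warning("near-linear dependence in basis (smallest overlap eigenvalue < 1e-9); ",
            "using canonical orthogonalization")
    keep <- ev$values >= 1e-9
    orth <- ev$vectors[, keep, drop = FALSE] %*%
      diag(1 / sqrt(ev$values[keep]), sum(keep))
  } else {
    orth <- ev$vectors %*% diag(1 / sqrt(ev$values), n) %*% t(ev$vectors)
  }

  nn <- 0
  nat <- length(z)
  if (nat > 1) {
    for (a in 1:(nat - 1)) {
      for (b in (a + 1):nat) {
        nn <- nn + z[a] * z[b] / sqrt(sum((xyz[a, ] - xyz[b, ])^2))
      }
    }
  }

  ctx <- list(
    n_ao = n, overlap = ints$S, core_h = ints$T + ints$V,
    kinetic = ints$T, nuclear = ints$V, nuclear_repulsion = nn,
    orth = orth, molecule = molecule,
    basis = tolower(config$basis), functional = tolower(config$functional),
    shells = shells, shell_args = sa, xyz_bohr = xyz,
    geometry_hash = .geometry_hash(molecule, config)
  )
  if (with_eri) {
    eri <- array(ints$eri, dim = rep(n, 4))
    ctx$eri_j <- matrix(eri, n * n, n * n)                 # (mu nu | la si)
    ctx$eri_k <- matrix(aperm(eri, c(1, 3, 2, 4)), n * n, n * n)
    ctx$eri <- eri
  }
  structure(ctx, class = "coox_context")
}

.geometry_hash <- function(molecule, config) {
  paste(paste(molecule$atoms, collapse = ""),
        paste(sprintf("%.10f", molecule$coords), collapse = ","),
        config$basis, config$functional, sep = "|")
}

#' Build the (spin-resolved) Kohn-Sham/Fock matrices for given densities
#'
#' For fixed densities the returned electronic energy is the backend energy
#' functional evaluated at those densities.
#'
#' @param context a [build_context()] result holding the integral tensors
#' @param p_alpha,p_beta spin density matrices (AO, contravariant)
#' @return list with per-spin `fock` matrices and the `electronic_energy`
#' @export
build_fock <- function(context, p_alpha, p_beta = p_alpha) {
  n <- context$n_ao
  ptot <- p_alpha + p_beta
  j <- matrix(context$eri_j %*% as.numeric(ptot), n, n)
  ka <- matrix(context$eri_k %*% as.numeric(p_alpha), n, n)
  kb <- if (identical(p_alpha, p_beta)) ka else
    matrix(context$eri_k %*% as.numeric(p_beta), n, n)
  fa <- context$core_h + j - ka
  fb <- context$core_h + j - kb
  e <- sum(ptot * context$core_h) + 0.5 * sum(ptot * j) -
    0.5 * (sum(p_alpha * ka) + sum(p_beta * kb))
  list(fock = list(alpha = fa, beta = fb), electronic_energy = e)
}

# derivative contractions for nuclear gradients; densities/Wew in AO basis
gradient_terms <- function(context, p_tot, p_alpha, p_beta, w_ew) {
  sa <- context$shell_args
  cxx_gradient_terms(sa$l, sa$atom, sa$nprim, sa$exps, sa$coefs,
                     context$xyz_bohr,
                     as.numeric(context$molecule$atomic_numbers),
                     p_tot, p_alpha, p_beta, w_ew)
}

#' Evaluate an AO density matrix on points in space
#'
#' @param context a [build_context()] result
#' @param density AO density matrix (contravariant)
#' @param points n x 3 matrix of coordinates in Bohr
#' @return electron density values at the points
#' @export
density_on_points <- function(context, density, points) {
  sa <- context$shell_args
  cxx_density_on_points(sa$l, sa$atom, sa$nprim, sa$exps, sa$coefs,
                        context$xyz_bohr, density, as.matrix(points))
}
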
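# synthetic reference states: constraint algebra is pure linear algebra over
# an S-orthonormal orbital set, so a reproducible random reference lets the
# algebraic invariants be exercised (and demonstrated) without an SCF

#' Synthetic S-orthonormal reference state
#'
#' Builds a random symmetric-positive-definite metric, an S-orthonormal
#' orbital set and an aufbau occupation pattern, packaged like a converged
#' restricted SCF state.  Useful for exercising the constraint algebra
#' (whose invariants hold for any orthonormal reference) in isolation.
#'
#' @param n_occ,n_virt occupied / virtual space dimensions
#' @param seed RNG seed (reproducible)
#' @return an `coox_scf`-like reference state
#' @export
synthetic_reference_state <- function(n_occ, n_virt, seed = 42L) {
  n <- n_occ + n_virt
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  a <- matrix(stats::rnorm(n * n), n, n)
  s <- crossprod(a) / n + diag(n)           # well-conditioned SPD metric
  es <- eigen(s, symmetric = TRUE)
  orth <- es$vectors %*% diag(1 / sqrt(es$values), n) %*% t(es$vectors)
  q <- qr.Q(qr(matrix(stats::rnorm(n * n), n, n)))
  coeff <- orth %*% q                       # C^T S C = I
  occ <- c(rep(1, n_occ), rep(0, n_virt))
  eps <- sort(stats::rnorm(n))
  structure(
    list(
      mo_coeff = list(alpha = coeff, beta = coeff),
      mo_energy = list(alpha = eps, beta = eps),
      occupations = list(alpha = occ, beta = occ),
      chemical_potential = c(alpha = NA_real_, beta = NA_real_),
      density = list(alpha = coeff %*% (occ * t(coeff)),
                     beta = coeff %*% (occ * t(coeff))),
      energy = NA_real_, entropy_term = 0,
      n_spin = c(alpha = n_occ, beta = n_occ),
      restricted = TRUE, smearing = FALSE, converged = TRUE,
      commutator_norm = 0, n_iter = 0L,
      context = list(overlap = s, n_ao = n, geometry_hash = "synthetic"),
      temperature = 0
    ),
    class = "coox_scf"
  )
}

#' Random Frobenius-normalized transition amplitudes
#'
#' @param n_occ,n_virt amplitude matrix dimensions (virt x occ)
#' @param seed RNG seed
#' @export
random_transition_vector <- function(n_occ, n_virt, seed = 42L) {
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  x <- matrix(stats::rnorm(n_virt * n_occ), n_virt, n_occ)
  transition_vector(x, omega = NA_real_, source = "imported")
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}

.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}
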
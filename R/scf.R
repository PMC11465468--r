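# ground-state SCF with DIIS and Fermi-smearing fractional occupations

#' Fermi-Dirac occupations at an electronic temperature
#'
#' Solves the chemical potential so that the occupations
#' `f_p = 1 / (1 + exp((e_p - mu) / kT))` sum to the requested electron
#' number (per spin channel) to within 1e-10.
#'
#' @param mo_energy orbital energies (Hartree)
#' @param n_electrons electron count of the spin channel (0 .. length(mo_energy))
#' @param temperature electronic temperature in Kelvin
#' @return list with `occupations` and `chemical_potential`
#' @export
fermi_occupations <- function(mo_energy, n_electrons, temperature) {
  m <- length(mo_energy)
  if (n_electrons < 0 || n_electrons > m) {
    stop(errorCondition("electron count outside [0, n_orbitals]",
                        class = c("coox_bad_occupation", "coox_error")))
  }
  if (n_electrons == 0) {
    return(list(occupations = rep(0, m), chemical_potential = -Inf))
  }
  if (n_electrons == m) {
    return(list(occupations = rep(1, m), chemical_potential = Inf))
  }
  if (temperature <= 0) {
    stop(errorCondition("temperature must be positive for smearing",
                        class = c("coox_bad_config", "coox_error")))
  }
  kt <- KBOLTZ_HARTREE * temperature
  nsum <- function(mu) sum(stats::plogis((mu - mo_energy) / kt)) - n_electrons
  lo <- min(mo_energy) - 60 * kt - 1
  hi <- max(mo_energy) + 60 * kt + 1
  mu <- stats::uniroot(nsum, c(lo, hi), tol = 1e-14)$root
  # Newton polish to push |sum f - N| below 1e-10 even for tiny kT
  for (i in 1:50) {
    f <- stats::plogis((mu - mo_energy) / kt)
    r <- sum(f) - n_electrons
    if (abs(r) <= 1e-12) break
    d <- sum(f * (1 - f)) / kt
    if (d < 1e-300) break
    mu <- mu - r / d
  }
  f <- stats::plogis((mu - mo_energy) / kt)
  list(occupations = f, chemical_potential = mu)
}

# electronic entropy term -T * S_elec in Hartree (0 log 0 := 0)
entropy_term <- function(occ_list, temperature) {
  kt <- KBOLTZ_HARTREE * temperature
  s <- 0
  for (f in occ_list) {
    f <- pmin(pmax(f, 0), 1)
    x <- ifelse(f > 0, f * log(f), 0) + ifelse(f < 1, (1 - f) * log(1 - f), 0)
    s <- s + sum(x)
  }
  kt * s  # equals -T * S_elec with S_elec = -k * sum[...]
}

# aufbau or smeared occupations for one spin channel
.assign_occupations <- function(mo_energy, n_electrons, temperature,
                                smearing) {
  if (smearing) {
    fermi_occupations(mo_energy, n_electrons, temperature)
  } else {
    occ <- rep(0, length(mo_energy))
    if (n_electrons > 0) occ[seq_len(n_electrons)] <- 1
    list(occupations = occ, chemical_potential = NA_real_)
  }
}

# generalized symmetric eigenproblem F C = S C e via the orthogonalizer
.solve_fock <- function(fock, orth) {
  fp <- t(orth) %*% fock %*% orth
  ev <- eigen((fp + t(fp)) / 2, symmetric = TRUE)
  ord <- order(ev$values)
  list(coeff = orth %*% ev$vectors[, ord, drop = FALSE],
       energy = ev$values[ord])
}

.density_from <- function(coeff, occ) {
  coeff %*% (occ * t(coeff))
}

.commutator_norm <- function(fock, density, overlap) {
  e <- fock %*% density %*% overlap
  sqrt(sum((e - t(e))^2))
}

# Pulay DIIS over concatenated per-spin Fock matrices
.diis_new <- function(max_len = 8L) {
  env <- new.env(parent = emptyenv())
  env$focks <- list()
  env$errs <- list()
  env$max_len <- max_len
  env
}

.diis_update <- function(diis, focks, errs) {
  diis$focks[[length(diis$focks) + 1L]] <- focks
  diis$errs[[length(diis$errs) + 1L]] <- unlist(lapply(errs, as.numeric))
  if (length(diis$focks) > diis$max_len) {
    diis$focks <- diis$focks[-1]
    diis$errs <- diis$errs[-1]
  }
  m <- length(diis$focks)
  if (m < 2) return(focks)
  b <- matrix(0, m + 1, m + 1)
  for (i in 1:m) {
    for (j in 1:i) {
      b[i, j] <- b[j, i] <- sum(diis$errs[[i]] * diis$errs[[j]])
    }
  }
  b[m + 1, 1:m] <- b[1:m, m + 1] <- -1
  rhs <- c(rep(0, m), -1)
  w <- tryCatch(solve(b, rhs)[1:m], error = function(e) NULL)
  if (is.null(w) || any(!is.finite(w))) {
    diis$focks <- diis$focks[m]
    diis$errs <- diis$errs[m]
    return(focks)
  }
  out <- lapply(focks, function(x) x * 0)
  for (i in 1:m) {
    for (s in seq_along(out)) out[[s]] <- out[[s]] + w[i] * diis$focks[[i]][[s]]
  }
  out
}

# electron counts per spin from molecule + spin channel
.spin_electrons <- function(molecule, spin_channel = "singlet_restricted") {
  n <- molecule$n_electrons
  if (spin_channel == "triplet") {
    if (n < 2) {
      stop(errorCondition("triplet channel needs at least two electrons",
                          class = c("coox_bad_multiplicity", "coox_error")))
    }
    if (n %% 2 != 0) {
      stop(errorCondition("triplet promotion assumes an even-electron ground state",
                          class = c("coox_bad_multiplicity", "coox_error")))
    }
    c(alpha = n / 2 + 1, beta = n / 2 - 1)
  } else {
    na <- (n + (molecule$spin_multiplicity - 1)) / 2
    c(alpha = na, beta = n - na)
  }
}

#' Ground-state self-consistent field
#'
#' Restricted (closed-shell) or unrestricted Hartree-Fock with DIIS
#' acceleration.  Occupations are integer (aufbau) by default; with
#' `smearing = TRUE` they follow the Fermi distribution at the configured
#' electronic temperature and the state carries the corresponding entropy
#' term.  Convergence is measured by the Frobenius norm of `FPS - SPF`.
#'
#' @param molecule a [molecule_spec()]
#' @param config a [run_config()]
#' @param context optionally a prebuilt [build_context()]
#' @param smearing apply Fermi smearing to the ground state
#' @param restricted closed-shell restricted solve; default for singlets
#' @return an `coox_scf` state: MO coefficients, energies, occupations,
#'   per-spin densities, total energy and diagnostics
#' @export
ground_scf <- function(molecule, config = run_config(), context = NULL,
                       smearing = FALSE,
                       restricted = (molecule$spin_multiplicity == 1)) {
  if (is.null(context)) context <- build_context(molecule, config)
  nspin <- .spin_electrons(molecule)
  if (restricted && nspin["alpha"] != nspin["beta"]) {
    stop(errorCondition("restricted SCF needs equal alpha and beta counts",
                        class = c("coox_bad_multiplicity", "coox_error")))
  }
  # core-Hamiltonian initial guess
  guess <- .solve_fock(context$core_h, context$orth)
  occ_a <- .assign_occupations(guess$energy, nspin["alpha"],
                               config$temperature, smearing)
  occ_b <- .assign_occupations(guess$energy, nspin["beta"],
                               config$temperature, smearing)
  ca <- cb <- guess$coeff
  pa <- .density_from(ca, occ_a$occupations)
  pb <- .density_from(cb, occ_b$occupations)

  diis <- .diis_new()
  energy_hist <- numeric(0)
  conv <- FALSE
  comm <- Inf
  e_total <- NA_real_
  for (iter in seq_len(config$max_iter)) {
    fb <- build_fock(context, pa, pb)
    e_total <- fb$electronic_energy + context$nuclear_repulsion
    energy_hist <- c(energy_hist, e_total)
    err_a <- fb$fock$alpha %*% pa %*% context$overlap
    err_a <- err_a - t(err_a)
    err_b <- fb$fock$beta %*% pb %*% context$overlap
    err_b <- err_b - t(err_b)
    comm <- sqrt(sum(err_a^2) + sum(err_b^2))
    if (config$verbose) {
      message(sprintf("[scf %s] iter %3d  E = %.10f  |[F,P]| = %.3e",
                      format(Sys.time(), "%H:%M:%S"), iter, e_total, comm))
    }
    if (comm <= config$scf_conv) {
      conv <- TRUE
      break
    }
    fset <- .diis_update(diis, list(fb$fock$alpha, fb$fock$beta),
                         list(err_a, err_b))
    sol_a <- .solve_fock(fset[[1]], context$orth)
    sol_b <- if (restricted) sol_a else .solve_fock(fset[[2]], context$orth)
    occ_a <- .assign_occupations(sol_a$energy, nspin["alpha"],
                                 config$temperature, smearing)
    occ_b <- .assign_occupations(sol_b$energy, nspin["beta"],
                                 config$temperature, smearing)
    ca <- sol_a$coeff
    cb <- sol_b$coeff
    pa <- .density_from(ca, occ_a$occupations)
    pb <- .density_from(cb, occ_b$occupations)
  }
  if (!conv) {
    warning(sprintf("SCF did not converge in %d iterations (|[F,P]| = %.3e)",
                    config$max_iter, comm))
  }
  # consistent final set: orbitals, energies and occupations of the last Fock
  fb <- build_fock(context, pa, pb)
  sol_a <- .solve_fock(fb$fock$alpha, context$orth)
  sol_b <- if (restricted) sol_a else .solve_fock(fb$fock$beta, context$orth)
  occ_a <- .assign_occupations(sol_a$energy, nspin["alpha"],
                               config$temperature, smearing)
  occ_b <- .assign_occupations(sol_b$energy, nspin["beta"],
                               config$temperature, smearing)
  ca <- sol_a$coeff
  cb <- sol_b$coeff
  pa <- .density_from(ca, occ_a$occupations)
  pb <- .density_from(cb, occ_b$occupations)
  fb <- build_fock(context, pa, pb)
  e_total <- fb$electronic_energy + context$nuclear_repulsion
  ent <- if (smearing) {
    entropy_term(list(occ_a$occupations, occ_b$occupations), config$temperature)
  } else 0
  structure(
    list(
      mo_coeff = list(alpha = ca, beta = cb),
      mo_energy = list(alpha = sol_a$energy, beta = sol_b$energy),
      occupations = list(alpha = occ_a$occupations, beta = occ_b$occupations),
      chemical_potential = c(alpha = occ_a$chemical_potential,
                             beta = occ_b$chemical_potential),
      density = list(alpha = pa, beta = pb),
      energy = e_total, entropy_term = ent,
      n_spin = nspin, restricted = restricted, smearing = smearing,
      converged = conv, commutator_norm = comm, n_iter = iter,
      energy_history = energy_hist, context = context,
      temperature = config$temperature
    ),
    class = "coox_scf"
  )
}

#' @export
print.coox_scf <- function(x, ...) {
  cat(sprintf("<SCF state: E = %.8f Ha, %s, %sconverged (|[F,P]| = %.2e)>\n",
              x$energy, if (x$restricted) "restricted" else "unrestricted",
              if (x$converged) "" else "NOT ", x$commutator_norm))
  invisible(x)
}

# occupied / virtual MO index helpers (integer-occupation ground states)
.occ_idx <- function(state, spin = "alpha") {
  which(state$occupations[[spin]] > 0.5)
}
.virt_idx <- function(state, spin = "alpha") {
  which(state$occupations[[spin]] <= 0.5)
}

#' Persist an SCF state (orbitals, energies, occupations) to a checkpoint
#'
#' Uses R's serialization; the round trip is bit exact.
#'
#' @param state an `coox_scf` state or constrained solution
#' @param path checkpoint file
#' @export
save_checkpoint <- function(state, path) {
  slim <- state
  slim$context <- NULL  # integrals are recomputed, not persisted
  saveRDS(slim, path)
  invisible(NULL)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) readRDS(path)
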
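# Excited-state nuclear gradients and geometry optimization.
#
# The constrained solution is a stationary point of the Lagrangian
# W = E_KS + lambda (Tr[P W_c] - N_c) in both the density and the
# multiplier, so the gradient of the (free) energy surface at fixed
# constraint potential is assembled exactly like a ground-state gradient:
# Hellmann-Feynman and two-electron derivative terms contracted with the
# constrained density, the nuclear-repulsion derivative, and the Pulay term
# with the energy-weighted density built from fractional occupations and the
# eigenvalues of the *total* (constraint-including) Fock operator - the
# operator whose eigenbasis the orbitals actually are.  The constraint
# potential itself is a fixed AO matrix, not a function of the nuclear
# coordinates, and contributes no extra derivative term.

# energy-weighted density  sum_p f_p e_p c_p c_p^T  per spin, summed
.energy_weighted_density <- function(state) {
  wa <- state$mo_coeff$alpha %*%
    ((state$occupations$alpha * state$mo_energy$alpha) * t(state$mo_coeff$alpha))
  wb <- state$mo_coeff$beta %*%
    ((state$occupations$beta * state$mo_energy$beta) * t(state$mo_coeff$beta))
  wa + wb
}

#' Nuclear gradient of a converged (constrained) SCF state
#'
#' @param solution an `coox_constrained` result or a ground `coox_scf` state
#' @param molecule the [molecule_spec()] at the solution geometry
#' @param config the [run_config()] used
#' @return a `coox_gradient`: per-atom Cartesian forces (Hartree/Bohr) plus
#'   summary norms
#' @export
nuclear_gradient <- function(solution, molecule, config = run_config()) {
  if (inherits(solution, "coox_constrained")) {
    if (!solution$converged || max(solution$constraint_residuals) > 1e-6) {
      stop(errorCondition("gradient requested for an unconverged solution",
                          class = c("coox_not_converged", "coox_error")))
    }
    state <- solution$state
  } else {
    state <- solution
    if (!state$converged) {
      stop(errorCondition("gradient requested for an unconverged state",
                          class = c("coox_not_converged", "coox_error")))
    }
  }
  ctx <- state$context
  # orbital energies must belong to the operator that was diagonalized
  # (total Fock including lambda * W_c); they do by construction
  wew <- .energy_weighted_density(state)
  pa <- state$density$alpha
  pb <- state$density$beta
  terms <- gradient_terms(ctx, pa + pb, pa, pb, wew)
  grad <- terms$core + terms$eri + terms$overlap + terms$nn
  rownames(grad) <- molecule$atoms
  colnames(grad) <- c("x", "y", "z")
  structure(
    list(forces = grad,
         max_component = max(abs(grad)),
         rms = sqrt(mean(grad^2)),
         energy_at_geometry = state$energy + state$entropy_term,
         terms = terms),
    class = "coox_gradient"
  )
}

#' @export
print.coox_gradient <- function(x, ...) {
  cat(sprintf("<gradient: max |g| = %.2e, rms %.2e Ha/Bohr, E = %.8f Ha>\n",
              x$max_component, x$rms, x$energy_at_geometry))
  invisible(x)
}

# one full single-point evaluation at given coordinates (Bohr, flattened):
# ground SCF, optional state-tracked excitation, energy + gradient
.evaluate_geometry <- function(coords_bohr, molecule, config, excited,
                               prev_tvec_ao = NULL) {
  mol <- molecule_spec(molecule$atoms,
                       matrix(coords_bohr, ncol = 3, byrow = TRUE) /
                         BOHR_PER_ANGSTROM,
                       charge = molecule$charge,
                       spin_multiplicity = molecule$spin_multiplicity,
                       label = molecule$label)
  ground <- ground_scf(mol, config)
  if (!excited) {
    g <- nuclear_gradient(ground, mol, config)
    return(list(molecule = mol, energy = g$energy_at_geometry,
                gradient = g$forces, ground = ground, tvec_ao = NULL))
  }
  spin_type <- if (config$spin_channel == "triplet") "triplet" else "singlet"
  n_states <- if (is.null(config$n_states)) {
    max(config$state_index + 2L, 4L)
  } else config$n_states
  states <- tda_solve(ground, config, n_states = n_states,
                      spin_type = spin_type)
  occ <- .occ_idx(ground)
  virt <- .virt_idx(ground)
  co <- ground$mo_coeff$alpha[, occ, drop = FALSE]
  cv <- ground$mo_coeff$alpha[, virt, drop = FALSE]
  s <- ground$context$overlap
  t_ao <- lapply(states, function(tv) cv %*% tv$amplitudes %*% t(co))
  pick <- config$state_index
  if (!is.null(prev_tvec_ao)) {
    ovl <- vapply(t_ao, function(t1) {
      abs(sum((s %*% t1 %*% s) * prev_tvec_ao)) /
        sqrt(sum((s %*% t1 %*% s) * t1) *
             sum((s %*% prev_tvec_ao %*% s) * prev_tvec_ao))
    }, numeric(1))
    pick <- which.max(ovl)
    if (ovl[pick] < 0.5) {
      stop(errorCondition(
        sprintf("state tracking lost the excitation (best overlap %.2f)",
                ovl[pick]),
        class = c("coox_state_switch", "coox_error")
      ))
    }
  }
  cfg1 <- config
  cfg1$state_index <- pick
  res <- excite(mol, cfg1, tvec = states[[pick]])
  g <- nuclear_gradient(res$solution, mol, cfg1)
  list(molecule = mol, energy = g$energy_at_geometry, gradient = g$forces,
       ground = ground, solution = res$solution, tvec_ao = t_ao[[pick]])
}

#' Geometry optimization on the (excited-state) energy surface
#'
#' Quasi-Newton (BFGS) descent with backtracking line search.  For excited
#' states the linear-response transition vector and the constraint are
#' rebuilt at every geometry and the target state is followed by maximum
#' overlap of the transition density with the previous step (aborting if
#' the best overlap drops below 0.5).  Convergence: maximum force component
#' below `fmax` (default 4.5e-4 Hartree/Bohr).
#'
#' @param molecule starting [molecule_spec()]
#' @param config a [run_config()]
#' @param excited optimize the configured excited state (otherwise the
#'   ground state)
#' @param fmax force convergence threshold, Hartree/Bohr
#' @param max_steps maximum accepted optimization steps
#' @param trajectory_file optionally, a multi-frame XYZ path to append
#'   accepted geometries to
#' @return list with the optimized `molecule`, final `energy`, `converged`
#'   flag, and a `trajectory` data frame of per-step energies and forces
#' @export
optimize_geometry <- function(molecule, config = run_config(), excited = FALSE,
                              fmax = 4.5e-4, max_steps = 100L,
                              trajectory_file = NULL) {
  x <- as.numeric(t(molecule$coords)) * BOHR_PER_ANGSTROM
  ev <- .evaluate_geometry(x, molecule, config, excited)
  g <- as.numeric(t(ev$gradient))
  n <- length(x)
  h_inv <- diag(n) * 1.0  # initial inverse Hessian (Bohr^2/Hartree scale)
  traj <- data.frame(step = 0L, energy = ev$energy,
                     fmax = max(abs(g)))
  if (!is.null(trajectory_file)) {
    write_xyz(ev$molecule, trajectory_file,
              comment = sprintf("step 0 E = %.8f", ev$energy))
  }
  converged <- max(abs(g)) <= fmax
  step <- 0L
  while (!converged && step < max_steps) {
    step <- step + 1L
    p <- -as.numeric(h_inv %*% g)
    # trust-region style cap on the displacement
    maxdisp <- max(abs(p))
    if (maxdisp > 0.3) p <- p * 0.3 / maxdisp
    alpha <- 1
    repeat {
      ev_new <- tryCatch(
        .evaluate_geometry(x + alpha * p, molecule, config, excited,
                           prev_tvec_ao = ev$tvec_ao),
        coox_state_switch = function(e) e,
        coox_not_converged = function(e) e
      )
      if (inherits(ev_new, "error")) {
        if (alpha < 1e-3) stop(ev_new)
        alpha <- alpha / 2
        next
      }
      if (ev_new$energy <= ev$energy + 1e-4 * alpha * sum(g * p) ||
          alpha < 1e-3) {
        break
      }
      alpha <- alpha / 2
    }
    s_vec <- alpha * p
    g_new <- as.numeric(t(ev_new$gradient))
    y_vec <- g_new - g
    sy <- sum(s_vec * y_vec)
    if (sy > 1e-12) {
      rho <- 1 / sy
      i_n <- diag(n)
      h_inv <- (i_n - rho * outer(s_vec, y_vec)) %*% h_inv %*%
        (i_n - rho * outer(y_vec, s_vec)) + rho * outer(s_vec, s_vec)
    }
    x <- x + s_vec
    ev <- ev_new
    g <- g_new
    traj <- rbind(traj, data.frame(step = step, energy = ev$energy,
                                   fmax = max(abs(g))))
    if (config$verbose) {
      message(sprintf("[opt] step %3d  E = %.8f  fmax = %.2e", step,
                      ev$energy, max(abs(g))))
    }
    if (!is.null(trajectory_file)) {
      write_xyz(ev$molecule, trajectory_file, append = TRUE,
                comment = sprintf("step %d E = %.8f", step, ev$energy))
    }
    converged <- max(abs(g)) <= fmax
  }
  list(molecule = ev$molecule, energy = ev$energy, converged = converged,
       n_steps = step, trajectory = traj,
       solution = ev$solution, ground = ev$ground)
}

#' Validate a gradient against central finite differences
#'
#' Re-solves the constrained problem at displaced geometries with the
#' constraint potential held fixed (the surface the analytic gradient
#' differentiates) and compares component by component.
#'
#' @param solution converged `coox_constrained` (or ground `coox_scf`)
#' @param molecule geometry at the solution
#' @param config run configuration
#' @param step displacement, Bohr
#' @param components optional subset of Cartesian components (indices into
#'   the flattened 3N vector) to check; default all
#' @return list with `analytic`, `numeric` (matrices), `max_deviation`
#' @export
fd_gradient_check <- function(solution, molecule, config = run_config(),
                              step = 1e-3, components = NULL) {
  ana <- nuclear_gradient(solution, molecule, config)$forces
  nat <- length(molecule$atoms)
  num <- matrix(NA_real_, nat, 3)
  idx <- if (is.null(components)) seq_len(3 * nat) else components
  constrained <- inherits(solution, "coox_constrained")
  energy_at <- function(coords_bohr) {
    mol <- molecule_spec(molecule$atoms,
                         matrix(coords_bohr, ncol = 3, byrow = TRUE) /
                           BOHR_PER_ANGSTROM,
                         charge = molecule$charge,
                         spin_multiplicity = molecule$spin_multiplicity)
    if (!constrained) {
      st <- ground_scf(mol, config)
      return(st$energy + st$entropy_term)
    }
    ctx <- build_context(mol, config)
    init <- if (constrained) solution$state else solution
    init$context <- ctx
    sol <- solve_constrained(mol, config, solution$constraints, init)
    sol$state$energy + sol$state$entropy_term
  }
  x0 <- as.numeric(t(molecule$coords)) * BOHR_PER_ANGSTROM
  for (k in idx) {
    xp <- x0
    xp[k] <- xp[k] + step
    xm <- x0
    xm[k] <- xm[k] - step
    num[ceiling(k / 3), ((k - 1) %% 3) + 1] <-
      (energy_at(xp) - energy_at(xm)) / (2 * step)
  }
  dev <- abs(ana - num)
  list(analytic = ana, numeric = num,
       max_deviation = max(dev, na.rm = TRUE))
}
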
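# Post-solution diagnostics: excitation energy, excited-electron count,
# single/double character, difference densities, and the one-call driver.

#' Excitation energy of a constrained solution
#'
#' Difference of the smeared variational energies (electronic energy plus
#' the -T*S_elec entropy term) between the constrained solution and the
#' ground state, in eV.  Both states must share geometry, basis and
#' functional.
#'
#' @param ground the reference `coox_scf`
#' @param solution an `coox_constrained` result
#' @return excitation energy in eV
#' @export
excitation_energy <- function(ground, solution) {
  gctx <- ground$context
  sctx <- solution$state$context
  if (!identical(gctx$geometry_hash, sctx$geometry_hash)) {
    stop(errorCondition("ground and excited states refer to different geometries",
                        class = c("coox_geometry_mismatch", "coox_error")))
  }
  de <- (solution$state$energy + solution$state$entropy_term) -
    (ground$energy + ground$entropy_term)
  de * HARTREE_EV
}

#' Number of excited electrons
#'
#' Projects the constrained total density onto the virtual MO space of the
#' unperturbed ground state:
#' `n_exc = Tr[P_exc S C_virt C_virt^T S]`, alpha and beta summed.
#' The ground and excited determinants are built from different orbital sets
#' and are not mutually orthogonal; the count is reported as is.
#'
#' @param solution an `coox_constrained` result (or any `coox_scf` state)
#' @param ground the reference `coox_scf`
#' @export
excited_electron_count <- function(solution, ground) {
  state <- if (inherits(solution, "coox_constrained")) solution$state else solution
  if (!identical(state$context$geometry_hash, ground$context$geometry_hash)) {
    stop(errorCondition("states do not share a basis/geometry",
                        class = c("coox_geometry_mismatch", "coox_error")))
  }
  s <- ground$context$overlap
  cv <- ground$mo_coeff$alpha[, .virt_idx(ground), drop = FALSE]
  proj <- s %*% cv %*% t(cv) %*% s
  sum((state$density$alpha + state$density$beta) * proj)
}

# spin-resolved variant used by the symmetry diagnostics
.n_exc_by_spin <- function(solution, ground) {
  state <- if (inherits(solution, "coox_constrained")) solution$state else solution
  s <- ground$context$overlap
  cv <- ground$mo_coeff$alpha[, .virt_idx(ground), drop = FALSE]
  proj <- s %*% cv %*% t(cv) %*% s
  c(alpha = sum(state$density$alpha * proj),
    beta = sum(state$density$beta * proj))
}

#' Single- and double-excitation character
#'
#' Solves the two-equation system `T1 + T2 = 100` and
#' `T1 + 2 T2 = 100 n_exc`: the percentages interpolate between a pure
#' single excitation (`n_exc = 1`) and a pure double (`n_exc = 2`).
#' For `n_exc < 1` the negative double share is clamped to zero and the
#' result flagged.
#'
#' @param n_exc excited-electron count in `[0, 2]`
#' @return list with `pct_t1`, `pct_t2`, `clamped`
#' @export
single_double_character <- function(n_exc) {
  if (!is.finite(n_exc) || n_exc < 0 || n_exc > 2) {
    stop(errorCondition(
      sprintf("n_exc = %g outside [0, 2]", n_exc),
      class = c("coox_bad_nexc", "coox_error")
    ))
  }
  t2 <- 100 * (n_exc - 1)
  t1 <- 100 * (2 - n_exc)
  clamped <- FALSE
  if (t2 < 0) {
    t2 <- 0
    t1 <- 100
    clamped <- TRUE
  }
  list(pct_t1 = t1, pct_t2 = t2, clamped = clamped)
}

#' Difference density on a real-space grid
#'
#' `dP = P_excited - P_ground` evaluated on the grid points; the integral
#' over space vanishes by electron conservation (a warning flags grids too
#' coarse to resolve that).
#'
#' @param solution an `coox_constrained` result
#' @param ground the reference `coox_scf`
#' @param grid a [grid_spec()]
#' @return numeric field in cube data order, with attribute `integral`
#' @export
difference_density <- function(solution, ground, grid) {
  state <- solution$state
  if (!identical(state$context$geometry_hash, ground$context$geometry_hash)) {
    stop(errorCondition("states do not share a basis/geometry",
                        class = c("coox_geometry_mismatch", "coox_error")))
  }
  dp <- (state$density$alpha + state$density$beta) -
    (ground$density$alpha + ground$density$beta)
  pts <- grid_points(grid)
  field <- density_on_points(ground$context, dp, pts)
  vox <- abs(det(grid$axes))
  integral <- sum(field) * vox
  if (abs(integral) > 1e-3) {
    warning(sprintf(
      "difference density integrates to %.2e electrons; grid too coarse", integral))
  }
  attr(field, "integral") <- integral
  field
}

#' Assemble an excitation report
#'
#' @param ground reference `coox_scf`
#' @param solution converged `coox_constrained`
#' @param config the [run_config()] used
#' @param scaled_used whether the scaled constraint produced the solution
#' @return a `coox_report` (serializable with [report_json()])
#' @export
excitation_report <- function(ground, solution, config, scaled_used = FALSE) {
  n_exc <- excited_electron_count(solution, ground)
  sd <- single_double_character(min(max(n_exc, 0), 2))
  de <- excitation_energy(ground, solution)
  collapsed <- n_exc < 0.1 && de < 0.1
  structure(
    list(
      schema_version = REPORT_SCHEMA_VERSION,
      delta_e_ev = de,
      lambda_c = solution$lambdas,
      n_exc = n_exc,
      pct_t1 = sd$pct_t1,
      pct_t2 = sd$pct_t2,
      method = config$method,
      functional = config$functional,
      basis = config$basis,
      spin_type = config$spin_channel,
      scaled_used = scaled_used,
      residual = max(solution$constraint_residuals),
      commutator_norm = solution$commutator_norm,
      macro_iterations = solution$macro_iterations,
      micro_iterations = solution$micro_iterations_total,
      converged = solution$converged,
      collapsed = collapsed
    ),
    class = "coox_report"
  )
}

#' @export
print.coox_report <- function(x, ...) {
  cat(sprintf("Excitation report (%s, %s/%s, %s)\n", x$method, x$functional,
              x$basis, x$spin_type))
  cat(sprintf("  dE      = %.4f eV\n", x$delta_e_ev))
  cat(sprintf("  lambda  = %s Ha\n",
              paste(sprintf("%.6f", x$lambda_c), collapse = " ")))
  cat(sprintf("  n_exc   = %.4f  (%%T1 = %.1f, %%T2 = %.1f)\n", x$n_exc,
              x$pct_t1, x$pct_t2))
  cat(sprintf("  residual %.1e, |[F,P]| %.1e, %d macro cycles, %s\n",
              x$residual, x$commutator_norm, x$macro_iterations,
              if (x$converged) "converged" else "NOT converged"))
  invisible(x)
}

#' One-call excited-state calculation
#'
#' Runs the full pipeline: ground-state SCF, Tamm-Dancoff linear response,
#' constraint construction for the configured method, and the constrained
#' SCF.  With `method = "coox_auto"` the unscaled constraint is tried first
#' and the scaled variant substituted when the excited-electron count
#' deviates from one by more than `auto_switch_tol`.
#'
#' @param molecule a [molecule_spec()]
#' @param config a [run_config()]
#' @param tvec optionally an externally computed [transition_vector()]
#'   (e.g. imported simplified-TDA amplitudes) overriding the internal solver
#' @return list with `ground`, `tvec`, `solution`, `report`
#' @export
excite <- function(molecule, config = run_config(), tvec = NULL) {
  ground <- ground_scf(molecule, config)
  spin_type <- if (config$spin_channel == "triplet") "triplet" else "singlet"
  if (is.null(tvec)) {
    n_states <- if (is.null(config$n_states)) {
      max(config$state_index, 3L)
    } else config$n_states
    states <- tda_solve(ground, config, n_states = n_states,
                        spin_type = spin_type)
    if (config$state_index > length(states)) {
      stop(errorCondition("state_index exceeds the number of solved states",
                          class = c("coox_bad_config", "coox_error")))
    }
    tvec <- states[[config$state_index]]
  }

  run_one <- function(scaled) {
    if (config$method == "xcdft") {
      cons <- xcdft_constraint(ground)
      init <- .alpha_promoted_guess(ground)
      return(solve_constrained(molecule, config, cons, init))
    }
    if (config$method == "tcdft") {
      cons <- tcdft_constraints(tvec, ground,
                                threshold = config$tcdft_threshold,
                                use_nto = TRUE)
      return(solve_constrained(molecule, config, cons, ground))
    }
    build <- if (scaled) scaled_coox_constraint else coox_constraint
    if (config$spin_channel == "triplet") {
      ts <- triplet_setup(ground, tvec)
      cons <- build(ground, tvec, spin_mask = "both")
      solve_constrained(molecule, config, cons, ts$initial_state)
    } else if (config$spin_channel == "singlet_unrestricted_alpha") {
      cons <- build(ground, tvec, spin_mask = "alpha_only")
      solve_constrained(molecule, config, cons, .alpha_promoted_guess(ground))
    } else {
      cons <- build(ground, tvec, spin_mask = "both")
      solve_constrained(molecule, config, cons, ground)
    }
  }

  scaled <- config$method == "coox_scaled"
  sol <- run_one(scaled)
  if (config$method == "coox_auto") {
    n_exc <- excited_electron_count(sol, ground)
    if (abs(n_exc - 1) > config$auto_switch_tol) {
      if (config$verbose) {
        message(sprintf(
          "n_exc = %.3f deviates from 1 by more than %.0f%%; switching to the scaled constraint",
          n_exc, 100 * config$auto_switch_tol))
      }
      sol <- run_one(TRUE)
      scaled <- TRUE
    }
  }
  list(ground = ground, tvec = tvec, solution = sol,
       report = excitation_report(ground, sol, config, scaled_used = scaled))
}

# unrestricted initial guess from restricted ground orbitals (x-cDFT and the
# alpha-only fallback start from the plain ground density)
.alpha_promoted_guess <- function(ground) {
  st <- ground
  st$restricted <- FALSE
  st
}
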
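# Constraint potentials: COOX (plain and scaled), x-cDFT, t-cDFT, triplet
# setup.  All potentials are stored in the covariant AO representation, i.e.
# MO-space blocks are sandwiched as S C (block) C^T S so that constraint
# values are plain traces Tr[P W] against contravariant densities and count
# electrons.

#' Constraint specification
#'
#' @param w_matrix symmetric covariant AO constraint potential
#' @param n_target constraint constant (electrons)
#' @param spin_mask `"both"` or `"alpha_only"`
#' @param scale_f_v virtual-block scale factor (1 for unscaled)
#' @param parts list retaining the covariant occupied/virtual blocks
#' @param kind `"coox"`, `"xcdft"` or `"tcdft_term"`
#' @export
constraint_spec <- function(w_matrix, n_target, spin_mask = "both",
                            scale_f_v = 1, parts = list(), kind = "coox") {
  asym <- max(abs(w_matrix - t(w_matrix)))
  if (asym > 1e-10) {
    stop(errorCondition(
      sprintf("constraint potential asymmetric (max dev %.2e)", asym),
      class = c("coox_bad_constraint", "coox_error")
    ))
  }
  structure(
    list(w_matrix = (w_matrix + t(w_matrix)) / 2, n_target = n_target,
         spin_mask = spin_mask, scale_f_v = scale_f_v, parts = parts,
         kind = kind),
    class = "coox_constraint"
  )
}

#' Metric-weighted trace of a covariant AO matrix
#'
#' For a covariant potential `W = S C B C^T S` this recovers the MO-space
#' trace of the block `B`, i.e. the electron count the potential represents.
#'
#' @param w covariant AO matrix
#' @param overlap the AO overlap (metric)
#' @export
metric_trace <- function(w, overlap) {
  sum(diag(solve(overlap, w)))
}

# covariant projections of the difference-density blocks for a transition
# vector X (virt x occ):  virtual block X X^T, occupied block X^T X
.coox_parts <- function(ground, tvec) {
  occ <- .occ_idx(ground)
  virt <- .virt_idx(ground)
  x <- tvec$amplitudes
  if (nrow(x) != length(virt) || ncol(x) != length(occ)) {
    stop(errorCondition("amplitude dimensions do not match the MO partition",
                        class = c("coox_dimension_mismatch", "coox_error")))
  }
  if (abs(sqrt(sum(x^2)) - 1) > 1e-8) {
    stop(errorCondition("transition vector is not Frobenius-normalized",
                        class = c("coox_bad_amplitudes", "coox_error")))
  }
  s <- ground$context$overlap
  co <- ground$mo_coeff$alpha[, occ, drop = FALSE]
  cv <- ground$mo_coeff$alpha[, virt, drop = FALSE]
  list(
    dp_virt = s %*% cv %*% (x %*% t(x)) %*% t(cv) %*% s,
    dp_occ = s %*% co %*% (t(x) %*% x) %*% t(co) %*% s
  )
}

#' COOX constraint potential
#'
#' The combined constraint `W_c = dP_virt - dP_occ` built from the static
#' occupied-occupied and virtual-virtual blocks of the linear-response
#' difference density: an expulsion of one electron from the hole image and
#' an admittance of one electron into the particle image.  `Tr[P W_c]`
#' therefore measures (electrons in the particle image) minus (electrons
#' remaining in the hole image); the combined target is 0 when both spins are
#' constrained and 1 for the alpha-only fallback.
#'
#' @param ground converged integer-occupation `coox_scf`
#' @param tvec a [transition_vector()] referenced to `ground`
#' @param spin_mask `"both"` (restricted singlet / triplet) or `"alpha_only"`
#' @return a [constraint_spec()]
#' @export
coox_constraint <- function(ground, tvec, spin_mask = "both") {
  parts <- .coox_parts(ground, tvec)
  constraint_spec(parts$dp_virt - parts$dp_occ,
                  n_target = if (spin_mask == "both") 0 else 1,
                  spin_mask = spin_mask, scale_f_v = 1, parts = parts,
                  kind = "coox")
}

#' Scaled COOX constraint potential
#'
#' Multiplies the virtual block by the factor
#' `f_V = (2 - t) / t`, `t = Tr[(X^T X)^2]`,
#' chosen so that the trace of the modified potential against the
#' linear-response excited-state density (occupied block `2I - X^T X`,
#' virtual block `X X^T`) reproduces the constraint target.  For a rank-1
#' amplitude matrix `f_V = 1` (the unscaled case); for transitions spread
#' over degenerate orbital pairs `f_V > 1`, which restores a finite frontier
#' gap and a single-electron excitation in the restricted solution.
#'
#' @inheritParams coox_constraint
#' @export
scaled_coox_constraint <- function(ground, tvec, spin_mask = "both") {
  parts <- .coox_parts(ground, tvec)
  x <- tvec$amplitudes
  t4 <- sum((t(x) %*% x) * (t(x) %*% x))  # Tr[(X^T X)^2] = sum of sigma^4
  f_v <- (2 - t4) / t4
  if (!is.finite(f_v) || f_v <= 0) {
    stop(errorCondition(
      sprintf("scale factor f_V = %g is not usable (degenerate amplitudes)", f_v),
      class = c("coox_bad_constraint", "coox_error")
    ))
  }
  constraint_spec(f_v * parts$dp_virt - parts$dp_occ,
                  n_target = if (spin_mask == "both") 0 else 1,
                  spin_mask = spin_mask, scale_f_v = f_v, parts = parts,
                  kind = "coox")
}

#' Linear-response consistency trace of a COOX constraint
#'
#' Evaluates `Tr[P1 W] - N_c` where `P1` is the TDA excited-state density
#' assembled on top of the ground density (occupied block depleted by
#' `X^T X`, virtual block populated by `X X^T`).  Vanishes by construction
#' for the scaled constraint and for rank-1 amplitudes in the unscaled case.
#'
#' @param constraint a [constraint_spec()] from [coox_constraint()] or
#'   [scaled_coox_constraint()]
#' @param ground the reference ground state
#' @param tvec the transition vector that built the constraint
#' @export
lr_consistency_trace <- function(constraint, ground, tvec) {
  occ <- .occ_idx(ground)
  virt <- .virt_idx(ground)
  x <- tvec$amplitudes
  co <- ground$mo_coeff$alpha[, occ, drop = FALSE]
  cv <- ground$mo_coeff$alpha[, virt, drop = FALSE]
  p0 <- ground$density$alpha + ground$density$beta
  p1 <- p0 + cv %*% (x %*% t(x)) %*% t(cv) - co %*% (t(x) %*% x) %*% t(co)
  if (constraint$spin_mask == "alpha_only") {
    # single-spin bookkeeping: the alpha density carries the whole transition
    p1 <- ground$density$alpha + cv %*% (x %*% t(x)) %*% t(cv) -
      co %*% (t(x) %*% x) %*% t(co)
  }
  sum(p1 * constraint$w_matrix) - constraint$n_target
}

#' x-cDFT constraint potential
#'
#' The covariant projector onto the ground-state virtual MO space,
#' `W_c = S C_virt C_virt^T S`, applied to the alpha channel only with
#' target `N_c = 1`: it forces one alpha electron into the virtual space of
#' the unperturbed ground state.  At the solution, `-lambda_c` estimates the
#' excitation energy (the work of moving the electron across the gap).
#'
#' @param ground converged integer-occupation `coox_scf`
#' @export
xcdft_constraint <- function(ground) {
  virt <- .virt_idx(ground)
  if (length(virt) == 0) {
    stop(errorCondition("no virtual orbitals to constrain",
                        class = c("coox_bad_constraint", "coox_error")))
  }
  s <- ground$context$overlap
  cv <- ground$mo_coeff$alpha[, virt, drop = FALSE]
  constraint_spec(s %*% cv %*% t(cv) %*% s, n_target = 1,
                  spin_mask = "alpha_only", kind = "xcdft")
}

#' t-cDFT constraint set
#'
#' One symmetrized dyadic constraint per retained transition amplitude (or
#' per retained natural-transition-orbital pair), each built from a hole and
#' a particle MO vector.  Amplitudes (or NTO weights) below the threshold are
#' dropped and the surviving coefficients renormalized so their squares sum
#' to one: the retained set then represents a single electron excitation.
#'
#' @param tvec a [transition_vector()]
#' @param ground the reference ground state
#' @param threshold retention threshold on |amplitude| (or on NTO weight)
#' @param use_nto draw the constraints from natural transition orbitals
#' @return list of [constraint_spec()]s (`kind = "tcdft_term"`)
#' @export
tcdft_constraints <- function(tvec, ground, threshold = 0.1, use_nto = FALSE) {
  s <- ground$context$overlap
  occ <- .occ_idx(ground)
  virt <- .virt_idx(ground)
  specs <- list()
  if (use_nto) {
    nto <- nto_decompose(tvec, ground)
    keep <- which(nto$weights >= threshold)
    if (length(keep) == 0) {
      stop(errorCondition("no NTO pair survives the threshold",
                          class = c("coox_bad_constraint", "coox_error")))
    }
    coef <- nto$singular_values[keep]
    coef <- coef / sqrt(sum(coef^2))
    for (k in seq_along(keep)) {
      h <- nto$hole_orbitals[, keep[k], drop = FALSE]
      p <- nto$particle_orbitals[, keep[k], drop = FALSE]
      w <- s %*% (h %*% t(p) + p %*% t(h)) %*% s
      specs[[k]] <- constraint_spec(w, n_target = coef[k],
                                    spin_mask = "both",
                                    kind = "tcdft_term")
    }
  } else {
    x <- tvec$amplitudes
    keep <- which(abs(x) >= threshold, arr.ind = TRUE)
    if (nrow(keep) == 0) {
      stop(errorCondition("no amplitude survives the threshold",
                          class = c("coox_bad_constraint", "coox_error")))
    }
    coef <- x[keep]
    coef <- coef / sqrt(sum(coef^2))
    co <- ground$mo_coeff$alpha[, occ, drop = FALSE]
    cv <- ground$mo_coeff$alpha[, virt, drop = FALSE]
    for (k in seq_len(nrow(keep))) {
      h <- co[, keep[k, "col"], drop = FALSE]   # occupied index i
      p <- cv[, keep[k, "row"], drop = FALSE]   # virtual index a
      w <- s %*% (h %*% t(p) + p %*% t(h)) %*% s
      specs[[k]] <- constraint_spec(w, n_target = coef[k],
                                    spin_mask = "both",
                                    kind = "tcdft_term")
    }
  }
  specs
}

#' Initial state and constraint for a triplet COOX solve
#'
#' Promotes one beta electron to alpha (N_alpha = N/2 + 1,
#' N_beta = N/2 - 1) on top of the restricted ground orbitals and builds the
#' COOX constraint from a restricted triplet transition vector, applied to
#' both spin channels.
#'
#' @param ground converged restricted `coox_scf`
#' @param tvec triplet [transition_vector()] from [tda_solve()]
#' @return list with `initial_state` (unrestricted, aufbau-promoted) and
#'   `constraint`
#' @export
triplet_setup <- function(ground, tvec) {
  n <- ground$context$molecule$n_electrons
  if (n < 2) {
    stop(errorCondition("triplet promotion needs at least two electrons",
                        class = c("coox_bad_multiplicity", "coox_error")))
  }
  na <- n / 2 + 1
  nb <- n / 2 - 1
  occ_a <- rep(0, ground$context$n_ao)
  occ_a[seq_len(na)] <- 1
  occ_b <- rep(0, ground$context$n_ao)
  if (nb > 0) occ_b[seq_len(nb)] <- 1
  st <- ground
  st$restricted <- FALSE
  st$occupations <- list(alpha = occ_a, beta = occ_b)
  st$density <- list(
    alpha = .density_from(ground$mo_coeff$alpha, occ_a),
    beta = .density_from(ground$mo_coeff$beta, occ_b)
  )
  st$n_spin <- c(alpha = na, beta = nb)
  list(initial_state = st,
       constraint = coox_constraint(ground, tvec, spin_mask = "both"))
}
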
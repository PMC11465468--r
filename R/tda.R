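# Tamm-Dancoff linear response: the source of the transition vectors that
# seed every constraint, plus the natural-transition-orbital decomposition.

# full MO-basis two-electron tensor (pq|rs) by four quarter transforms
.mo_eri <- function(context, coeff) {
  n <- context$n_ao
  t1 <- matrix(aperm(context$eri, c(2, 3, 4, 1)), n^3, n) %*% coeff
  t1 <- array(t1, c(n, n, n, n))              # [nu, la, si, p]
  t2 <- matrix(aperm(t1, c(2, 3, 4, 1)), n^3, n) %*% coeff
  t2 <- array(t2, c(n, n, n, n))              # [la, si, p, q]
  t3 <- matrix(aperm(t2, c(2, 3, 4, 1)), n^3, n) %*% coeff
  t3 <- array(t3, c(n, n, n, n))              # [si, p, q, r]
  t4 <- matrix(aperm(t3, c(2, 3, 4, 1)), n^3, n) %*% coeff
  array(t4, c(n, n, n, n))                    # [p, q, r, s] = (pq|rs)
}

#' Transition-vector container
#'
#' Amplitudes are stored as a (n_virt x n_occ) matrix `X[a, i]` with unit
#' Frobenius norm, referenced to the occupied/virtual partition of the ground
#' state that produced them.
#'
#' @param amplitudes n_virt x n_occ amplitude matrix
#' @param omega excitation energy in Hartree
#' @param spin_type `"singlet"` or `"triplet"`
#' @param source `"tda"` or `"imported"`
#' @param state_index 1-based index of the state
#' @export
transition_vector <- function(amplitudes, omega = NA_real_,
                              spin_type = "singlet", source = "imported",
                              state_index = 1L) {
  amplitudes <- as.matrix(amplitudes)
  nrm <- sqrt(sum(amplitudes^2))
  if (!is.finite(nrm) || nrm < 1e-8) {
    stop(errorCondition("transition amplitudes have (near) zero norm",
                        class = c("coox_bad_amplitudes", "coox_error")))
  }
  structure(
    list(amplitudes = amplitudes / nrm, omega = omega, spin_type = spin_type,
         source = source, state_index = as.integer(state_index)),
    class = "coox_tvec"
  )
}

#' @export
print.coox_tvec <- function(x, ...) {
  cat(sprintf("<transition vector: state %d (%s), omega = %.6f Ha, %d x %d>\n",
              x$state_index, x$spin_type, x$omega, nrow(x$amplitudes),
              ncol(x$amplitudes)))
  invisible(x)
}

#' Tamm-Dancoff linear-response solver
#'
#' Builds the TDA response matrix in the occupied -> virtual product space of
#' a converged integer-occupation ground state and diagonalizes it (dense).
#' At the Hartree-Fock level this is configuration interaction singles.
#' Singlet coupling: `2 (ia|jb) - (ij|ab)`; triplet: `-(ij|ab)`.
#'
#' @param ground a converged restricted `coox_scf` with integer occupations
#' @param config a [run_config()]
#' @param n_states number of lowest states to return
#' @param spin_type `"singlet"` or `"triplet"` excitation block
#' @return list of [transition_vector()]s, lowest first
#' @export
tda_solve <- function(ground, config = run_config(), n_states = 3L,
                      spin_type = c("singlet", "triplet")) {
  spin_type <- match.arg(spin_type)
  if (!ground$converged) {
    stop(errorCondition("ground state is not converged",
                        class = c("coox_not_converged", "coox_error")))
  }
  if (ground$smearing || any(!ground$occupations$alpha %in% c(0, 1))) {
    stop(errorCondition("TDA reference needs integer occupations",
                        class = c("coox_bad_occupation", "coox_error")))
  }
  ctx <- ground$context
  occ <- .occ_idx(ground)
  virt <- .virt_idx(ground)
  no <- length(occ)
  nv <- length(virt)
  if (no == 0 || nv == 0) {
    stop(errorCondition("occupied/virtual partition is empty",
                        class = c("coox_bad_occupation", "coox_error")))
  }
  eps <- ground$mo_energy$alpha
  mo <- .mo_eri(ctx, ground$mo_coeff$alpha)

  dim_ov <- no * nv
  a <- matrix(0, dim_ov, dim_ov)
  idx <- function(i, a_) (i - 1L) * nv + a_   # i slow, a fast
  for (i in seq_len(no)) {
    for (av in seq_len(nv)) {
      r <- idx(i, av)
      for (j in seq_len(no)) {
        for (bv in seq_len(nv)) {
          cpl <- -mo[occ[i], occ[j], virt[av], virt[bv]]
          if (spin_type == "singlet") {
            cpl <- cpl + 2 * mo[occ[i], virt[av], occ[j], virt[bv]]
          }
          a[r, idx(j, bv)] <- cpl
        }
      }
      a[r, r] <- a[r, r] + eps[virt[av]] - eps[occ[i]]
    }
  }
  ev <- eigen((a + t(a)) / 2, symmetric = TRUE)
  ord <- order(ev$values)
  n_states <- min(n_states, dim_ov)
  out <- vector("list", n_states)
  for (s in seq_len(n_states)) {
    w <- ev$values[ord[s]]
    if (w < 0) {
      warning(sprintf("TDA state %d has negative eigenvalue %.6f Ha (instability)",
                      s, w))
    }
    vec <- ev$vectors[, ord[s]]
    x <- matrix(vec, nrow = nv, ncol = no)  # X[a, i]
    # deterministic sign: largest-magnitude amplitude positive
    k <- which.max(abs(x))
    if (x[k] < 0) x <- -x
    out[[s]] <- transition_vector(x, omega = w, spin_type = spin_type,
                                  source = "tda", state_index = s)
  }
  out
}

#' Export a transition vector as a plain-text amplitude table
#'
#' Format: header lines with state index, spin and energy, then rows
#' `occ_index virt_index amplitude` (1-based, referenced to the ground-state
#' MO ordering).  This file format is the bridge for amplitudes computed by
#' external simplified-TDA programs.
#'
#' @param tvec a [transition_vector()]
#' @param path output file
#' @param threshold amplitudes below this magnitude are not written
#' @export
export_transition_vector <- function(tvec, path, threshold = 0) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("# cooxr transition vector v1",
               sprintf("# state %d spin %s omega %.16e",
                       tvec$state_index, tvec$spin_type, tvec$omega),
               sprintf("# dims %d %d", ncol(tvec$amplitudes),
                       nrow(tvec$amplitudes))), con)
  x <- tvec$amplitudes
  for (i in seq_len(ncol(x))) {
    for (a in seq_len(nrow(x))) {
      if (abs(x[a, i]) > threshold) {
        writeLines(sprintf("%d %d %.16e", i, a, x[a, i]), con)
      }
    }
  }
  invisible(NULL)
}

#' Import a transition vector from an amplitude table
#'
#' @param path file in the layout of [export_transition_vector()]
#' @param ground the ground `coox_scf` the amplitudes refer to
#' @return a [transition_vector()] with Frobenius-normalized amplitudes
#' @export
import_transition_vector <- function(path, ground) {
  lines <- readLines(path)
  header <- lines[startsWith(lines, "#")]
  body <- lines[!startsWith(lines, "#") & nzchar(trimws(lines))]
  no <- length(.occ_idx(ground))
  nv <- length(.virt_idx(ground))
  omega <- NA_real_
  spin <- "singlet"
  state <- 1L
  hs <- grep("^# state ", header, value = TRUE)
  if (length(hs) == 1) {
    tk <- strsplit(trimws(hs), "[[:space:]]+")[[1]]
    state <- as.integer(tk[3])
    spin <- tk[5]
    omega <- as.numeric(tk[7])
  }
  x <- matrix(0, nv, no)
  for (ln in body) {
    tk <- strsplit(trimws(ln), "[[:space:]]+")[[1]]
    i <- as.integer(tk[1])
    a <- as.integer(tk[2])
    if (is.na(i) || is.na(a) || i < 1 || i > no || a < 1 || a > nv) {
      stop(errorCondition(
        sprintf("amplitude row '%s' does not fit a %d-occupied / %d-virtual reference",
                ln, no, nv),
        class = c("coox_dimension_mismatch", "coox_error")
      ))
    }
    x[a, i] <- as.numeric(tk[3])
  }
  transition_vector(x, omega = omega, spin_type = spin, source = "imported",
                    state_index = state)
}

#' Natural transition orbitals of a transition vector
#'
#' Singular value decomposition of the amplitude matrix; hole (occupied-space)
#' and particle (virtual-space) orbitals are the correspondingly rotated
#' ground-state MOs, and the weights are the squared singular values.
#'
#' @param tvec a [transition_vector()]
#' @param ground the ground `coox_scf` the amplitudes refer to
#' @return list with `hole_orbitals`, `particle_orbitals` (AO coefficients),
#'   `weights` (descending, summing to 1) and `singular_values`
#' @export
nto_decompose <- function(tvec, ground) {
  occ <- .occ_idx(ground)
  virt <- .virt_idx(ground)
  x <- tvec$amplitudes
  if (nrow(x) != length(virt) || ncol(x) != length(occ)) {
    stop(errorCondition("amplitude dimensions do not match the MO partition",
                        class = c("coox_dimension_mismatch", "coox_error")))
  }
  sv <- svd(x)
  list(
    hole_orbitals = ground$mo_coeff$alpha[, occ, drop = FALSE] %*% sv$v,
    particle_orbitals = ground$mo_coeff$alpha[, virt, drop = FALSE] %*% sv$u,
    weights = sv$d^2,
    singular_values = sv$d
  )
}
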
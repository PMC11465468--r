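test_that("one-pair system reproduces the closed-form CIS energies", {
  # H2/minimal basis has a single occupied-virtual pair: the TDA matrix is
  # 1x1 with the textbook closed forms
  st <- h2_ground()
  ctx <- st$context
  cc <- st$mo_coeff$alpha
  mo <- function(p, q, r, s) {
    val <- 0
    for (mu in 1:2) for (nu in 1:2) for (la in 1:2) for (si in 1:2) {
      val <- val + cc[mu, p] * cc[nu, q] * cc[la, r] * cc[si, s] *
        ctx$eri[mu, nu, la, si]
    }
    val
  }
  de <- st$mo_energy$alpha[2] - st$mo_energy$alpha[1]
  w_singlet <- de + 2 * mo(1, 2, 1, 2) - mo(1, 1, 2, 2)
  w_triplet <- de - mo(1, 1, 2, 2)

  cfg <- base_config()
  ts <- tda_solve(st, cfg, n_states = 1, spin_type = "singlet")[[1]]
  tt <- tda_solve(st, cfg, n_states = 1, spin_type = "triplet")[[1]]
  expect_equal(ts$omega, w_singlet, tolerance = 1e-10)
  expect_equal(tt$omega, w_triplet, tolerance = 1e-10)
  expect_lte(tt$omega, ts$omega)  # exchange splitting is nonnegative at HF
  expect_equal(sqrt(sum(ts$amplitudes^2)), 1, tolerance = 1e-12)
})

test_that("dense TDA eigenvalues match an explicit-loop oracle on water", {
  st <- h2o_ground()
  a <- cached("h2o_tda_oracle", oracle_tda_matrix(st, "singlet"))
  ev <- sort(eigen((a + t(a)) / 2, symmetric = TRUE)$values)
  states <- cached("h2o_tda5",
                   tda_solve(st, base_config(), n_states = 5))
  for (s in 1:5) {
    expect_equal(states[[s]]$omega, ev[s], tolerance = 1e-8)
    expect_equal(sqrt(sum(states[[s]]$amplitudes^2)), 1, tolerance = 1e-8)
  }
})

test_that("TDA spectra are invariant under rotations of degenerate orbitals", {
  # H6 ring: doubly degenerate HOMO pair; mixing the two occupied partners
  # by any unitary must leave the response spectrum unchanged
  mol <- molecule_h6_ring(1.0)
  st <- cached("h6_ground", ground_scf(mol, base_config()))
  deg <- c(2, 3)                       # degenerate occupied pair
  expect_lt(abs(st$mo_energy$alpha[2] - st$mo_energy$alpha[3]), 1e-8)
  th <- 0.6154797
  u <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
  rot <- st
  rot$mo_coeff$alpha[, deg] <- st$mo_coeff$alpha[, deg] %*% u
  rot$mo_coeff$beta <- rot$mo_coeff$alpha
  w0 <- vapply(tda_solve(st, base_config(), n_states = 4),
               function(x) x$omega, numeric(1))
  w1 <- vapply(tda_solve(rot, base_config(), n_states = 4),
               function(x) x$omega, numeric(1))
  expect_equal(w0, w1, tolerance = 1e-8)
})

test_that("transition vectors export and import faithfully", {
  st <- h2o_ground()
  tv <- cached("h2o_tda5", tda_solve(st, base_config(), n_states = 5))[[2]]
  tmp <- withr::local_tempfile(fileext = ".tv")
  export_transition_vector(tv, tmp)
  back <- import_transition_vector(tmp, st)
  expect_lt(max(abs(back$amplitudes - tv$amplitudes)), 1e-12)
  expect_equal(back$omega, tv$omega, tolerance = 1e-12)
  expect_equal(back$state_index, tv$state_index)

  # single-amplitude file: one nonzero entry, HOMO -> LUMO
  writeLines(c("# cooxr transition vector v1",
               "# state 1 spin singlet omega 5.0e-01",
               "5 1 1.0"), tmp)
  single <- import_transition_vector(tmp, st)
  expect_equal(sum(single$amplitudes != 0), 1)
  expect_equal(single$amplitudes[1, 5], 1)

  # amplitudes (0.6, 0.8) are already unit norm and stay unchanged
  writeLines(c("5 1 0.6", "4 1 0.8"), tmp)
  two <- import_transition_vector(tmp, st)
  expect_equal(two$amplitudes[1, 5], 0.6, tolerance = 1e-12)
  expect_equal(two$amplitudes[1, 4], 0.8, tolerance = 1e-12)

  writeLines("9 5 1.0", tmp)  # virtual index out of range (2 virtuals)
  expect_error(import_transition_vector(tmp, st),
               class = "coox_dimension_mismatch")
  writeLines("1 1 1e-12", tmp)
  expect_error(import_transition_vector(tmp, st),
               class = "coox_bad_amplitudes")
})

test_that("NTO decomposition has the SVD structure and conserves weight", {
  st <- h2o_ground()
  no <- 5
  nv <- 2

  # rank-1 amplitude: a single NTO pair with weight 1
  x <- matrix(0, nv, no)
  x[1, 5] <- 1
  nto <- nto_decompose(transition_vector(x), st)
  expect_equal(nto$weights[1], 1, tolerance = 1e-12)

  # two equal disjoint amplitudes: weights 1/2 each
  x <- matrix(0, nv, no)
  x[1, 5] <- x[2, 4] <- 1 / sqrt(2)
  nto <- nto_decompose(transition_vector(x), st)
  expect_equal(nto$weights[1:2], c(0.5, 0.5), tolerance = 1e-12)

  # random amplitudes: reconstruction, weight sum, S-orthonormality
  tv <- random_transition_vector(no, nv, seed = 11)
  nto <- nto_decompose(tv, st)
  expect_equal(sum(nto$weights), 1, tolerance = 1e-8)
  s <- st$context$overlap
  hh <- t(nto$hole_orbitals) %*% s %*% nto$hole_orbitals
  pp <- t(nto$particle_orbitals) %*% s %*% nto$particle_orbitals
  expect_lt(max(abs(hh - diag(nrow(hh)))), 1e-8)
  expect_lt(max(abs(pp - diag(nrow(pp)))), 1e-8)
  # X = sum_k sigma_k u_k v_k^T in the MO representation
  occ <- which(st$occupations$alpha > 0.5)
  virt <- which(st$occupations$alpha <= 0.5)
  co <- st$mo_coeff$alpha[, occ]
  cv <- st$mo_coeff$alpha[, virt]
  u <- t(cv) %*% s %*% nto$particle_orbitals
  v <- t(co) %*% s %*% nto$hole_orbitals
  recon <- u %*% diag(sqrt(nto$weights)) %*% t(v)
  expect_lt(max(abs(recon - tv$amplitudes)), 1e-10)
})
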
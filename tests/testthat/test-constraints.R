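test_that("COOX constraint has the projector structure for a pure transition", {
  st <- h2_ground()
  x <- matrix(1, 1, 1)           # HOMO -> LUMO, single unit amplitude
  cs <- coox_constraint(st, transition_vector(x))
  # MO representation: -1 on the hole, +1 on the particle
  w_mo <- t(st$mo_coeff$alpha) %*% cs$w_matrix %*% st$mo_coeff$alpha
  expect_equal(diag(w_mo), c(-1, 1), tolerance = 1e-10)
  expect_lt(max(abs(w_mo - diag(diag(w_mo)))), 1e-10)
  # the alpha ground density sits entirely in the hole image
  expect_equal(sum(st$density$alpha * cs$w_matrix), -1, tolerance = 1e-10)
  expect_equal(cs$n_target, 0)
})

test_that("constraint algebra holds for arbitrary normalized amplitudes", {
  ref <- synthetic_reference_state(3, 4, seed = 42)
  s <- ref$context$overlap
  for (k in 1:10) {
    tv <- random_transition_vector(3, 4, seed = 100 + k)
    cs <- coox_constraint(ref, tv)
    expect_lt(abs(metric_trace(cs$parts$dp_virt, s) - 1), 1e-10)
    expect_lt(abs(metric_trace(cs$parts$dp_occ, s) - 1), 1e-10)
    expect_lt(abs(metric_trace(cs$w_matrix, s)), 1e-10)
  }
  # unnormalized amplitudes are rejected at the constraint boundary
  tv <- random_transition_vector(3, 4)
  tv$amplitudes <- tv$amplitudes * 2
  expect_error(coox_constraint(ref, tv), class = "coox_bad_amplitudes")
})

test_that("scaled constraint satisfies the linear-response consistency trace", {
  ref <- synthetic_reference_state(3, 4, seed = 42)

  # rank-1 amplitude: f_V = 1 and the unscaled constraint is already consistent
  x <- matrix(0, 4, 3)
  x[2, 1] <- 1
  tv1 <- transition_vector(x)
  sc1 <- scaled_coox_constraint(ref, tv1)
  expect_equal(sc1$scale_f_v, 1, tolerance = 1e-12)
  expect_lt(abs(lr_consistency_trace(sc1, ref, tv1)), 1e-10)

  # generic multi-configurational amplitudes
  for (k in 1:5) {
    tv <- random_transition_vector(3, 4, seed = 200 + k)
    sc <- scaled_coox_constraint(ref, tv)
    expect_gt(sc$scale_f_v, 1)
    expect_lt(abs(lr_consistency_trace(sc, ref, tv)), 1e-10)
    # forcing f_V = 1 breaks consistency for a spread-out transition
    un <- coox_constraint(ref, tv)
    expect_gt(abs(lr_consistency_trace(un, ref, tv)), 1e-3)
  }
})

test_that("constraints are invariant under degenerate-orbital rotations", {
  mol <- molecule_h6_ring(1.0)
  st <- cached("h6_ground", ground_scf(mol, base_config()))
  tv <- tda_solve(st, base_config(), n_states = 1)[[1]]
  w0 <- coox_constraint(st, tv)$w_matrix

  # rotate the degenerate occupied pair (2,3) and the degenerate virtual
  # pair (4,5); amplitudes transform contragradiently
  th <- 0.83
  u <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
  rot <- st
  rot$mo_coeff$alpha[, 2:3] <- st$mo_coeff$alpha[, 2:3] %*% u
  rot$mo_coeff$alpha[, 4:5] <- st$mo_coeff$alpha[, 4:5] %*% u
  rot$mo_coeff$beta <- rot$mo_coeff$alpha
  x <- tv$amplitudes                  # rows: virtuals 4..6, cols: occ 1..3
  x[1:2, ] <- t(u) %*% x[1:2, ]
  x[, 2:3] <- x[, 2:3] %*% u
  w1 <- coox_constraint(rot, transition_vector(x))$w_matrix
  expect_lt(max(abs(w1 - w0)), 1e-8)
})

test_that("x-cDFT constraint is the covariant virtual projector", {
  st <- h2o_ground()
  cs <- xcdft_constraint(st)
  expect_equal(cs$n_target, 1)
  expect_equal(cs$spin_mask, "alpha_only")
  # ground density has no virtual component
  expect_lt(abs(sum(st$density$alpha * cs$w_matrix)), 1e-10)
  # promoting one electron into any virtual combination gives trace 1
  virt <- which(st$occupations$alpha <= 0.5)
  mix <- st$mo_coeff$alpha[, virt] %*% c(0.6, 0.8)
  p_prom <- st$density$alpha -
    tcrossprod(st$mo_coeff$alpha[, 5]) + tcrossprod(mix)
  expect_equal(sum(p_prom * cs$w_matrix), 1, tolerance = 1e-10)
})

test_that("t-cDFT retention and renormalization arithmetic", {
  ref <- synthetic_reference_state(3, 4, seed = 42)

  # one dominant amplitude: a single constraint with unit coefficient
  x <- matrix(0, 4, 3)
  x[1, 1] <- sqrt(1 - 0.01^2)
  x[2, 2] <- 0.01
  cs <- tcdft_constraints(transition_vector(x), ref, threshold = 0.1)
  expect_length(cs, 1)
  expect_equal(abs(cs[[1]]$n_target), 1, tolerance = 1e-12)

  # two equal amplitudes: coefficients renormalized to squares summing to 1
  x <- matrix(0, 4, 3)
  x[1, 1] <- x[2, 2] <- 1 / sqrt(2)
  cs <- tcdft_constraints(transition_vector(x), ref, threshold = 0.1)
  expect_length(cs, 2)
  expect_equal(sum(vapply(cs, function(c) c$n_target^2, numeric(1))), 1,
               tolerance = 1e-12)

  # rank-1 amplitudes: NTO path and raw-amplitude path agree (up to the
  # joint sign of the dyad and its target)
  x <- matrix(0, 4, 3)
  x[3, 2] <- 1
  raw <- tcdft_constraints(transition_vector(x), ref, threshold = 0.1)[[1]]
  nto <- tcdft_constraints(transition_vector(x), ref, threshold = 0.1,
                           use_nto = TRUE)[[1]]
  sgn <- sign(raw$n_target) * sign(nto$n_target)
  expect_lt(max(abs(raw$w_matrix - sgn * nto$w_matrix)), 1e-10)
  expect_equal(raw$n_target, sgn * nto$n_target, tolerance = 1e-10)

  expect_error(tcdft_constraints(transition_vector(diag(3) / sqrt(3)), ref,
                                 threshold = 0.9),
               class = "coox_bad_constraint")
})

test_that("triplet setup promotes one beta electron to alpha", {
  st <- h2o_ground()
  tv <- cached("h2o_triplet_tda",
               tda_solve(st, base_config(), n_states = 1,
                         spin_type = "triplet"))[[1]]
  ts <- triplet_setup(st, tv)
  expect_equal(sum(ts$initial_state$occupations$alpha), 6)
  expect_equal(sum(ts$initial_state$occupations$beta), 4)
  # <S_z> = (N_alpha - N_beta) / 2 = 1
  expect_equal((sum(ts$initial_state$occupations$alpha) -
                  sum(ts$initial_state$occupations$beta)) / 2, 1)
  expect_equal(ts$constraint$spin_mask, "both")
  expect_equal(ts$constraint$n_target, 0)
})

test_that("triplet COOX on water excites about one electron", {
  res <- cached("h2o_triplet",
                excite(h2o_mol(),
                       run_config(method = "coox", spin_channel = "triplet")))
  expect_true(res$solution$converged)
  n_exc <- excited_electron_count(res$solution, res$ground)
  expect_gt(n_exc, 0.8)
  expect_lt(n_exc, 1.2)
  expect_gt(res$report$delta_e_ev, 0)
})
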
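test_that("AO context reproduces published minimal-basis H2 integrals", {
  # H2 at 1.4 Bohr: the classic printed reference values for the STO-3G
  # one- and two-electron integrals
  mol <- molecule_spec(c("H", "H"),
                       matrix(c(0, 0, 0, 0, 0, 1.4 / 1.8897261246),
                              ncol = 3, byrow = TRUE))
  ctx <- build_context(mol, base_config())
  expect_equal(ctx$n_ao, 2L)
  expect_gt(ctx$overlap[1, 2], 0)
  expect_lt(ctx$overlap[1, 2], 1)
  expect_lt(abs(ctx$overlap[1, 2] - 0.6593), 1e-4)
  expect_lt(abs(ctx$kinetic[1, 1] - 0.7600), 1e-4)
  expect_lt(abs(ctx$kinetic[1, 2] - 0.2365), 1e-4)
  expect_lt(abs(ctx$eri[1, 1, 1, 1] - 0.7746), 1e-4)
  expect_lt(abs(ctx$eri[1, 1, 2, 2] - 0.5697), 1e-4)
  expect_lt(abs(ctx$eri[1, 2, 1, 2] - 0.2970), 1e-4)
  expect_lt(abs(ctx$eri[1, 2, 1, 1] - 0.4441), 1e-4)
  expect_true(all(eigen(ctx$overlap, symmetric = TRUE)$values > 0))

  he <- molecule_spec("He", matrix(0, 1, 3))
  expect_equal(build_context(he, base_config())$nuclear_repulsion, 0)

  expect_error(build_context(mol, run_config(basis = "def2-qzvp")),
               class = "coox_unknown_basis")
  expect_error(build_context(mol, run_config(functional = "pbe0")),
               class = "coox_unknown_functional")
})

test_that("overlap matrix matches an independent quadrature oracle", {
  # p-function machinery: numerically integrate phi_mu * phi_nu on a grid
  # via the independent point evaluator and compare with the analytic S
  mol <- h2o_mol()
  ctx <- h2o_ground()$context
  n <- ctx$n_ao
  ng <- 41L
  grid <- grid_spec(rep(-6, 3), diag(rep(12 / (ng - 1), 3)), rep(ng, 3))
  pts <- grid_points(grid)
  # center grid on the molecule
  pts <- sweep(pts, 2, colMeans(mol$coords) * 1.8897261246, "+")
  vox <- abs(det(grid$axes))
  # pairs among the valence functions (the grid cannot resolve the O 1s core)
  for (pair in list(c(2, 2), c(2, 4), c(3, 5), c(4, 4), c(3, 7), c(6, 7))) {
    p <- matrix(0, n, n)
    p[pair[1], pair[2]] <- p[pair[2], pair[1]] <- 0.5
    if (pair[1] == pair[2]) p[pair[1], pair[2]] <- 1
    quad <- sum(density_on_points(ctx, p, pts)) * vox
    expect_lt(abs(quad - ctx$overlap[pair[1], pair[2]]), 2e-5)
  }
})

test_that("build_fock satisfies its limiting cases and energy consistency", {
  ctx <- h2o_ground()$context
  n <- ctx$n_ao
  z <- matrix(0, n, n)
  fb <- build_fock(ctx, z, z)
  expect_equal(fb$fock$alpha, ctx$core_h, tolerance = 1e-12)
  expect_equal(fb$electronic_energy, 0)

  p <- h2o_ground()$density$alpha
  fb <- build_fock(ctx, p, p)
  expect_equal(fb$fock$alpha, fb$fock$beta, tolerance = 1e-13)
  expect_lt(max(abs(fb$fock$alpha - t(fb$fock$alpha))), 1e-10)

  # dE/dP_alpha == F_alpha along a random symmetric direction
  set.seed(7)
  d <- matrix(rnorm(n * n), n, n)
  d <- (d + t(d)) / 2
  h <- 1e-6
  ep <- build_fock(ctx, p + h * d, p)$electronic_energy
  em <- build_fock(ctx, p - h * d, p)$electronic_energy
  expect_equal((ep - em) / (2 * h), sum(fb$fock$alpha * d), tolerance = 1e-6)
})

test_that("Fermi occupations solve the chemical potential correctly", {
  # wide gap: integer limiting values
  fo <- fermi_occupations(c(-0.5, 0.3), 1, 1000)
  expect_equal(fo$occupations, c(1, 0), tolerance = 1e-10)

  # exact degeneracy: symmetric split
  fo <- fermi_occupations(c(0, 0), 1, 1000)
  expect_equal(fo$occupations, c(0.5, 0.5), tolerance = 1e-12)

  # level spacing equal to kT: mu at the midpoint by symmetry
  kt <- 3.1668115634e-6 * 1000
  eps <- c(0, 0.0031668)
  fo <- fermi_occupations(eps, 1, 1000)
  mu <- mean(eps)
  expect_equal(fo$chemical_potential, mu, tolerance = 1e-9)
  expect_equal(fo$occupations, stats::plogis((mu - eps) / kt),
               tolerance = 1e-9)
  expect_equal(round(fo$occupations, 4), c(0.6225, 0.3775))
  expect_equal(sum(fo$occupations), 1, tolerance = 1e-10)

  # empty / full shells
  expect_equal(fermi_occupations(c(0, 1), 0, 1000)$occupations, c(0, 0))
  expect_equal(fermi_occupations(c(0, 1), 2, 1000)$occupations, c(1, 1))
  expect_error(fermi_occupations(c(0, 1), 3, 1000),
               class = "coox_bad_occupation")
})

test_that("ground SCF matches a brute-force Roothaan oracle on H2", {
  st <- h2_ground()
  oracle <- oracle_scf(st$context, 1)
  expect_equal(st$energy, oracle$energy, tolerance = 1e-6)
  expect_true(st$converged)
  expect_lt(st$commutator_norm, 1e-7)
})

test_that("converged SCF states satisfy their structural invariants", {
  for (st in list(h2_ground(), h2o_ground())) {
    s <- st$context$overlap
    cc <- st$mo_coeff$alpha
    expect_lt(max(abs(t(cc) %*% s %*% cc - diag(ncol(cc)))), 1e-8)
    expect_equal(sum(diag(st$density$alpha %*% s)), st$n_spin[["alpha"]],
                 tolerance = 1e-8)
    # integer occupations: idempotency P S P = P
    p <- st$density$alpha
    expect_lt(max(abs(p %*% s %*% p - p)), 1e-8)
    # re-running a Roothaan step from the converged density is a fixed point
    fb <- build_fock(st$context, st$density$alpha, st$density$beta)
    e0 <- fb$electronic_energy + st$context$nuclear_repulsion
    expect_equal(e0, st$energy, tolerance = 1e-10)
  }
  # loose monotonicity over the final macro iterations
  hist <- h2o_ground()$energy_history
  expect_true(all(diff(tail(hist, 5)) < 1e-6))
})

test_that("smearing: entropy, trace defect, and the T -> 0 limit", {
  cfg <- base_config()
  st <- ground_scf(h2o_mol(), cfg, smearing = TRUE)
  f <- st$occupations$alpha
  s <- st$context$overlap
  p <- st$density$alpha
  # trace defect of the smeared density equals sum f (1 - f)
  defect <- sum(diag(p %*% s)) - sum(diag(p %*% s %*% p %*% s))
  expect_equal(defect, sum(f * (1 - f)), tolerance = 1e-8)
  # entropy term: kT sum [f ln f + (1-f) ln(1-f)] (a negative quantity)
  kt <- 3.1668115634e-6 * cfg$temperature
  ff <- f[f > 0 & f < 1]
  expected <- 2 * kt * sum(ff * log(ff) + (1 - ff) * log(1 - ff))
  expect_equal(st$entropy_term, expected, tolerance = 1e-10)
  expect_lte(st$entropy_term, 0)

  # gapped system: the T -> 0 smeared energy equals the aufbau energy
  cold <- ground_scf(h2o_mol(), run_config(temperature = 1), smearing = TRUE)
  expect_equal(cold$energy, h2o_ground()$energy, tolerance = 1e-8)
})

test_that("checkpoints round-trip bit-exactly", {
  st <- h2_ground()
  tmp <- withr::local_tempfile(fileext = ".rds")
  save_checkpoint(st, tmp)
  back <- load_checkpoint(tmp)
  expect_identical(back$mo_coeff, st$mo_coeff)
  expect_identical(back$energy, st$energy)
  expect_identical(back$occupations, st$occupations)
})
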
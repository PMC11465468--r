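# shared fixtures and independent oracles
#
# Expensive reference states are computed once per test run and cached.
# The oracle implementations here are deliberately naive and separate from
# the package's solvers: plain fixed-point SCF loops, explicit-loop integral
# transforms, grid scans.

.cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (is.null(.cache[[key]])) .cache[[key]] <- force(expr)
  .cache[[key]]
}

h2_mol <- function() read_xyz(fixture_path("h2"))
h2o_mol <- function() read_xyz(fixture_path("h2o"))

base_config <- function(...) run_config(method = "coox", ...)

h2_ground <- function() cached("h2_ground", ground_scf(h2_mol(), base_config()))
h2o_ground <- function() cached("h2o_ground",
                                ground_scf(h2o_mol(), base_config()))

h2_coox <- function() cached("h2_coox", excite(h2_mol(), base_config()))
h2o_coox <- function() cached("h2o_coox", excite(h2o_mol(), base_config()))

h6_results <- function() {
  cached("h6", {
    mol <- molecule_h6_ring(1.0)
    list(
      unscaled = excite(mol, run_config(method = "coox")),
      scaled = excite(mol, run_config(method = "coox_scaled"))
    )
  })
}

# --- naive Fock assembly straight from the integral tensor -----------------
oracle_fock <- function(ctx, pa, pb) {
  n <- ctx$n_ao
  pt <- pa + pb
  j <- matrix(0, n, n)
  ka <- matrix(0, n, n)
  kb <- matrix(0, n, n)
  for (mu in 1:n) {
    for (nu in 1:n) {
      j[mu, nu] <- sum(ctx$eri[mu, nu, , ] * pt)
      ka[mu, nu] <- sum(ctx$eri[mu, , nu, ] * pa)
      kb[mu, nu] <- sum(ctx$eri[mu, , nu, ] * pb)
    }
  }
  e <- sum(pt * ctx$core_h) + 0.5 * sum(pt * j) -
    0.5 * (sum(pa * ka) + sum(pb * kb))
  list(fa = ctx$core_h + j - ka, fb = ctx$core_h + j - kb, e_elec = e)
}

# plain damped Roothaan iteration, integer occupations, no DIIS
oracle_scf <- function(ctx, n_occ_per_spin, damping = 0.5, max_iter = 500,
                       tol = 1e-10) {
  n <- ctx$n_ao
  sol <- eigen(t(ctx$orth) %*% ctx$core_h %*% ctx$orth, symmetric = TRUE)
  c0 <- ctx$orth %*% sol$vectors[, order(sol$values)]
  occ <- rep(0, n)
  occ[seq_len(n_occ_per_spin)] <- 1
  p <- c0 %*% (occ * t(c0))
  e_old <- Inf
  for (it in 1:max_iter) {
    fk <- oracle_fock(ctx, p, p)
    e <- fk$e_elec + ctx$nuclear_repulsion
    if (abs(e - e_old) < tol && it > 2) break
    e_old <- e
    sol <- eigen(t(ctx$orth) %*% fk$fa %*% ctx$orth, symmetric = TRUE)
    cc <- ctx$orth %*% sol$vectors[, order(sol$values)]
    p_new <- cc %*% (occ * t(cc))
    p <- damping * p_new + (1 - damping) * p
  }
  list(energy = e, density = p)
}

# Brute-force constrained-branch oracle for the two-level H2 system.  The
# restricted density has one free parameter -- the bonding-MO occupation f
# per spin (the g/u orbitals are fixed by symmetry) -- and the smeared
# self-consistency condition can be inverted in closed form: for two levels
# sharing one electron the Fermi occupation obeys
#   f = plogis(Delta_total / (2 kT)),
# so the multiplier that makes a given f self-consistent is
#   lambda(f) = (2 kT qlogis(f) - Delta_KS(f)) / (w_2 - w_1).
# Scanning f maps out the entire (lambda, residual) branch, including the
# segment plain fixed-point iteration is repelled from.
oracle_h2_branch <- function(ctx, w, mo_coeff, temperature, f) {
  kt <- 3.1668115634e-6 * temperature
  occ <- c(f, 1 - f)
  p <- mo_coeff %*% (occ * t(mo_coeff))       # per spin
  fk <- oracle_fock(ctx, p, p)
  eps <- diag(t(mo_coeff) %*% fk$fa %*% mo_coeff)   # symmetry: no mixing
  wdiag <- diag(t(mo_coeff) %*% w %*% mo_coeff)
  lambda <- (2 * kt * stats::qlogis(f) - (eps[2] - eps[1])) /
    (wdiag[2] - wdiag[1])
  cval <- 2 * sum(p * w)
  e <- fk$e_elec + ctx$nuclear_repulsion
  ent <- cooxr:::entropy_term(list(occ, occ), temperature)
  list(f = f, lambda = lambda, energy = e, entropy = ent,
       constraint_value = cval,
       free_energy_a = e + ent + lambda * cval)
}

# explicit-loop MO transform and dense TDA matrix (independent of tda_solve)
oracle_tda_matrix <- function(ground, spin_type = "singlet") {
  ctx <- ground$context
  cc <- ground$mo_coeff$alpha
  n <- ctx$n_ao
  occ <- which(ground$occupations$alpha > 0.5)
  virt <- which(ground$occupations$alpha <= 0.5)
  eps <- ground$mo_energy$alpha
  mo_int <- function(p, q, r, s) {
    val <- 0
    for (mu in 1:n) for (nu in 1:n) for (la in 1:n) for (si in 1:n) {
      val <- val + cc[mu, p] * cc[nu, q] * cc[la, r] * cc[si, s] *
        ctx$eri[mu, nu, la, si]
    }
    val
  }
  no <- length(occ)
  nv <- length(virt)
  a <- matrix(0, no * nv, no * nv)
  for (i in 1:no) for (av in 1:nv) for (j in 1:no) for (bv in 1:nv) {
    r <- (i - 1) * nv + av
    c_ <- (j - 1) * nv + bv
    val <- -mo_int(occ[i], occ[j], virt[av], virt[bv])
    if (spin_type == "singlet") {
      val <- val + 2 * mo_int(occ[i], virt[av], occ[j], virt[bv])
    }
    if (r == c_) val <- val + eps[virt[av]] - eps[occ[i]]
    a[r, c_] <- val
  }
  a
}

angle_deg <- function(coords, i, j, k) {
  v1 <- coords[i, ] - coords[j, ]
  v2 <- coords[k, ] - coords[j, ]
  acos(sum(v1 * v2) / sqrt(sum(v1^2) * sum(v2^2))) * 180 / pi
}
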
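---
title: "Constraint-based orbital-optimized excited states: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Constraint-based orbital-optimized excited states: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's account of the science it implements: the
constrained-SCF model of electronic excited states, the constraint potentials
it supports, the numerical choices inside the solvers, and what the shipped
tests do and do not demonstrate.

## The model

Ordinary Kohn-Sham or Hartree-Fock SCF relaxes a density `P` to the ground
state.  Constrained DFT (cDFT) augments the energy with a Lagrange-multiplier
term,

    W[P, lambda] = E[P] + lambda (Tr[P W_c] - N_c),

where `W_c` is a fixed one-electron "constraint potential" and `N_c` a target
expectation value.  The stationary point is a minimum in the density and a
maximum in the multiplier, which suggests a nested algorithm: a regular SCF
(macro) loop whose Fock operator is `F_KS + lambda W_c`, with an embedded
(micro) optimization of `lambda` so that `Tr[P W_c] = N_c` at every cycle.
Because the solution diagonalizes a single effective operator and fills it by
the aufbau/Fermi rule, the resulting orbitals respect the aufbau principle —
in contrast to delta-SCF determinants with a hole below the Fermi level.

Excited states enter through the choice of `W_c`.  The package implements
three schemes:

* **COOX** (the package's main method): the constraint is the difference of
  the *static* blocks of the linear-response excited-state difference
  density.  From a Tamm-Dancoff (TDA) amplitude matrix `X` (dimension
  `n_virt x n_occ`, Frobenius norm 1) referenced to the ground-state MOs,

        dP_virt = S C_virt (X X^T) C_virt^T S      (particle image)
        dP_occ  = S C_occ  (X^T X) C_occ^T  S      (hole image)
        W_c     = dP_virt - dP_occ.

  Both blocks are stored covariantly (sandwiched in the metric `S`) so that
  plain traces against contravariant densities count electrons; the
  metric-weighted trace of each block is exactly 1 for a normalized `X`.
  The combined constraint superposes the *expulsion* of one electron from
  the hole image and the *admittance* of one electron into the particle
  image, one electron each, so the combined target is `N_c = 0` when both
  spin channels are constrained (restricted singlets, triplets) and
  `N_c = 1` for the alpha-only fallback.  At a converged `N_c = 0` solution
  the multiplier term vanishes identically, so the free energy equals the
  plain energy of the unconstrained Hamiltonian — the excited state behaves
  like a free oscillation rather than a forced one, and excitation energies
  are direct energy differences.

* **x-cDFT** (comparison): `W_c` is the covariant projector onto the entire
  ground-state virtual space, applied to the alpha channel only with
  `N_c = 1`.  It can target only the lowest excitation, and `-lambda`
  estimates the excitation energy (the work of moving one electron across
  the gap; see the branch caveat below).

* **t-cDFT** (comparison): one symmetrized dyadic constraint
  `S (c_i c_a^T + c_a c_i^T) S` per retained transition amplitude, with the
  targets given by the amplitudes renormalized so their squares sum to one.
  Following the constraint-reduction idea, the dyads can equivalently be
  drawn from natural transition orbitals (NTOs, the SVD of `X`); the driver
  uses the NTO route.  Note a structural property of this ansatz: a dyadic
  potential constrains an occupied-virtual *coherence* `2 P_ia`, whose
  magnitude is bounded by 1 per spin channel, so a dyadic target can pin at
  most a partial transfer; the package applies these constraints to both
  spin channels, where the targets are interior (attainable) roots.  The
  weak electron transfer this produces is visible in the `n_exc` diagnostic
  and mirrors the known unreliability of transition-density-constrained
  excited-state densities.

### Restricted singlets, smearing, and triplets

For singlet excitations the COOX equations are solved in a *restricted*
fashion: one set of orbitals, with half an alpha and half a beta electron
excited.  This requires fractional occupations, which are induced by Fermi
smearing at an electronic temperature `T` (default 1000 K,
`kT ~ 3.17e-3` Hartree): occupations follow
`f_p = 1/(1 + exp((e_p - mu)/kT))` with the chemical potential solved per
spin channel to conserve the electron count to 1e-10.  The smeared
variational quantity is `E - T S_elec` with
`S_elec = -k sum_p [f ln f + (1-f) ln(1-f)]`; reported excitation energies
are differences of this free energy (for a gapped ground state the entropy
term is zero, and at the default temperature the excited-state term is of
order 1 mHartree).  Whether reported energies should include the entropy
term is genuinely open; the free-energy choice keeps the reported quantity
variational and consistent with the gradients, and the Lagrangian identity
`W = E` at `N_c = 0` is checked without the entropy term, so both
conventions are exposed.

Restricted solutions have `P_alpha = P_beta` by construction — no spin
contamination, no spin purification needed.

Triplets: the amplitudes come from a restricted *triplet* TDA solve; one
beta electron is then switched to alpha (`N_alpha = N/2 + 1`,
`N_beta = N/2 - 1`) and the COOX constraint is applied to both spin
channels with `N_c = 0`.

### Degenerate frontier orbitals and the scaled constraint

When the HOMO and/or LUMO are degenerate (benzene being the canonical case;
the package's cheap analog is a regular H6 ring), the unmodified restricted
constraint collapses the frontier gap: Fermi smearing then distributes
electrons equally over four quasi-degenerate levels and *two* electrons are
excited, with a roughly doubled excitation energy.  The cure is to scale the
virtual block:

    W'_c = f_V dP_virt - dP_occ,   f_V = (2 - t) / t,   t = Tr[(X^T X)^2].

`t` is the sum of the fourth powers of the singular values of `X`, so
`f_V = 1` exactly for a rank-1 transition (the unscaled case) and
`f_V = 3` for a transition spread equally over a degenerate pair.  The
factor is fixed by a linear-response consistency condition: the trace of
`W'_c` against the TDA excited-state density (ground density with the
occupied block depleted by `X^T X` and the virtual block populated by
`X X^T`) must reproduce the constraint target, so that the scaled solution
still satisfies the free-energy equality at convergence.  The default
driver (`method = "coox_auto"`) runs the unscaled constraint first and
switches to the scaled variant when the excited-electron count deviates
from one by more than 20% (`auto_switch_tol = 0.20`).  The scaling acts
like a level shift and can slightly overcorrect toward single-excitation
character; the unscaled result is retained whenever it already has
`|n_exc - 1| <= 0.2`.

### Diagnostics

The number of excited electrons projects the relaxed total density onto the
virtual space of the *unperturbed* ground state:

    n_exc = Tr[P_exc S C_virt C_virt^T S].

Ground and excited determinants are built from different orbital sets and
are not mutually orthogonal; `n_exc` is reported as is, without an
orthogonalization correction.  The single/double character solves

    %T1 + %T2 = 100,    %T1 + 2 %T2 = 100 n_exc,

the unique linear system interpolating a pure single (`n_exc = 1`) and a
pure double (`n_exc = 2`); negative `%T2` (from `n_exc < 1`) is clamped to
zero and flagged.  Difference densities `P_exc - P_ground` can be evaluated
on rectilinear grids and written as Gaussian cube files (default export
grid 80^3 points with a 4 Bohr margin — a plotting grid, not a quadrature).
Note that the *positive lobe* of a difference density is generally smaller
than `n_exc`: the depleted and populated orbital densities overlap in
space, most severely in minimal bases.

## Solvers and numerical choices

* **Macro loop**: Fock build from the current density, micro solve of the
  multiplier(s) at that fixed Fock, DIIS (error vector `FPS - SPF`, history
  8) on the *total* operator `F_KS + lambda W_c`, generalized
  diagonalization through a symmetric orthogonalizer (canonical
  orthogonalization below overlap eigenvalue 1e-9), Fermi occupations.
  Convergence requires the Frobenius norm of the commutator `[F, P]` below
  `scf_conv` (default 1e-7) *and* every constraint residual below 1e-6.
  If DIIS has not settled within `max_iter` cycles the solver restarts with
  plain damped density mixing (factor 0.3) — slower but robust for
  triplet solves at strongly displaced geometries.
* **Micro solve**: single constraints use Brent-class bracketing
  (`uniroot`) on `c(lambda) = Tr[P(lambda) W] - N`, with the bracket
  `[-B, B]` doubling from 1 to 64 Hartree and a secant polish to
  `|c| <= 1e-8`; `lambda = 0` is returned immediately when the constraint
  is already satisfied.  Multi-constraint (t-cDFT) sets use a damped Newton
  iteration with a finite-difference Jacobian.  Degeneracy ties are always
  broken by the Fermi distribution, never by orbital index.
* **Asymptotic targets**: under smearing an integer target can be a
  supremum rather than a crossing (e.g. the x-cDFT target `N = 1` when
  only one alpha electron is constrainable: `sum f_virt < 1` strictly at
  `T > 0`).  When bracket expansion finds no sign change but the residual
  is numerically satisfied at the bracket edge, the solver accepts the
  multiplier closest to the start with `|c| <= tol`.
* **Multiplier landscapes**: `lambda(N)` for hard integer x-cDFT targets is
  discontinuous exactly at the integer (two constrained-SCF branches
  cross).  The relation `dE/dN = -lambda` therefore holds one-sidedly per
  branch; the package's tests verify it inside a smooth branch.  For the
  same reason x-cDFT solutions sit at a kink of the fixed-potential energy
  surface, which is why their forces are not validated by finite
  differences (COOX and t-cDFT are).
* **TDA solver**: dense build of the response matrix in the
  occupied-virtual product space and full symmetric diagonalization.  At
  the Hartree-Fock level this is CIS, and the solver doubles as its own
  reference for two-electron systems.  The dense route is the only one
  implemented: the largest shipped system (benzene, STO-3G) has a
  315-dimensional pair space, far below where an iterative (Davidson)
  solver would pay off, so that branch was deliberately left out.
* **Gradients**: the constraint potential is a fixed AO matrix — not a
  function of the nuclear coordinates — so the analytic gradient of the
  constrained free-energy surface is assembled exactly like a ground-state
  gradient: Hellmann-Feynman and two-electron derivative terms contracted
  with the constrained density, the nuclear-repulsion derivative, and the
  Pulay term `-Tr[W_ew dS/dx]` with the energy-weighted density
  `W_ew = sum_p f_p e_p c_p c_p^T` built from fractional occupations and
  the eigenvalues of the *total* Fock (the operator whose eigenbasis the
  orbitals are; with any other choice the finite-difference test fails).
  The occupation response contributes nothing to first order because the
  smeared free energy is variational in the occupations.
* **Geometry optimization**: BFGS with a 0.3 Bohr trust cap and
  backtracking line search; convergence at maximum force 4.5e-4
  Hartree/Bohr.  On excited surfaces the transition vector and constraint
  are rebuilt at every geometry and the state is followed by maximum
  overlap of transition densities with the previous step (abort below
  overlap 0.5, which also triggers line-search backtracking).

## The backend

All integrals live behind a single backend contract (overlap, core
Hamiltonian, two-electron tensor, derivative integrals, densities on
points); the shipped engine is a compiled McMurchie-Davidson evaluator over
contracted Cartesian Gaussians with a built-in STO-3G minimal basis
(H, He, C, N, O, F) and Hartree-Fock Fock builds.  Derivative integrals
use the exponent-shift relation (raising/lowering Cartesian powers), and
nuclear-attraction operator derivatives follow from translational
invariance.  The engine reproduces the classic printed minimal-basis H2
integral values to all printed digits, and its overlap matrix is checked
against an independent grid quadrature for p functions.
Any engine honouring the same contract — including one with DFT
exchange-correlation functionals and larger basis sets — could be swapped
in without touching the constraint machinery, which is deliberately written
against the contract only.

## What the fixtures show — and what they cannot

The shipped geometries (H2, H2O, CH2O, C2H4, benzene, and the engineered H6
ring) are documented literature structures chosen for reproducibility; they
are *not* the benchmark geometries of published excitation data sets, and
HF/STO-3G is not the level of theory at which published excitation energies
were produced.  What the desk-scale results demonstrate is the *mechanics*
of the method, each item checked by the test suite:

* constraint algebra (block traces, scaled-constraint consistency) to
  1e-10 for arbitrary normalized amplitudes;
* solver correctness against independent brute-force oracles (explicit
  dense response matrix; a closed-form constrained-branch scan for the
  two-level system);
* the free-energy equality `W = E` at every converged COOX solution
  (1e-8 Hartree);
* spin purity of restricted singlets (1e-8);
* the degenerate-frontier pathology and its cure on the H6 ring
  (`n_exc = 2` and doubled excitation energy unscaled; `n_exc = 1` with
  `f_V = 3` scaled);
* force correctness against finite differences (5e-5 Hartree/Bohr),
  ground-state optimization to a verified stationary point, and the
  excited-state surface topology of the water triplet: the constrained
  energy falls monotonically as the molecule opens toward linearity.  (At
  this level of theory the radial coordinate of that state is dissociative,
  so linearity is asserted on an angular scan rather than at an
  unconstrained minimum.  Full excited-state optimizations with state
  tracking — e.g. the formaldehyde n->pi* state, which lengthens its CO
  bond — run in minutes and are left out of the default suite.)

Quantities that depend on the functional and basis — absolute excitation
energies compared to correlated references, charge-transfer asymptotics,
conical-intersection topography — are outside what a minimal-basis
Hartree-Fock backend can reproduce, and no test claims otherwise.  In this
regime orbital relaxation is heavily restricted and the half-half smeared
singlet lies noticeably *above* the TDA excitation; with realistic
functionals and bases the method's published behaviour is the opposite.
Problem sizes throughout the default suite are desk-scale by design: the
largest default calculations are water (7 basis functions) and the H6 ring,
chosen so every oracle can be brute-force.

## Known limitations

* Hartree-Fock only in the shipped backend; no XC functionals, no effective
  core potentials, no relativistic corrections.
* Restricted open-shell variants are not implemented (the triplet protocol
  is unrestricted-based); no spin purification is applied anywhere.
* The t-cDFT transcription uses dyadic coherence targets and inherits their
  partial-transfer ceiling (see above).
* The TDA solver is dense-only; full TDDFT/RPA amplitudes enter only
  through the import bridge.
* x-cDFT forces are assembled but not finite-difference-validated, for the
  structural branch-kink reason above.
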
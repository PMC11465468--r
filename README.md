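# cooxr

Targeted electronic excited states from a *self-consistent field*
calculation, by constrained density-functional / Hartree–Fock theory.

Linear-response TDDFT in the Tamm–Dancoff approximation (TDA) is the
workhorse for excited states, but it misses orbital relaxation, struggles
with charge transfer, and cannot describe double excitations.
Orbital-optimized alternatives (ΔSCF, maximum-overlap methods) relax the
orbitals but violate the aufbau principle and like to collapse back to the
ground state.  `cooxr` implements the constraint-based orbital-optimized
excitation method (**COOX**): a constrained-SCF scheme whose constraint
potential is assembled from the static blocks of the linear-response
difference density,

```
W_c = S C_virt (X Xᵀ) C_virtᵀ S  −  S C_occ (Xᵀ X) C_occᵀ S ,    Tr[P W_c] = N_c = 0,
```

where `X` is the (Frobenius-normalized, n_virt × n_occ) TDA amplitude
matrix of the target state.  The constraint expels one electron from the
hole image and admits one into the particle image; because the combined
target is zero, the converged free energy equals the plain energy of the
unconstrained Hamiltonian and excitation energies are direct energy
differences.  Singlets are solved *restricted* with Fermi-smearing
fractional occupations (half an α and half a β electron excited), so the
solution is spin-pure by construction.  For degenerate frontier orbitals a
scaled constraint `f_V·ΔP^virt − ΔP^occ` with `f_V = (2 − t)/t`,
`t = Tr[(XᵀX)²]`, restores a single-electron excitation.  The package also
implements the **x-cDFT** (virtual-space projector, α channel, N = 1) and
**t-cDFT** (renormalized dyadic transition-density constraints) comparison
schemes, excitation diagnostics (`n_exc`, %T1/%T2, difference densities as
cube files), analytic excited-state nuclear gradients with fractional
occupations, and a BFGS geometry optimizer with excited-state tracking.

Everything runs on a self-contained compiled McMurchie–Davidson Gaussian
integral backend (Hartree–Fock, built-in STO-3G for H/He/C/N/O/F) behind a
documented backend contract — an engine with DFT functionals and larger
bases can be plugged in without touching the method code.

## Worked example

```r
library(cooxr)

h2o <- read_xyz(fixture_path("h2o"))
res <- excite(h2o, run_config(method = "coox_auto"))
print(res$report)
#> Excitation report (coox_auto, hf/sto-3g, singlet_restricted)
#>   dE      = 20.4824 eV
#>   lambda  = -0.273755 Ha
#>   n_exc   = 1.0237  (%T1 = 97.6, %T2 = 2.4)
#>   residual 6.3e-13, |[F,P]| 9.4e-08, 12 macro cycles, converged
```

`dE` is the free-energy difference to the ground state, `lambda` the
converged constraint multiplier, and `n_exc` the number of excited
electrons (the relaxed density projected onto the ground-state virtual
space) with its single/double-excitation decomposition — here a clean
single excitation, so the unscaled constraint was kept.  (Minimal-basis
Hartree–Fock leaves little room for orbital relaxation; absolute energies
at this level are illustrative, not comparable to correlated references.)

The degenerate-frontier pathology and its cure, on a hydrogen-ring toy
with benzene-like degenerate HOMO/LUMO pairs:

```r
h6 <- molecule_h6_ring(1.0)
excite(h6, run_config(method = "coox"))$report       # unmodified constraint
#> dE = 39.93 eV   n_exc = 2.000        <- double excitation, doubled energy
excite(h6, run_config(method = "coox_auto"))$report  # auto-switches to scaled
#> dE = 21.83 eV   n_exc = 1.000        (scaled_used = TRUE, f_V = 3)
```

Gradients and optimization:

```r
g <- nuclear_gradient(res$solution, h2o, run_config(method = "coox"))
opt <- optimize_geometry(read_xyz(fixture_path("ch2o")),
                         run_config(method = "coox"), excited = TRUE)
```

A thin command-line driver wraps the same functions:

```sh
inst/cli/coox run inst/extdata/h2o.xyz --method coox_auto --out results/
inst/cli/coox grad inst/extdata/h2o.xyz --method coox --out results/
inst/cli/coox opt  inst/extdata/ch2o.xyz --excited --out results/
```

Exit status is 0 only for converged results; `--config file.yaml` mirrors
all flags, with command-line flags taking precedence.

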
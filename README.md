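# cycluster

Real-space cyclic-cluster semiempirical molecular-orbital calculations in
R: a self-contained NDDO (MNDO / AM1, sp basis) SCF engine for molecules
and for crystals, surfaces and molecular solids treated with periodic
boundary conditions imposed on a single supercell.

## Who this is for

Computational chemists and materials modellers who want fast quantum
chemistry on periodic systems — covalent and ionic crystals, slabs,
molecular boxes — without reciprocal-space machinery, plus the real-space
local-property maps (electrostatic potential, local ionization energy and
electron affinity) used in QSPR and charge-transport work.

## The model

NDDO semiempirical SCF keeps only one- and two-center integrals over
monatomic orbital-pair distributions, represented as distributed point
multipoles with Klopman-smoothed interactions. This package adds the three
ingredients that make the model periodic while staying entirely in real
space (Born–von Kármán conditions on one supercell, no k-point sampling):

* **Damped two-electron integrals.** Beyond a cutoff `c_cut` (default
  10 bohr) the two-center integral becomes

  `γ_AB(r) = 1 / (r + exp(-0.5 (r - c_cut)² (1/G_A + 1/G_B)))`,

  where `G` is the element's monopole constant (`g_ss` in hartree), so γ
  runs smoothly into the bare Coulomb `1/r` and neutral-atom contributions
  cancel at long range instead of summing to a divergent potential.
* **Three-zone screened electrostatics.** Interactions beyond `α` act at an
  effective distance: `r_eff = r` for `r < α`;
  `r_eff = -α/2 + 2r - r²/(2α)` for `α ≤ r ≤ 2α`; `r_eff = 1.5α` beyond.
  Distributed multipoles are simultaneously contracted by
  `λ(r) = 2 - r/α` (the derivative of `r_eff`), collapsing to point
  charges at `2α`, so distant neutral cells cancel exactly. The keyword
  `ScreeningR` sets `2α` in Å (default 30).
* **Wigner–Seitz exchange.** Exchange terms are evaluated only at each
  pair's minimum image — inside the Wigner–Seitz cell of each atom.

Heats of formation follow the usual semiempirical bookkeeping
`ΔH_f = E_total − Σ_A EISOL(A) + Σ_A ΔH_f,atom(A)`, energies are assembled
with compensated magnitude-ordered summation, and every calculation ends
with a Coulson population analysis (`q_A = Z_v(A) − Σ_{μ∈A} P_μμ`).

## Worked example

```r
library(cycluster)

# gas-phase AM1 water at the published AM1 geometry
st <- scf(molecule_fixture("water_am1"))
st
#> <SCF AM1: 3 atoms, 6 orbitals, 8 electrons, converged in 19 iterations>
#>   E(elec)    -493.298554 eV   E(core)     144.736014 eV
#>   E(total)   -348.562540 eV   heat of formation     -59.2407 kcal/mol
#>   HOMO  -12.4649 eV   LUMO    4.4215 eV

coulson_charges(st)
#>   element     charge
#> 1       O -0.3825886
#> 2       H  0.1912943
#> 3       H  0.1912943
```

The heat of formation (−59.24 kcal/mol) and charges reproduce the
published AM1 results for water (−59.2 kcal/mol, q(O) ≈ −0.38); the
dipole moment `dipole_moment(st)$total` gives 1.86 D.

Periodic cells work the same way — a 64-atom diamond supercell:

```r
d <- scf(crystal_fixture("diamond", c(2, 2, 2)))
d
#> <SCF AM1: 64 atoms, 256 orbitals, 256 electrons, converged in 12 iterations>
#>   E(elec) -8082320.482985 eV   E(core) 8074133.968020 eV
#>   E(total)  -8186.514966 eV   heat of formation     460.2520 kcal/mol
#>   HOMO   -9.4919 eV   LUMO    0.6605 eV
d$hf / 64      # per-atom heat of formation, kcal/mol
#> [1] 7.191438
```

The per-atom value converges as the supercell (and with it the Born–von
Kármán sampling) grows — the convergence study lives in the test-suite.
Local-property grids come from a converged state:

```r
g <- local_property_grid(st, "mep")      # electrostatic potential, kcal/mol
write_cube(g, st$cell, "water_mep.cube") # standard Gaussian cube file
```

A thin command line (`inst/cli/cycluster`) wraps the same functions:
`fixture`, `scf`, `grid` and `params` subcommands; see `?cli_run`.

## Scope

sp-basis MNDO and AM1 for H, C, N, O, F, Na, P, S, Cl, Zn; closed shells
only; charged species only non-periodically. No forces or geometry
optimization, no d orbitals, no excited states. See the methods vignette
(`vignettes/cyclic-cluster-methods.Rmd`) for the model details, parameter
provenance, numerical conventions and known limitations.
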
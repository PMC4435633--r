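---
title: "Real-space cyclic-cluster NDDO: model, parameters, and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Real-space cyclic-cluster NDDO: model, parameters, and numerical choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cycluster)
```

## The model

`cycluster` implements restricted closed-shell self-consistent-field theory
in the NDDO (neglect of diatomic differential overlap) approximation with
the MNDO and AM1 sp-basis parameterizations, for gas-phase molecules and
for crystals treated with the cyclic-cluster model: periodicity is imposed
as Born-von-Karman boundary conditions on a single real-space supercell,
all lattice sums are carried out in real space, and no reciprocal-space
sampling is performed. A calculation on a periodic cell is therefore the
familiar molecular SCF with three modifications:

1. **Damped two-electron integrals.** The two-center `(ss|ss)`-type
   integrals decay like `1/r` and would sum to a divergent potential over
   an infinite lattice. Beyond a cutoff `c_cut` (default 10 bohr) the
   Klopman additive term is suppressed by a Gaussian, so the integral runs
   smoothly into the bare point-charge `1/r` and neutral-atom contributions
   cancel at long range. See "The damping convention" below.
2. **Screened electrostatics.** All electrostatic interactions (electron-
   electron, electron-core, core-core) between centers farther apart than
   `alpha` are evaluated at an effective distance `r_eff(r)`; between
   `alpha` and `2*alpha` the distributed multipoles are simultaneously
   contracted toward their centers by `lambda(r) = d r_eff / d r`, and
   beyond `2*alpha` every multipole has collapsed to a point charge sitting
   at the fixed radius `1.5*alpha`. Because every distant charge then
   interacts through one and the same kernel, the contribution of any
   complete (hence neutral) unit cell vanishes identically and the lattice
   sum becomes absolutely convergent. The keyword `ScreeningR` sets
   `2*alpha` in Angstrom; its default, 30 A, is a conservative value.
3. **Wigner-Seitz exchange.** Exchange contributions to the Fock matrix
   are evaluated only at the minimum image of each atom pair, i.e. inside
   the Wigner-Seitz cell of each atom; very weak exchange with more distant
   periodic copies is neglected.

A non-periodic cell has no images, no far field, and (for molecules of
ordinary size) no pair beyond `c_cut`, so the engine reduces exactly to
textbook MNDO/AM1; the published AM1 heats of formation of water and
methane at their published geometries are reproduced to better than
0.1 kcal/mol by the test-suite.

## Parameters

All per-element constants (one-electron energies `U_ss`, `U_pp`, Slater
exponents, resonance parameters `beta`, one-center two-electron integrals
`g_ss, g_sp, g_pp, g_p2, h_sp`, core-repulsion exponents and the AM1 core
Gaussians, atomic heats of formation) are embedded as in-code tables
transcribed from the original method publications, with a provenance
comment per element. Three families of derived quantities are *computed*
from the tables rather than transcribed:

* the isolated-atom electronic energies (EISOL), from standard open-shell
  pair-energy counting over the Hund ground configuration — the derivation
  reproduces the published values exactly where those are in the
  literature (e.g. MNDO C and O, AM1 O and Zn), and guarantees internal
  consistency elsewhere;
* the charge separations `D1`, `D2` of the distributed multipoles, from
  closed-form Slater matrix elements;
* the additive Klopman radii: `rho0 = 1/(2 g_ss)` analytically, and
  `rho1`, `rho2` by Newton iteration on the one-center conditions that the
  dipole-dipole and quadrupole-quadrupole configuration self-energies
  reproduce `h_sp` and `(g_pp - g_p2)/2`. For AM1 carbon the resulting
  constants agree with the values printed by established semiempirical
  codes to all published digits.

Zinc is treated with an sp basis (the AM1 zinc parameterization); d
orbitals are out of scope. The sodium parameters come from the later
alkali extension literature and carry lower confidence than the main-group
set; sodium is exercised only in structural fixtures and symmetry tests,
never in a quantitative benchmark. Only closed-shell species are
supported, and charged species only non-periodically.

Energy bookkeeping uses the legacy conversion constants of the
semiempirical literature (1 hartree = 27.21 eV, 1 eV = 23.061 kcal/mol,
a0 = 0.529167 A); published MNDO/AM1 results were parameterized with these
values and are only reproduced when using them.

## The damping convention

The damped long-range integral is written here as

    gamma(r) = 1 / (r + exp(-0.5 (r - c_cut)^2 (1/G_A + 1/G_B))),   r > c_cut

with `G` the element's monopole constant (`g_ss` in hartree, so `1/G` is a
length in bohr), and `1/sqrt(r^2 + (1/G_A + 1/G_B)^2)` below the cutoff.
Two readings of the printed formula are possible, differing in whether the
`G` sum sits inside the Gaussian exponent (the default above) or
multiplies the Gaussian with the product squared (available via
`convention = "product-squared"`). The default was chosen because it is
the only reading that is approximately continuous at `c_cut`: the mismatch
stays below 5e-3 hartree for every supported pair not involving Na (the
largest, about 4.3e-3 hartree, occurs for F-F) and below 1.2e-2 hartree
for Na pairs, whose soft monopole constant makes `1/G` unusually long.
Directly past the onset the additive term decays faster than `r` grows, so
`gamma` exhibits a small bump (amplitude ~1e-4 hartree for typical
elements) before resuming its monotone `1/r` descent; this is a property
of the printed functional form, shared by both readings, and is asserted
(with its documented amplitude) rather than hidden by the tests. The
damping is applied to every multipole channel beyond `c_cut`, with one
common additive term per pair, so that the potential of a *neutral* atom
cancels exactly in the monopole channel and decays at least as `1/r^3`
overall — the property the screening cancellation argument rests on.

## Far field: the complete-cell plateau

Beyond `2*alpha` every pair interacts through the universal kernel
`1/(1.5*alpha)` (the Gaussian remnant at that distance is below e^-30 and
is dropped, making the kernel element-independent). Summed over complete
unit cells the plateau contribution of each cell is `q_cell * const = 0`
for a neutral cell, so rather than enumerating an infinite (or very large)
set of images, the engine enumerates images only up to `2*alpha` plus the
cell diameter and adds the far field analytically: the Fock matrix gains
`gbar * (s_A + q_A)` on the diagonal block of atom A, and the energy
`-gbar/2 * sum_A q_A (s_A + q_A)`, where `s_A` is the sum of Coulson
charges over all near images of A and `gbar = 1/(1.5*alpha)`. This is
algebraically identical to the infinite complete-cell sum, avoids the
catastrophic cancellation of huge plateau constants in `H` and `F`, and
makes the enumeration-radius-independence of the result exact by
construction. One consequence worth noting: a single neutral molecule in a
periodic box larger than `2*alpha` has *exactly* the gas-phase energy.

## SCF procedure

The initial guess is the diagonal atomic density `Z_v / basis size` — no
randomness enters anywhere, so runs are bitwise reproducible. The first
iteration is taken undamped (it is exact for isolated-atom-like problems);
iterations 2-5 apply 50% density damping while the density step exceeds
0.05; thereafter Pulay DIIS over at most 8 Fock matrices (error
`FP - PF`; the NDDO basis is orthonormal) drives convergence. Convergence
requires both max `|dP| < 1e-6` and `|dE| < 1e-6` eV (configurable);
non-convergence after 200 iterations returns the state flagged
unconverged, and heat-of-formation reporting refuses such states. The
accelerator choices are this package's own; the cyclic-cluster model does
not prescribe them.

Energy assembly uses Neumaier-compensated summation with
magnitude-ordered accumulation (`compensated_sum()`, also exported),
serving the same purpose as the quadruple-precision ordered summation used
by large-scale production codes; the contract is agreement with exact
cancellation oracles, not a bit width.

### Exchange ties at the Wigner-Seitz boundary

For high-symmetry cells many atom pairs sit exactly on the Wigner-Seitz
boundary, where two or more images are equidistant. The membership
predicate `in_wigner_seitz()` resolves such ties deterministically
(lexicographic comparison, exactly one image accepted), which is the right
contract for a partition-of-space predicate. The *engine*, however,
averages the exchange integral block over all tied minimum images: a
single-image choice cannot be made odd under relabeling of the pair in all
degenerate cases, and averaging is the unique choice that preserves exact
invariance of the energy under atom permutation and rigid translation
(verified to ~5e-9 eV, the double-precision noise floor of assembling
energies of a few thousand eV; the residual scales with machine epsilon
times the total energy, which is why a fixed absolute threshold such as
1e-10 eV is not attainable for ionic cells in double precision).

## Local properties

Grids are evaluated with Born-von-Karman basis functions (each Slater
function summed over lattice images within the basis cutoff, 12 bohr by
default), which makes periodic grids exactly lattice-periodic. The MO
coefficients of the orthogonalized NDDO basis are applied directly to the
raw Slater functions — the customary semiempirical grid approximation (no
deorthogonalization) — and each molecular orbital is renormalized in the
raw-STO metric so that the density grid integrates to the electron count
(the test-suite checks 2% on a finite box). The electrostatic potential
uses bare cores plus the atomwise distributed multipoles of the converged
density with the same screening machinery as the energy, plus the
complete-cell far-field correction; it is reported in kcal/mol per unit
probe charge. The local ionization energy and electron affinity are the
orbital-density-weighted means

    IE_L(r) = - sum_occ rho_i(r) e_i / sum_occ rho_i(r)
    EA_L(r) = - sum_virt rho_a(r) e_a / sum_virt rho_a(r)

with simple orbital-density weights (the plainest of the variants in the
local-property literature; the weighting enters only through `rho_i`, so a
different variant can be substituted in `local_property_grid()`'s
weighting helper). Electronegativity `(IE_L + EA_L)/2` and hardness
`(IE_L - EA_L)/2` are provided as derived grids. `IE_L` is a weighted
mean, hence bounded by the occupied spectrum — an invariant the tests
assert pointwise.

## What the fixtures emulate — and what they do not

The programmatic fixtures (conventional diamond, rocksalt NaCl, wurtzite
ZnO, a non-polar ZnO(10-10) slab with an optional surface dimer vacancy,
and molecules replicated in periodic boxes) use standard literature
lattice constants and published AM1 molecular geometries. They exercise
covalent, ionic, 2-D and molecular periodicity, which is what the periodic
machinery needs; they do not probe geometry relaxation (no forces are
implemented), open shells, d-electron chemistry, or thermal disorder, so
passing tests say nothing about those regimes. Problem sizes in the
test-suite were chosen to keep the default run under a minute of compute
for the routine tests plus about half a minute for the largest supercell
series (diamond up to 3x3x3, 216 atoms / 864 orbitals); convergence of the
heat of formation with supercell size is asserted as a trend (shrinking
successive per-atom differences), which is the property the cyclic-cluster
model claims. Strict energy extensivity under supercell doubling holds
only for systems whose images do not interact (it is asserted exactly for
a molecular box); for dense crystals, enlarging the supercell *improves*
the Born-von-Karman sampling, which is precisely why the convergence study
is meaningful rather than trivially flat.

## Degenerate and edge inputs

Atoms closer than 0.5 bohr are rejected as a geometry error. Open-shell
(odd-electron) inputs and charged periodic cells are refused with explicit
errors. `minimum_image()` first wraps displacements into the home cell via
fractional coordinates and then searches a +/-2 shell (widened to +/-4
when any lattice angle is sharper than 45 degrees), so arbitrarily distant
displacements reduce correctly. The z-aligned degenerate case of the local
diatomic frame uses a fixed deterministic completion. Overlaps below 1e-8
are floored to zero, bounding the resonance range.
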
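# R-level surface of the two-center integral machinery. The hot paths live
# in compiled code; these wrappers exist for direct use and for tests.

# Build the per-atom parameter matrix consumed by the compiled core.
# Column layout must match the enum in src/nddo.cpp.
.atom_params_matrix <- function(elements, hamiltonian) {
  n <- length(elements)
  m <- matrix(0, n, 37)
  for (i in seq_len(n)) {
    p <- element_params(elements[i], hamiltonian)
    g <- p$gauss
    ng <- if (is.null(g)) 0L else nrow(g)
    row <- c(p$zv, p$nbasis, p$nq, p$zs, p$zp, p$uss, p$upp, p$betas,
             p$betap, p$gss, p$gsp, p$gpp, p$gp2, p$hsp, p$alpha,
             p$d1, p$d2, p$rho0, p$rho1, p$rho2, p$gmono,
             p$z, p$eisol, p$hf_atom, ng, rep(0, 12))
    if (ng > 0L) {
      row[26:(25 + 3 * ng)] <- as.numeric(t(g))
    }
    m[i, ] <- row
  }
  m
}

#' Klopman-smoothed pair interaction
#'
#' The basic two-center kernel of NDDO electrostatics:
#' `q1*q2 / sqrt(r12^2 + (rho_a + rho_b)^2)` (atomic units). Finite at
#' coincidence when the additive radii are positive, and Coulombic at long
#' range.
#'
#' @param q1,q2 point charges (e).
#' @param r12 distance, bohr.
#' @param rho_a,rho_b additive radii, bohr.
#' @return interaction energy, hartree.
#' @export
klopman_pair_term <- function(q1, q2, r12, rho_a, rho_b) {
  stopifnot(rho_a >= 0, rho_b >= 0)
  q1 * q2 / sqrt(r12^2 + (rho_a + rho_b)^2)
}

#' Damped two-center monopole integral
#'
#' The `(ss|ss)`-type integral with the periodic-limit correction: below the
#' cutoff `c_cut` the Klopman form with additive length `1/G_A + 1/G_B`;
#' beyond it a Gaussian-damped form that decays to the bare Coulomb `1/r`,
#' so that lattice sums of the associated potential stay finite. `G` is the
#' monopole constant of each element (`g_ss` in hartree).
#'
#' Two grouping conventions for the damped branch are provided.
#' `"exponent-sum"` (default) places the additive-length sum inside the
#' Gaussian exponent, `1/(r + exp(-0.5 (r - c_cut)^2 (1/G_A + 1/G_B)))`;
#' it is the convention used throughout the SCF engine and is approximately
#' continuous at `c_cut` (mismatch below 5e-3 hartree for all supported
#' pairs not involving alkali metals; below 1.2e-2 hartree for Na pairs,
#' whose soft monopole constant makes the additive length unusually long).
#' `"product-squared"` multiplies the additive length by the Gaussian and
#' squares the product, `1/(r + (exp(-0.25 (r-c_cut)^2) (1/G_A+1/G_B))^2)`.
#'
#' @param r distance, bohr (> 0).
#' @param g_a,g_b monopole constants, hartree.
#' @param c_cut damping onset, bohr (default 10).
#' @param convention `"exponent-sum"` or `"product-squared"`.
#' @return integral value, hartree.
#' @examples
#' gamma_damped(20, 0.45, 0.45)            # ~ 1/20
#' @export
gamma_damped <- function(r, g_a, g_b, c_cut = 10,
                         convention = c("exponent-sum", "product-squared")) {
  convention <- match.arg(convention)
  stopifnot(all(r > 0), c_cut > 0, g_a > 0, g_b > 0)
  s <- 1 / g_a + 1 / g_b
  lower <- 1 / sqrt(r^2 + s^2)
  x <- r - c_cut
  add <- if (convention == "exponent-sum") {
    exp(pmax(-0.5 * x^2 * s, -700))
  } else {
    (exp(-0.25 * x^2) * s)^2
  }
  ifelse(r < c_cut, lower, 1 / (r + add))
}

#' Two-center two-electron integral block
#'
#' The full 10 x 10 block of NDDO electron-repulsion integrals between the
#' unique orbital-pair distributions of two sp atoms, evaluated via
#' distributed point-charge multipoles in the local diatomic frame and
#' rotated to the global frame. Distributions are damped beyond `c_cut`
#' and, when `screen = TRUE`, relocated/contracted by the three-zone
#' screening beyond `alpha`.
#'
#' Row/column order of the condensed pairs (orbitals s, px, py, pz):
#' ss, s-px, s-py, s-pz, xx, xy, xz, yy, yz, zz.
#'
#' @param params_a,params_b `element_params` records.
#' @param dr displacement vector A to B, bohr.
#' @param alpha screening radius, bohr (default: 30 A / 2 expressed in
#'   bohr).
#' @param c_cut damping onset, bohr.
#' @param convention damping convention, see [gamma_damped].
#' @param screen apply the three-zone screening?
#' @return 10 x 10 matrix, eV.
#' @export
eri_block <- function(params_a, params_b, dr,
                      alpha = angstrom_to_bohr(15), c_cut = 10,
                      convention = c("exponent-sum", "product-squared"),
                      screen = TRUE) {
  convention <- match.arg(convention)
  pa <- .atom_params_matrix(params_a$symbol, params_a$hamiltonian)[1, ]
  pb <- .atom_params_matrix(params_b$symbol, params_b$hamiltonian)[1, ]
  EV_PER_HARTREE *
    eri_block_cpp(pa, pb, as.numeric(dr), alpha, c_cut,
                  ifelse(convention == "exponent-sum", 0L, 1L), screen)
}

#' Overlap and resonance block between two atoms
#'
#' Exact two-center Slater-orbital overlaps (prolate-spheroidal auxiliary
#' integrals), returned together with the one-electron resonance block
#' `H_uv = (beta_u + beta_v)/2 * S_uv`. Overlaps below 1e-8 are floored to
#' zero.
#'
#' @inheritParams eri_block
#' @return list with `S` (overlap) and `H` (resonance, eV), each
#'   `nbasis_a` x `nbasis_b`.
#' @export
overlap_resonance <- function(params_a, params_b, dr) {
  stopifnot(sum(dr^2) > 0)
  pa <- .atom_params_matrix(params_a$symbol, params_a$hamiltonian)[1, ]
  pb <- .atom_params_matrix(params_b$symbol, params_b$hamiltonian)[1, ]
  S <- overlap_block_cpp(pa, pb, as.numeric(dr))
  S[abs(S) < 1e-8] <- 0
  beta_a <- c(params_a$betas, rep(params_a$betap, 3))
  beta_b <- c(params_b$betas, rep(params_b$betap, 3))
  H <- 0.5 * outer(beta_a, beta_b, "+") * S
  na <- params_a$nbasis; nb <- params_b$nbasis
  list(S = S[seq_len(na), seq_len(nb), drop = FALSE],
       H = H[seq_len(na), seq_len(nb), drop = FALSE])
}

#' Core-core repulsion energy of an atom pair
#'
#' The MNDO-family core repulsion
#' `Z_A Z_B (s_A s_A | s_B s_B) (1 + e^{-alpha_A R} + e^{-alpha_B R})`
#' (with the N-H/O-H variant multiplying the heavy-atom exponential by R),
#' plus the AM1 core Gaussian corrections where present. The `(ss|ss)`
#' factor goes through the damped/screened integral path, so the periodic
#' corrections propagate to the cores.
#'
#' @inheritParams eri_block
#' @param r distance, bohr.
#' @return energy, eV.
#' @export
core_core_energy <- function(params_a, params_b, r,
                             alpha = angstrom_to_bohr(15), c_cut = 10,
                             convention = c("exponent-sum",
                                            "product-squared"),
                             screen = TRUE) {
  convention <- match.arg(convention)
  stopifnot(r > 0)
  pa <- .atom_params_matrix(params_a$symbol, params_a$hamiltonian)[1, ]
  pb <- .atom_params_matrix(params_b$symbol, params_b$hamiltonian)[1, ]
  core_core_cpp(pa, pb, r, alpha, c_cut,
                ifelse(convention == "exponent-sum", 0L, 1L), screen)
}
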
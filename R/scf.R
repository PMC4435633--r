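# Restricted closed-shell SCF for molecules and cyclic-cluster crystals.

.conv_int <- function(convention) {
  ifelse(match.arg(convention, c("exponent-sum", "product-squared")) ==
           "exponent-sum", 0L, 1L)
}

# Shared precomputation: core Hamiltonian, image-summed Coulomb blocks,
# Wigner-Seitz exchange blocks, core-core energy, near-image counts.
.assemble <- function(cell, hamiltonian, config) {
  apar <- .atom_params_matrix(cell$atoms$element, hamiltonian)
  lat <- if (cell$pdim == 0L) matrix(0, 0, 3) else cell$lattice
  pre <- assemble_cpp(apar, cell_coords(cell), lat,
                      config$screening_r / 2, config$c_cut,
                      ifelse(config$convention == "exponent-sum", 0L, 1L))
  pre$apar <- apar
  pre
}

#' Build the one-electron core Hamiltonian
#'
#' Diagonal one-electron energies, image-summed resonance from exact Slater
#' overlaps, and electron-core attraction summed over all lattice images
#' within the screening horizon (each term damped and screened).
#'
#' @param cell a [cell]; periodic cells must be neutral.
#' @param hamiltonian `"AM1"` or `"MNDO"`.
#' @param config a [run_config] list.
#' @return symmetric matrix (eV), dimension = [orbital_count].
#' @export
build_core_hamiltonian <- function(cell, hamiltonian = "AM1",
                                   config = run_config()) {
  .assemble(cell, hamiltonian, config)$H
}

#' Build a Fock matrix from a density matrix
#'
#' Coulomb contributions are summed over all atom pairs and lattice images
#' within the screening horizon (with the analytic far-field plateau
#' correction beyond `2 alpha`); exchange contributions are evaluated only
#' at the minimum image, i.e. within the Wigner-Seitz cell of each atom.
#' For a non-periodic cell this reduces to the standard NDDO Fock matrix.
#'
#' @inheritParams build_core_hamiltonian
#' @param p density matrix (trace = number of valence electrons).
#' @param pre optional precomputed assembly (internal reuse).
#' @return list with the Fock matrix `F` (eV) and the electronic energy
#'   `e_elec` (eV) consistent with it.
#' @export
build_fock <- function(cell, p, hamiltonian = "AM1", config = run_config(),
                       pre = NULL) {
  if (is.null(pre)) pre <- .assemble(cell, hamiltonian, config)
  if (nrow(p) != pre$norb) stop("density matrix dimension mismatch",
                                call. = FALSE)
  fk <- fock_cpp(pre$apar, pre$H, pre$Wsum, pre$Wx, pre$pair_a, pre$pair_b,
                 pre$Nnear, pre$gbar_ev, pre$offsets, p)
  list(F = fk$F, e_elec = fk$e_elec, e_far = fk$e_far)
}

#' Run a self-consistent-field calculation
#'
#' Closed-shell restricted SCF with a fixed deterministic initial guess
#' (diagonal atomic densities `Z_v / basis size`), density damping for the
#' first iterations and DIIS afterwards. Converged when both the maximum
#' density change and the energy change fall below the configured
#' tolerances.
#'
#' @inheritParams build_core_hamiltonian
#' @return an object of class `scf_state`: converged density matrix, MO
#'   coefficients and orbital energies (eV, ascending), energy components
#'   (eV), heat of formation (kcal/mol), Coulson charges, iteration history
#'   and a `converged` flag.
#' @examples
#' \donttest{
#' st <- scf(molecule_fixture("water_am1"))
#' st$hf                      # heat of formation, kcal/mol
#' coulson_charges(st)
#' }
#' @export
scf <- function(cell, hamiltonian = "AM1", config = run_config()) {
  hamiltonian <- toupper(hamiltonian)
  nelec <- valence_electron_count(cell, hamiltonian)
  if (nelec %% 2L != 0L) {
    stop("open shell unsupported: odd electron count ", nelec, call. = FALSE)
  }
  if (cell$pdim > 0L && cell$charge != 0L) {
    stop("periodic cells must be neutral", call. = FALSE)
  }
  pre <- .assemble(cell, hamiltonian, config)
  nb <- pre$norb
  nocc <- nelec %/% 2L

  # initial guess: diagonal atomic densities
  p <- matrix(0, nb, nb)
  apar <- pre$apar
  for (a in seq_len(nrow(apar))) {
    o <- pre$offsets[a] + 1L
    k <- apar[a, 2]
    p[seq(o, o + k - 1L), seq(o, o + k - 1L)] <- diag(apar[a, 1] / k, k)
  }

  e_old <- Inf
  history <- data.frame(iter = integer(), energy = numeric(),
                        dp_max = numeric())
  diis_f <- list(); diis_e <- list()
  converged <- FALSE
  fmat <- NULL; eorb <- NULL; cmat <- NULL; e_elec <- NA_real_

  for (it in seq_len(config$max_iter)) {
    fk <- fock_cpp(apar, pre$H, pre$Wsum, pre$Wx, pre$pair_a, pre$pair_b,
                   pre$Nnear, pre$gbar_ev, pre$offsets, p)
    fmat <- fk$F
    e_elec <- fk$e_elec
    e_tot <- e_elec + pre$enuc

    # DIIS (orthonormal NDDO basis: error = FP - PF)
    err <- fmat %*% p - p %*% fmat
    diis_f <- c(diis_f, list(fmat)); diis_e <- c(diis_e, list(err))
    if (length(diis_f) > config$diis_size) {
      diis_f <- diis_f[-1L]; diis_e <- diis_e[-1L]
    }
    f_use <- fmat
    nd <- length(diis_f)
    if (it > config$damp_iters && nd >= 2L) {
      b <- matrix(0, nd + 1L, nd + 1L)
      for (i in seq_len(nd)) for (j in seq_len(nd)) {
        b[i, j] <- sum(diis_e[[i]] * diis_e[[j]])
      }
      b[nd + 1L, seq_len(nd)] <- -1
      b[seq_len(nd), nd + 1L] <- -1
      rhs <- c(rep(0, nd), -1)
      coef <- tryCatch(solve(b, rhs)[seq_len(nd)],
                       error = function(e) NULL)
      if (!is.null(coef) && all(is.finite(coef))) {
        f_use <- Reduce(`+`, Map(`*`, diis_f, coef))
      }
    }

    es <- eigen(f_use, symmetric = TRUE)
    ord <- order(es$values)
    eorb <- es$values[ord]
    cmat <- es$vectors[, ord, drop = FALSE]
    cocc <- cmat[, seq_len(nocc), drop = FALSE]
    p_new <- 2 * tcrossprod(cocc)

    dp <- max(abs(p_new - p))
    de <- abs(e_tot - e_old)
    history <- rbind(history,
                     data.frame(iter = it, energy = e_tot, dp_max = dp))
    if (config$verbose) {
      message(sprintf("iter %3d  E = %18.8f eV  max|dP| = %10.3e", it,
                      e_tot, dp))
    }
    if (dp < config$tol_p && de < config$tol_e) {
      converged <- TRUE
      p <- p_new
      break
    }
    if (it > 1L && it <= config$damp_iters && dp > 0.05) {
      p <- (1 - config$damping) * p_new + config$damping * p
    } else {
      p <- p_new
    }
    e_old <- e_tot
  }

  # final consistent energy at the converged density
  fk <- fock_cpp(apar, pre$H, pre$Wsum, pre$Wx, pre$pair_a, pre$pair_b,
                 pre$Nnear, pre$gbar_ev, pre$offsets, p)
  e_elec <- fk$e_elec
  e_tot <- e_elec + pre$enuc

  eisol_sum <- compensated_sum(apar[, 23])
  hfat_sum <- compensated_sum(apar[, 24])
  hf <- ev_to_kcal(e_tot - eisol_sum) + hfat_sum

  st <- structure(list(
    cell = cell, hamiltonian = hamiltonian, config = config,
    p = p, coefficients = cmat, orbital_energies = eorb,
    n_electrons = nelec, n_occ = nocc,
    e_electronic = e_elec, e_core = pre$enuc, e_total = e_tot,
    hf = if (converged) hf else NA_real_, hf_raw = hf,
    history = history, converged = converged,
    offsets = pre$offsets, apar = apar
  ), class = "scf_state")
  st
}

#' @export
print.scf_state <- function(x, ...) {
  cat(sprintf("<SCF %s: %d atoms, %d orbitals, %d electrons, %s>\n",
              x$hamiltonian, nrow(x$cell$atoms), length(x$orbital_energies),
              x$n_electrons,
              if (x$converged) sprintf("converged in %d iterations",
                                       nrow(x$history))
              else "NOT converged"))
  cat(sprintf("  E(elec) %14.6f eV   E(core) %14.6f eV\n",
              x$e_electronic, x$e_core))
  cat(sprintf("  E(total) %13.6f eV   heat of formation %12.4f kcal/mol\n",
              x$e_total, x$hf_raw))
  ho <- homo_lumo(x)
  cat(sprintf("  HOMO %9.4f eV   LUMO %s eV\n", ho["homo"],
              if (is.na(ho["lumo"])) "      --" else
                sprintf("%9.4f", ho["lumo"])))
  invisible(x)
}

#' HOMO and LUMO energies of a converged state
#'
#' @param state an `scf_state`.
#' @return named numeric vector `c(homo = , lumo = )` in eV (`lumo` is `NA`
#'   when there are no virtual orbitals).
#' @export
homo_lumo <- function(state) {
  e <- state$orbital_energies
  n <- state$n_occ
  c(homo = e[n],
    lumo = if (length(e) > n) e[n + 1L] else NA_real_)
}

#' Compensated (error-tracking) summation
#'
#' Neumaier-compensated summation over the values sorted by increasing
#' magnitude: the ordering and the running compensation term keep the
#' result accurate to about one ulp of the true sum even for long sequences
#' with catastrophic cancellation, serving the same purpose as the
#' extended-precision energy summation of large-cell production codes.
#'
#' @param values numeric vector (the empty vector sums to 0).
#' @return the compensated sum.
#' @examples
#' compensated_sum(c(1e16, 1, -1e16))  # 1
#' @export
compensated_sum <- function(values) {
  if (length(values) == 0L) return(0)
  stopifnot(all(is.finite(values)))
  v <- values[order(abs(values))]
  s <- 0; comp <- 0
  for (x in v) {
    t <- s + x
    comp <- comp + if (abs(s) >= abs(x)) (s - t) + x else (x - t) + s
    s <- t
  }
  s + comp
}

#' Heat of formation of a converged SCF state
#'
#' `dHf = E_total - sum_A EISOL(A)` (converted to kcal/mol) `+ sum_A
#' dHf_atom(A)`: the semiempirical total energy referenced to isolated-atom
#' electronic energies plus experimental atomic heats of formation.
#'
#' @param state a converged `scf_state`.
#' @return kcal/mol.
#' @export
heat_of_formation <- function(state) {
  if (!state$converged) {
    stop("SCF did not converge; refusing to report a heat of formation",
         call. = FALSE)
  }
  state$hf
}

#' Coulson atomic charges
#'
#' `q_A = Z_v(A) - sum of the diagonal density-matrix elements on A`. For
#' any cell the charges sum to the net charge (to numerical precision).
#'
#' @param state an `scf_state`.
#' @return data.frame with columns `element`, `charge`.
#' @export
coulson_charges <- function(state) {
  apar <- state$apar
  n <- nrow(apar)
  q <- numeric(n)
  for (a in seq_len(n)) {
    o <- state$offsets[a] + 1L
    k <- apar[a, 2]
    q[a] <- apar[a, 1] - sum(diag(state$p)[seq(o, o + k - 1L)])
  }
  data.frame(element = state$cell$atoms$element, charge = q,
             stringsAsFactors = FALSE)
}

#' Molecular dipole moment (Debye)
#'
#' Point-charge contribution from the Coulson charges plus the sp
#' hybridization dipoles of the distributed-multipole density; meaningful
#' for non-periodic cells.
#'
#' @param state an `scf_state` for a non-periodic cell.
#' @return length-3 named list with `vector` (Debye) and `total`.
#' @export
dipole_moment <- function(state) {
  stopifnot(state$cell$pdim == 0L)
  apar <- state$apar
  xyz <- angstrom_to_bohr(cell_coords(state$cell))
  q <- coulson_charges(state)$charge
  mu <- colSums(q * xyz)
  for (a in seq_len(nrow(apar))) {
    if (apar[a, 2] == 4) {
      o <- state$offsets[a] + 1L
      d1 <- apar[a, 16]
      for (k in 1:3) {
        # electron density s-p cross term carries dipole -2 P_sp * d1
        mu[k] <- mu[k] - 2 * state$p[o, o + k] * d1
      }
    }
  }
  debye <- mu * 2.541765
  list(vector = debye, total = sqrt(sum(debye^2)))
}

#' Tidy orbital-level summary of an SCF state
#'
#' @param x an `scf_state`.
#' @param ... unused.
#' @return data.frame with one row per molecular orbital: index, energy
#'   (eV), occupation.
#' @export
tidy.scf_state <- function(x, ...) {
  n <- length(x$orbital_energies)
  data.frame(orbital = seq_len(n), energy = x$orbital_energies,
             occupation = c(rep(2, x$n_occ), rep(0, n - x$n_occ)))
}

#' One-row summary of an SCF state
#'
#' @param x an `scf_state`.
#' @param ... unused.
#' @return one-row data.frame: atoms, electrons, iterations, convergence,
#'   total energy (eV), heat of formation (kcal/mol), HOMO/LUMO (eV).
#' @export
glance.scf_state <- function(x, ...) {
  hl <- homo_lumo(x)
  data.frame(n_atoms = nrow(x$cell$atoms), n_electrons = x$n_electrons,
             iterations = nrow(x$history), converged = x$converged,
             e_total = x$e_total, hf = x$hf_raw,
             homo = hl[["homo"]], lumo = hl[["lumo"]])
}

#' @export
tidy <- function(x, ...) UseMethod("tidy")

#' @export
glance <- function(x, ...) UseMethod("glance")
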
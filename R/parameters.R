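# Embedded semiempirical parameter tables (MNDO, AM1; sp basis).
#
# Units follow the original parameterizations: U, beta, g, h in eV; orbital
# exponents zeta in bohr^-1; core-repulsion exponent alpha in A^-1; core
# Gaussian triples (K eV*A, L A^-2, M A); atomic heats of formation in
# kcal/mol. The isolated-atom electronic energy (EISOL) and the multipole
# geometry constants (D1, D2, rho0, rho1, rho2) are *derived* from these
# numbers at load time rather than transcribed, which keeps the table
# internally consistent (the derivation reproduces the literature EISOL and
# AD/AQ values where those are published).

.hamiltonians <- c("MNDO", "AM1")

.element_z <- c(H = 1L, C = 6L, N = 7L, O = 8L, F = 9L, Na = 11L,
                P = 15L, S = 16L, Cl = 17L, Zn = 30L)
.element_zv <- c(H = 1L, C = 4L, N = 5L, O = 6L, F = 7L, Na = 1L,
                 P = 5L, S = 6L, Cl = 7L, Zn = 2L)
.element_nq <- c(H = 1L, C = 2L, N = 2L, O = 2L, F = 2L, Na = 3L,
                 P = 3L, S = 3L, Cl = 3L, Zn = 4L)
.element_hfatom <- c(H = 52.102, C = 170.89, N = 113.00, O = 59.559,
                     F = 18.89, Na = 25.85, P = 75.57, S = 66.40,
                     Cl = 28.99, Zn = 31.17)

# One-center two-electron integrals (Oleari-derived; shared by MNDO and AM1
# for the elements below unless the AM1-era reparameterization changed them).
.one_center <- list(
  H  = c(gss = 12.848, gsp = 0, gpp = 0, gp2 = 0, hsp = 0),
  C  = c(gss = 12.23, gsp = 11.47, gpp = 11.08, gp2 = 9.84, hsp = 2.43),
  N  = c(gss = 13.59, gsp = 12.66, gpp = 12.98, gp2 = 11.59, hsp = 3.14),
  O  = c(gss = 15.42, gsp = 14.48, gpp = 14.52, gp2 = 12.98, hsp = 3.94),
  F  = c(gss = 16.92, gsp = 17.25, gpp = 16.71, gp2 = 14.91, hsp = 4.83),
  Cl = c(gss = 15.03, gsp = 13.16, gpp = 11.30, gp2 = 9.97, hsp = 2.42),
  Zn = c(gss = 11.80, gsp = 11.182018, gpp = 13.30, gp2 = 12.93,
         hsp = 0.484606)
)

# Per-element, per-Hamiltonian one-electron and core parameters.
# gauss: matrix with columns K (eV*A), L (A^-2), M (A); AM1 only.
.param_table <- list(
  AM1 = list(
    # Dewar, Zoebisch, Healy, Stewart (1985)
    H = list(uss = -11.396427, upp = 0, zs = 1.188078, zp = 0,
             betas = -6.173787, betap = 0, alpha = 2.882324,
             g = .one_center$H,
             gauss = cbind(K = c(0.122796, 0.005090, -0.018336),
                           L = c(5.00, 5.00, 2.00),
                           M = c(1.20, 1.80, 2.10))),
    C = list(uss = -52.028658, upp = -39.614239, zs = 1.808665,
             zp = 1.685116, betas = -15.715783, betap = -7.719283,
             alpha = 2.648274, g = .one_center$C,
             gauss = cbind(K = c(0.011355, 0.045924, -0.020061, -0.001260),
                           L = c(5.00, 5.00, 5.00, 5.00),
                           M = c(1.60, 1.85, 2.05, 2.65))),
    N = list(uss = -71.860000, upp = -57.167581, zs = 2.315410,
             zp = 2.157940, betas = -20.299110, betap = -18.238666,
             alpha = 2.947286, g = .one_center$N,
             gauss = cbind(K = c(0.025251, 0.028953, -0.005806),
                           L = c(5.00, 5.00, 2.00),
                           M = c(1.50, 2.10, 2.40))),
    O = list(uss = -97.830000, upp = -78.262380, zs = 3.108032,
             zp = 2.524039, betas = -29.272773, betap = -29.272773,
             alpha = 4.455371, g = .one_center$O,
             gauss = cbind(K = c(0.280962, 0.081430),
                           L = c(5.00, 7.00),
                           M = c(0.847918, 1.445071))),
    # Dewar & Zoebisch (1988)
    F = list(uss = -136.105579, upp = -104.889885, zs = 3.770082,
             zp = 2.494670, betas = -69.590277, betap = -27.922360,
             alpha = 5.517800, g = .one_center$F,
             gauss = cbind(K = c(0.242079, 0.003607),
                           L = c(4.80, 4.60),
                           M = c(0.930, 1.660))),
    # Sodium extension set (alkali parameterization literature); exercised
    # only by structural fixtures, not by quantitative benchmarks.
    Na = list(uss = -5.255536, upp = -2.081277, zs = 0.679779,
              zp = 0.980653, betas = -1.453694, betap = -0.229806,
              alpha = 2.248716,
              g = c(gss = 7.345994, gsp = 7.089437, gpp = 4.136122,
                    gp2 = 4.036273, hsp = 0.633120),
              gauss = NULL),
    # Dewar & Jie (1989)
    P = list(uss = -42.029863, upp = -34.030709, zs = 1.981280,
             zp = 1.875150, betas = -6.353764, betap = -6.590709,
             alpha = 2.455322,
             g = c(gss = 11.560005, gsp = 5.237449, gpp = 7.877589,
                   gp2 = 7.307648, hsp = 0.779238),
             gauss = cbind(K = c(-0.031827, 0.018470, 0.033290),
                           L = c(6.00, 7.00, 9.00),
                           M = c(1.474323, 1.779354, 3.006576))),
    # Dewar & Yuan (1990)
    S = list(uss = -56.694056, upp = -48.717049, zs = 2.366515,
             zp = 1.667263, betas = -3.920566, betap = -7.905278,
             alpha = 2.461648,
             g = c(gss = 11.786329, gsp = 8.663127, gpp = 10.039308,
                   gp2 = 7.781688, hsp = 2.532137),
             gauss = cbind(K = c(-0.509195, -0.011863, 0.012334),
                           L = c(4.593691, 5.865731, 13.557336),
                           M = c(0.770665, 1.503313, 2.009173))),
    # Dewar & Zoebisch (1988)
    Cl = list(uss = -111.613948, upp = -76.640107, zs = 3.631376,
              zp = 2.076799, betas = -24.594670, betap = -14.637216,
              alpha = 2.919368, g = .one_center$Cl,
              gauss = cbind(K = c(0.094243, 0.027168),
                            L = c(4.00, 4.00),
                            M = c(1.30, 2.10))),
    # Dewar & Merz (1988)
    Zn = list(uss = -21.040008, upp = -17.655574, zs = 1.954299,
              zp = 1.372365, betas = -1.997429, betap = -4.758119,
              alpha = 1.484563, g = .one_center$Zn, gauss = NULL)
  ),
  MNDO = list(
    # Dewar & Thiel (1977)
    H = list(uss = -11.906276, upp = 0, zs = 1.331967, zp = 0,
             betas = -6.989064, betap = 0, alpha = 2.544134,
             g = .one_center$H, gauss = NULL),
    C = list(uss = -52.279745, upp = -39.205558, zs = 1.787537,
             zp = 1.787537, betas = -18.985044, betap = -7.934122,
             alpha = 2.546380, g = .one_center$C, gauss = NULL),
    N = list(uss = -71.932122, upp = -57.172319, zs = 2.255614,
             zp = 2.255614, betas = -20.495758, betap = -20.495758,
             alpha = 2.861342, g = .one_center$N, gauss = NULL),
    O = list(uss = -99.644309, upp = -77.797472, zs = 2.699905,
             zp = 2.699905, betas = -32.688082, betap = -32.688082,
             alpha = 3.160604, g = .one_center$O, gauss = NULL),
    # Dewar & Rzepa (1978)
    F = list(uss = -131.071548, upp = -105.782137, zs = 2.848487,
             zp = 2.848487, betas = -48.290460, betap = -48.290460,
             alpha = 3.419661, g = .one_center$F, gauss = NULL),
    # Sodium extension set; see note on AM1 Na.
    Na = list(uss = -5.201883, upp = -2.712913, zs = 0.987508,
              zp = 0.893254, betas = -1.087391, betap = -0.486256,
              alpha = 1.681057,
              g = c(gss = 6.993438, gsp = 5.438053, gpp = 4.085883,
                    gp2 = 3.567685, hsp = 0.500602),
              gauss = NULL),
    # Dewar, McKee & Rzepa (1978)
    P = list(uss = -56.143360, upp = -42.851080, zs = 2.108720,
             zp = 1.785810, betas = -6.791600, betap = -6.791600,
             alpha = 2.415280,
             g = c(gss = 11.56, gsp = 10.08, gpp = 8.64, gp2 = 7.68,
                   hsp = 1.92),
             gauss = NULL),
    S = list(uss = -72.242281, upp = -56.973207, zs = 2.312962,
             zp = 2.009146, betas = -10.761610, betap = -10.108433,
             alpha = 2.478026,
             g = c(gss = 12.88, gsp = 11.26, gpp = 9.90, gp2 = 8.83,
                   hsp = 2.26),
             gauss = NULL),
    Cl = list(uss = -100.227166, upp = -77.378667, zs = 3.784645,
              zp = 2.036263, betas = -14.262320, betap = -14.262320,
              alpha = 2.542201, g = .one_center$Cl, gauss = NULL),
    # Dewar & Merz (1986)
    Zn = list(uss = -20.838337, upp = -19.625995, zs = 2.047359,
              zp = 1.460946, betas = -1.000000, betap = -2.000000,
              alpha = 1.506457, g = .one_center$Zn, gauss = NULL)
  )
)

supported_elements <- function() names(.element_zv)

# Isolated-atom ground-state electronic energy (eV) from the one-center
# parameters, using standard pair-energy counting for the Hund ground
# configuration (s fills first, then p with maximum multiplicity).
.eisol_from_params <- function(zv, g) {
  ns <- min(2L, zv)
  np <- zv - ns
  p_up <- min(np, 3L)
  p_dn <- np - p_up
  hpp <- 0.5 * (g[["gpp"]] - g[["gp2"]])
  n2 <- max(0L, np - 3L)                   # doubly occupied p orbitals
  coul_pp_diff <- choose(np, 2) - n2       # distinct-orbital p pairs
  exch_sp <- 1L * p_up + (ns - 1L) * p_dn  # same-spin s-p pairs
  exch_pp <- choose(p_up, 2) + choose(p_dn, 2)
  (if (ns == 2L) g[["gss"]] else 0) +
    ns * 0 + np * 0 +                      # U terms added by caller
    ns * np * g[["gsp"]] - exch_sp * g[["hsp"]] +
    n2 * g[["gpp"]] + coul_pp_diff * g[["gp2"]] - exch_pp * hpp
}

# Dipole and quadrupole charge separations (bohr) from the Slater exponents;
# the closed forms follow from <ns|z|npz> and <np|r^2|np> for principal
# quantum number n.
.charge_separations <- function(nq, zs, zp) {
  d1 <- (2 * nq + 1) / sqrt(3) * (4 * zs * zp)^(nq + 0.5) /
    (zs + zp)^(2 * nq + 2)
  d2 <- sqrt((2 * nq + 1) * (2 * nq + 2) / 20) / zp
  c(d1 = d1, d2 = d2)
}

# Additive radii (bohr): rho0 from the monopole limit, rho1/rho2 solved
# numerically so that the dipole-dipole and quadrupole-quadrupole
# configuration self-energies reproduce hsp and (gpp-gp2)/2 at r = 0.
.solve_rho1 <- function(hsp_au, d1) {
  f <- function(r) 0.25 * (1 / r - 1 / sqrt(d1^2 + r^2)) - hsp_au
  stats::uniroot(f, c(1e-4, 50), tol = 1e-14)$root
}

.solve_rho2 <- function(hpp_au, d2) {
  f <- function(r) {
    1 / (8 * r) - 0.5 / sqrt(4 * d2^2 + 4 * r^2) +
      0.25 / sqrt(8 * d2^2 + 4 * r^2) - hpp_au
  }
  stats::uniroot(f, c(1e-4, 50), tol = 1e-14)$root
}

#' Retrieve the semiempirical parameter record for an element
#'
#' Returns the full per-element, per-Hamiltonian parameter set used by the
#' SCF engine: one-electron energies and resonance parameters, Slater
#' exponents, one-center two-electron integrals, the core-repulsion exponent
#' and (for AM1) the core Gaussian triples, together with derived quantities:
#' the isolated-atom electronic energy `eisol` (eV), the monopole constant
#' `gmono` (`g_ss` in hartree, whose reciprocal is the Klopman additive
#' length in bohr), the charge separations `d1`, `d2` and the additive radii
#' `rho0 = 1/(2*gmono)`, `rho1`, `rho2` (all bohr).
#'
#' @param symbol element symbol; one of H, C, N, O, F, Na, P, S, Cl, Zn.
#' @param hamiltonian `"AM1"` (default) or `"MNDO"`.
#' @return an object of class `element_params` (a named list).
#' @examples
#' p <- element_params("C", "AM1")
#' p$zv          # 4 valence electrons
#' p$rho0        # Klopman monopole radius, bohr
#' @export
element_params <- function(symbol, hamiltonian = "AM1") {
  hamiltonian <- toupper(hamiltonian)
  symbol <- normalize_symbol(symbol)
  if (!hamiltonian %in% .hamiltonians || !symbol %in% supported_elements()) {
    stop(sprintf("unsupported species: element '%s' with Hamiltonian '%s'",
                 symbol, hamiltonian), call. = FALSE)
  }
  key <- paste(hamiltonian, symbol, sep = ".")
  cached <- .params_cache[[key]]
  if (!is.null(cached)) return(cached)

  raw <- .param_table[[hamiltonian]][[symbol]]
  zv <- .element_zv[[symbol]]
  nq <- .element_nq[[symbol]]
  nbasis <- if (symbol == "H") 1L else 4L
  g <- raw$g
  u_sum <- min(2L, zv) * raw$uss + max(0L, zv - 2L) * raw$upp
  eisol <- u_sum + .eisol_from_params(zv, g)
  gmono <- g[["gss"]] / EV_PER_HARTREE
  rho0 <- 1 / (2 * gmono)
  if (nbasis == 1L) {
    d1 <- d2 <- rho1 <- rho2 <- 0
  } else {
    ds <- .charge_separations(nq, raw$zs, raw$zp)
    d1 <- ds[["d1"]]; d2 <- ds[["d2"]]
    rho1 <- .solve_rho1(g[["hsp"]] / EV_PER_HARTREE, d1)
    rho2 <- .solve_rho2(0.5 * (g[["gpp"]] - g[["gp2"]]) / EV_PER_HARTREE, d2)
  }
  rec <- structure(list(
    symbol = symbol, hamiltonian = hamiltonian,
    z = .element_z[[symbol]], zv = zv, nq = nq, nbasis = nbasis,
    zs = raw$zs, zp = raw$zp,
    uss = raw$uss, upp = raw$upp,
    betas = raw$betas, betap = raw$betap,
    gss = g[["gss"]], gsp = g[["gsp"]], gpp = g[["gpp"]],
    gp2 = g[["gp2"]], hsp = g[["hsp"]],
    alpha = raw$alpha, gauss = raw$gauss,
    hf_atom = .element_hfatom[[symbol]],
    eisol = eisol, gmono = gmono,
    rho0 = rho0, rho1 = rho1, rho2 = rho2, d1 = d1, d2 = d2
  ), class = "element_params")
  assign(key, rec, envir = .params_cache)
  rec
}

.params_cache <- new.env(parent = emptyenv())

#' @export
print.element_params <- function(x, ...) {
  cat(sprintf("<%s parameters for %s (Z=%d, %d valence e-, basis %d)>\n",
              x$hamiltonian, x$symbol, x$z, x$zv, x$nbasis))
  num <- vapply(x[c("uss", "upp", "betas", "betap", "zs", "zp", "gss", "gsp",
                    "gpp", "gp2", "hsp", "alpha", "eisol", "hf_atom",
                    "gmono", "rho0", "rho1", "rho2", "d1", "d2")],
                identity, numeric(1))
  print(round(num, 6))
  invisible(x)
}

normalize_symbol <- function(symbol) {
  s <- as.character(symbol)
  paste0(toupper(substr(s, 1, 1)), tolower(substring(s, 2)))
}

#' Dipole and quadrupole charge separations of an sp element
#'
#' The distributed-multipole representation places the point charges of the
#' s-p dipole at distance `d1` and those of the p-p quadrupoles at distances
#' derived from `d2` (bohr), computed from the Slater exponents and the
#' principal quantum number by the standard closed-form matrix elements.
#'
#' @param params an `element_params` record with active p orbitals.
#' @return named numeric vector `c(d1 = ..., d2 = ...)` in bohr.
#' @export
multipole_distances <- function(params) {
  stopifnot(inherits(params, "element_params"))
  if (params$nbasis == 1L) {
    stop("no multipoles for s-only basis", call. = FALSE)
  }
  c(d1 = params$d1, d2 = params$d2)
}

#' Count valence electrons of a structure
#'
#' Sums the per-element valence electron counts (H=1, C=4, N=5, O=6, F=7,
#' Na=1, P=5, S=6, Cl=7, Zn=2) over all atoms and subtracts the net charge.
#'
#' @param x a [cell] object, or a character vector of element symbols, or a
#'   molecular formula string such as `"C32H64NO8P"`.
#' @param hamiltonian Hamiltonian tag (affects only parameter validation).
#' @param charge net charge; for a `cell` the cell's own charge is used.
#' @return integer electron count.
#' @examples
#' valence_electron_count("C32H64NO8P")  # one DLPC lipid: 250
#' @export
valence_electron_count <- function(x, hamiltonian = "AM1", charge = 0L) {
  if (inherits(x, "cell")) {
    charge <- x$charge
    syms <- x$atoms$element
  } else {
    syms <- expand_symbols(x)
  }
  zv <- vapply(syms, function(s) element_params(s, hamiltonian)$zv,
               integer(1))
  as.integer(sum(zv) - charge)
}

#' Count basis orbitals of a structure
#'
#' Hydrogen contributes one s orbital, every other supported element a full
#' sp set of four.
#'
#' @inheritParams valence_electron_count
#' @return integer orbital count.
#' @export
orbital_count <- function(x) {
  syms <- if (inherits(x, "cell")) x$atoms$element else expand_symbols(x)
  sum(ifelse(normalize_symbol(syms) == "H", 1L, 4L))
}

# Accepts either a character vector of symbols or a single formula string
# ("C32H64NO8P") and returns the expanded symbol vector.
expand_symbols <- function(x) {
  if (length(x) == 1L && grepl("[0-9]", x)) {
    m <- gregexpr("([A-Z][a-z]?)([0-9]*)", x)[[1]]
    parts <- regmatches(x, list(m))[[1]]
    parts <- parts[nzchar(parts)]
    syms <- sub("[0-9]*$", "", parts)
    cnt <- as.integer(sub("^[A-Za-z]+", "", parts))
    cnt[is.na(cnt)] <- 1L
    rep(syms, cnt)
  } else {
    as.character(x)
  }
}

#' Atom bookkeeping for a solvated membrane composition
#'
#' Returns the atom and valence-electron counts of a lipid-bilayer model
#' built from dilauroyl-phosphatidylcholine (DLPC, C32H64NO8P) and water.
#'
#' @param n_lipid number of DLPC molecules.
#' @param n_water number of water molecules.
#' @return named list with `atoms` and `electrons` counts.
#' @examples
#' membrane_composition(128, 3840)$atoms  # 25088
#' @export
membrane_composition <- function(n_lipid = 128L, n_water = 3840L) {
  dlpc <- expand_symbols("C32H64NO8P")
  list(
    atoms = as.integer(n_lipid * length(dlpc) + n_water * 3L),
    electrons = as.integer(
      n_lipid * valence_electron_count("C32H64NO8P") +
        n_water * valence_electron_count("H2O"))
  )
}

#' Dump the full embedded parameter table
#'
#' @param hamiltonian `"AM1"`, `"MNDO"`, or `"all"`.
#' @return a data.frame with one row per element and Hamiltonian.
#' @export
params_table <- function(hamiltonian = "all") {
  hams <- if (identical(hamiltonian, "all")) .hamiltonians
          else toupper(hamiltonian)
  rows <- list()
  for (h in hams) {
    for (el in supported_elements()) {
      p <- element_params(el, h)
      rows[[paste(h, el)]] <- data.frame(
        element = el, hamiltonian = h, zv = p$zv, nbasis = p$nbasis,
        uss = p$uss, upp = p$upp, betas = p$betas, betap = p$betap,
        zs = p$zs, zp = p$zp, gss = p$gss, gsp = p$gsp, gpp = p$gpp,
        gp2 = p$gp2, hsp = p$hsp, alpha = p$alpha, eisol = p$eisol,
        hf_atom = p$hf_atom, gmono = p$gmono, rho0 = p$rho0,
        rho1 = p$rho1, rho2 = p$rho2, d1 = p$d1, d2 = p$d2,
        stringsAsFactors = FALSE
      )
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
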
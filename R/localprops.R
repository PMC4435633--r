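# Real-space local-property grids over the cell.

#' Define a regular real-space grid
#'
#' For periodic axes the grid spans exactly one lattice vector (endpoint
#' exclusive); for non-periodic directions an origin and axis vectors are
#' given explicitly.
#'
#' @param origin grid origin, Angstrom.
#' @param axes 3 x 3 matrix; row i is the full extent of grid direction i,
#'   Angstrom.
#' @param npts integer vector of length 3, points per direction (>= 2).
#' @return a `grid_spec` list.
#' @export
grid_spec <- function(origin, axes, npts) {
  npts <- as.integer(npts)
  stopifnot(length(npts) == 3L, all(npts >= 2L),
            is.matrix(axes), all(dim(axes) == c(3L, 3L)))
  structure(list(origin = as.numeric(origin), axes = axes, npts = npts),
            class = "grid_spec")
}

#' Default grid over a cell
#'
#' Periodic axes span the lattice vectors; non-periodic directions cover
#' the atoms with a margin.
#'
#' @param cell a [cell].
#' @param npts points per direction (recycled to length 3).
#' @param margin padding for non-periodic directions, Angstrom.
#' @return a `grid_spec`.
#' @export
default_grid <- function(cell, npts = 24L, margin = 4) {
  npts <- rep(as.integer(npts), length.out = 3L)
  xyz <- cell_coords(cell)
  lo <- apply(xyz, 2, min) - margin
  hi <- apply(xyz, 2, max) + margin
  axes <- diag(hi - lo)
  origin <- lo
  if (cell$pdim > 0L) {
    for (i in seq_len(cell$pdim)) axes[i, ] <- cell$lattice[i, ]
    # periodic spans start at the cell origin projection
    origin[seq_len(cell$pdim)] <- 0
    if (cell$pdim == 3L) origin <- c(0, 0, 0)
  }
  grid_spec(origin, axes, npts)
}

.grid_points <- function(spec) {
  n <- spec$npts
  # endpoint-exclusive fractional coordinates along each axis
  f1 <- (seq_len(n[1]) - 1L) / n[1]
  f2 <- (seq_len(n[2]) - 1L) / n[2]
  f3 <- (seq_len(n[3]) - 1L) / n[3]
  fr <- as.matrix(expand.grid(f1 = f1, f2 = f2, f3 = f3))
  sweep(fr %*% spec$axes, 2, spec$origin, "+")
}

#' Compute a local-property grid
#'
#' Evaluates one of the real-space local properties on a regular grid over
#' the cell, using the Born-von-Karman (image-summed) basis functions so
#' that periodic cells give exactly periodic fields:
#' * `density`: electron density (e / A^3).
#' * `mep`: molecular electrostatic potential of a unit positive probe
#'   charge (kcal/mol), from bare cores and the atomwise distributed
#'   multipoles of the converged density, screened beyond `alpha`.
#' * `ie_local`: local ionization energy (kcal/mol), the orbital-density
#'   weighted average `-sum(rho_i e_i)/sum(rho_i)` over occupied orbitals.
#' * `ea_local`: local electron affinity (kcal/mol), the same weighted
#'   average over virtual orbitals (simple orbital-density weighting).
#' * `electronegativity`, `hardness`: `(IE_L + EA_L)/2` and
#'   `(IE_L - EA_L)/2`.
#'
#' @param state a converged `scf_state`.
#' @param kind property name (see above).
#' @param spec a [grid_spec]; default [default_grid] of the cell.
#' @param basis_cutoff basis-function range, bohr.
#' @return a `property_grid`: list with `spec`, `kind`, `values` (3-D
#'   array, x index fastest).
#' @export
local_property_grid <- function(state,
                                kind = c("density", "mep", "ie_local",
                                         "ea_local", "electronegativity",
                                         "hardness"),
                                spec = default_grid(state$cell),
                                basis_cutoff = 12) {
  kind <- match.arg(kind)
  if (!state$converged) {
    stop("SCF state is not converged", call. = FALSE)
  }
  cell <- state$cell
  pts <- .grid_points(spec)
  lat <- if (cell$pdim == 0L) matrix(0, 0, 3) else cell$lattice
  vals <- switch(kind,
    density = {
      phi <- basis_matrix_cpp(state$apar, cell_coords(cell), lat, pts,
                              basis_cutoff)
      m <- phi %*% state$coefficients[, seq_len(state$n_occ), drop = FALSE]
      nrm <- .mo_norms(state, lat, basis_cutoff)[seq_len(state$n_occ)]
      2 * as.vector(m^2 %*% (1 / nrm)) / ANGSTROM_PER_BOHR^3
    },
    mep = {
      v <- mep_cpp(state$apar, cell_coords(cell), lat, pts, state$p,
                   state$offsets, state$config$screening_r / 2)
      ev_to_kcal(hartree_to_ev(v))
    },
    ie_local = .orbital_weighted(state, pts, lat, basis_cutoff,
                                 occupied = TRUE),
    ea_local = .orbital_weighted(state, pts, lat, basis_cutoff,
                                 occupied = FALSE),
    electronegativity = {
      0.5 * (.orbital_weighted(state, pts, lat, basis_cutoff, TRUE) +
             .orbital_weighted(state, pts, lat, basis_cutoff, FALSE))
    },
    hardness = {
      0.5 * (.orbital_weighted(state, pts, lat, basis_cutoff, TRUE) -
             .orbital_weighted(state, pts, lat, basis_cutoff, FALSE))
    })
  structure(list(spec = spec, kind = kind,
                 values = array(vals, dim = spec$npts)),
            class = "property_grid")
}

# MO norms in the raw (non-orthogonal) STO metric, for the per-orbital
# renormalization of grid densities. The MO coefficients live in the
# orthogonalized NDDO basis; applying them to raw Slater functions is the
# documented grid approximation, and renormalizing each orbital keeps the
# density integral at the electron count.
.mo_norms <- function(state, lat, basis_cutoff) {
  s_real <- overlap_matrix_cpp(state$apar, cell_coords(state$cell), lat,
                               basis_cutoff)
  colSums(state$coefficients * (s_real %*% state$coefficients))
}

# orbital-density weighted mean of orbital energies (kcal/mol), with the
# sign convention IE_L = -<e_occ>, EA_L = -<e_virt>
.orbital_weighted <- function(state, pts, lat, basis_cutoff, occupied) {
  nocc <- state$n_occ
  norb <- length(state$orbital_energies)
  idx <- if (occupied) seq_len(nocc) else setdiff(seq_len(norb),
                                                  seq_len(nocc))
  if (length(idx) == 0L) {
    stop("no ", if (occupied) "occupied" else "virtual",
         " orbitals available", call. = FALSE)
  }
  phi <- basis_matrix_cpp(state$apar, cell_coords(state$cell), lat, pts,
                          basis_cutoff)
  m <- phi %*% state$coefficients[, idx, drop = FALSE]
  nrm <- .mo_norms(state, lat, basis_cutoff)[idx]
  rho <- sweep(m^2, 2, nrm, "/")              # per-orbital densities
  w <- rho %*% state$orbital_energies[idx]
  tot <- rowSums(rho)
  ev_to_kcal(-w / pmax(tot, 1e-300))
}

#' Extract a 2-D slice from a property grid
#'
#' @param grid a `property_grid`.
#' @param axis slice normal: 1, 2 or 3 (grid direction index).
#' @param index 1-based plane index along that direction.
#' @return list with `values` (2-D matrix) and the two in-plane axis
#'   vectors.
#' @export
extract_slice <- function(grid, axis, index) {
  stopifnot(axis %in% 1:3)
  n <- grid$spec$npts
  if (index < 1L || index > n[axis]) {
    stop("slice index out of range", call. = FALSE)
  }
  vals <- switch(axis,
                 grid$values[index, , ],
                 grid$values[, index, ],
                 grid$values[, , index])
  inplane <- grid$spec$axes[setdiff(1:3, axis), , drop = FALSE]
  list(values = as.matrix(vals), axes = inplane, axis = axis,
       index = index)
}

#' @export
print.property_grid <- function(x, ...) {
  cat(sprintf("<property grid '%s': %d x %d x %d points, range [%g, %g]>\n",
              x$kind, x$spec$npts[1], x$spec$npts[2], x$spec$npts[3],
              min(x$values), max(x$values)))
  invisible(x)
}

#' Write a property grid as a Gaussian cube file
#'
#' Standard cube layout: header with origin and axis steps in bohr, one
#' line per atom (nuclear charge and coordinates in bohr), then the
#' volumetric data with the last grid index fastest.
#'
#' @param grid a `property_grid`.
#' @param cell the [cell] the grid belongs to.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_cube <- function(grid, cell, path) {
  spec <- grid$spec
  n <- spec$npts
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("cycluster property grid",
               sprintf("kind: %s", grid$kind)), con)
  o <- angstrom_to_bohr(spec$origin)
  writeLines(sprintf("%5d %11.6f %11.6f %11.6f", nrow(cell$atoms),
                     o[1], o[2], o[3]), con)
  for (i in 1:3) {
    st <- angstrom_to_bohr(spec$axes[i, ]) / n[i]
    writeLines(sprintf("%5d %11.6f %11.6f %11.6f", n[i],
                       st[1], st[2], st[3]), con)
  }
  xyz <- angstrom_to_bohr(cell_coords(cell))
  z <- vapply(cell$atoms$element,
              function(s) element_params(s)$z, integer(1))
  writeLines(sprintf("%5d %11.6f %11.6f %11.6f %11.6f", z, as.numeric(z),
                     xyz[, 1], xyz[, 2], xyz[, 3]), con)
  # data order: x slowest, z fastest
  lines <- character(0)
  for (ix in seq_len(n[1])) {
    for (iy in seq_len(n[2])) {
      row <- grid$values[ix, iy, ]
      lines <- c(lines, paste(sprintf("%13.5e", row), collapse = " "))
    }
  }
  writeLines(lines, con)
  invisible(path)
}

#' Write a grid slice as tab-separated text
#'
#' @param slice a slice from [extract_slice].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_slice_tsv <- function(slice, path) {
  utils::write.table(slice$values, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a Gaussian cube file written by [write_cube]
#'
#' @param path cube file path.
#' @return list with `spec` (a [grid_spec]), `values` (3-D array) and
#'   `atoms` (data.frame: z, x, y, z coordinates in Angstrom).
#' @export
read_cube <- function(path) {
  lines <- readLines(path, warn = FALSE)
  hdr3 <- strsplit(trimws(lines[3]), "[ \t]+")[[1]]
  natom <- as.integer(hdr3[1])
  origin <- bohr_to_angstrom(as.numeric(hdr3[2:4]))
  npts <- integer(3)
  axes <- matrix(0, 3, 3)
  for (i in 1:3) {
    p <- strsplit(trimws(lines[3 + i]), "[ \t]+")[[1]]
    npts[i] <- as.integer(p[1])
    axes[i, ] <- bohr_to_angstrom(as.numeric(p[2:4])) * npts[i]
  }
  at <- do.call(rbind, lapply(lines[7:(6 + natom)], function(ln) {
    as.numeric(strsplit(trimws(ln), "[ \t]+")[[1]])
  }))
  vals <- as.numeric(unlist(strsplit(trimws(lines[(7 + natom):
                                                    length(lines)]),
                                     "[ \t]+")))
  arr <- array(0, dim = npts)
  k <- 1L
  for (ix in seq_len(npts[1])) {
    for (iy in seq_len(npts[2])) {
      arr[ix, iy, ] <- vals[k:(k + npts[3] - 1L)]
      k <- k + npts[3]
    }
  }
  list(spec = grid_spec(origin, axes, npts), values = arr,
       atoms = data.frame(z = at[, 1],
                          x = bohr_to_angstrom(at[, 3]),
                          y = bohr_to_angstrom(at[, 4]),
                          z_coord = bohr_to_angstrom(at[, 5])))
}
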
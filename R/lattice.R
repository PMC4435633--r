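# Unit-cell geometry: the single supercell of the cyclic-cluster model.
# Coordinates are Cartesian Angstrom throughout; lattice vectors are rows of
# the `lattice` matrix; fractional coordinates appear only internally.

#' Create a cell (atoms plus 0-3 lattice vectors)
#'
#' The central container of the package: a set of atoms with Cartesian
#' coordinates in Angstrom and `0 <= d <= 3` lattice vectors defining the
#' periodic directions of a cyclic-cluster calculation. Non-periodic
#' molecules are cells with `d = 0`.
#'
#' @param elements character vector of element symbols.
#' @param coords numeric matrix (n x 3) of Cartesian positions, Angstrom.
#' @param lattice `NULL`, or a (d x 3) matrix of lattice vectors (rows),
#'   Angstrom, with `d` in 1..3.
#' @param charge integer net charge (must be 0 for periodic SCF runs).
#' @return an object of class `cell`: a list with elements `atoms` (a
#'   data.frame with columns `element`, `x`, `y`, `z`), `lattice`, `pdim`
#'   and `charge`.
#' @examples
#' water <- molecule_fixture("water_am1")
#' cell(water$atoms$element, as.matrix(water$atoms[, c("x", "y", "z")]))
#' @export
cell <- function(elements, coords, lattice = NULL, charge = 0L) {
  coords <- as.matrix(coords)
  storage.mode(coords) <- "double"
  if (ncol(coords) != 3L || nrow(coords) != length(elements) ||
      nrow(coords) < 1L) {
    stop("coords must be an n x 3 matrix matching length(elements), n >= 1",
         call. = FALSE)
  }
  if (!all(is.finite(coords))) stop("non-finite coordinates", call. = FALSE)
  elements <- normalize_symbol(elements)
  if (!is.null(lattice)) {
    lattice <- matrix(as.numeric(lattice), ncol = 3L)
    if (nrow(lattice) < 1L || nrow(lattice) > 3L) {
      stop("lattice must have 1-3 row vectors", call. = FALSE)
    }
    if (qr(lattice)$rank < nrow(lattice)) {
      stop("lattice vectors are linearly dependent", call. = FALSE)
    }
  }
  structure(list(
    atoms = data.frame(element = elements, x = coords[, 1], y = coords[, 2],
                       z = coords[, 3], stringsAsFactors = FALSE),
    lattice = lattice,
    pdim = if (is.null(lattice)) 0L else nrow(lattice),
    charge = as.integer(charge)
  ), class = "cell")
}

#' @export
print.cell <- function(x, ...) {
  comp <- table(x$atoms$element)
  cat(sprintf("<cell: %d atoms (%s), %d-D periodic, charge %+d>\n",
              nrow(x$atoms),
              paste(sprintf("%s%d", names(comp), comp), collapse = " "),
              x$pdim, x$charge))
  if (x$pdim > 0L) {
    cat("lattice (A):\n")
    print(round(x$lattice, 6))
  }
  invisible(x)
}

#' Cartesian coordinates of a cell as a matrix
#'
#' @param cell a [cell].
#' @return n x 3 numeric matrix, Angstrom.
#' @export
cell_coords <- function(cell) {
  as.matrix(cell$atoms[, c("x", "y", "z")])
}

# Longest diagonal of the periodic repeat box (A); 0 for molecules.
cell_diameter <- function(cell) {
  if (cell$pdim == 0L) return(0)
  corners <- as.matrix(expand.grid(rep(list(c(0, 1)), cell$pdim)))
  pts <- corners %*% cell$lattice
  max(sqrt(rowSums(pts^2)))
}

# Integer translation shells. The +/-2 default per periodic direction covers
# reasonable cells; it is widened automatically for strongly skewed cells
# (any inter-vector angle below 45 degrees).
.shell_width <- function(cell) {
  w <- 2L
  if (cell$pdim >= 2L) {
    L <- cell$lattice
    for (i in seq_len(cell$pdim - 1L)) {
      for (j in (i + 1L):cell$pdim) {
        cosang <- abs(sum(L[i, ] * L[j, ])) /
          sqrt(sum(L[i, ]^2) * sum(L[j, ]^2))
        if (cosang > cos(pi / 4)) w <- 4L
      }
    }
  }
  w
}

.shell_translations <- function(cell, width = .shell_width(cell)) {
  d <- cell$pdim
  grids <- rep(list(-width:width), d)
  idx <- as.matrix(expand.grid(grids))
  idx %*% cell$lattice[seq_len(d), , drop = FALSE]
}

#' Minimum-image displacement
#'
#' Maps a displacement vector to its shortest periodic image
#' `dr + n1*a1 + n2*a2 + n3*a3`. Components along non-periodic directions are
#' unchanged; for a non-periodic cell the displacement is returned as is.
#'
#' @param cell a [cell].
#' @param dr displacement vector (length 3) or n x 3 matrix, Angstrom.
#' @return the minimum-image displacement(s), same shape as `dr`.
#' @export
minimum_image <- function(cell, dr) {
  vec_in <- is.null(dim(dr))
  dr <- matrix(as.numeric(dr), ncol = 3L)
  if (cell$pdim > 0L) {
    L <- cell$lattice
    # wrap to the home cell first (handles arbitrarily distant images),
    # then search the surrounding shell
    proj <- dr %*% t(L) %*% solve(L %*% t(L))
    dr <- dr - round(proj) %*% L
    tr <- .shell_translations(cell)
    for (k in seq_len(nrow(dr))) {
      cand <- sweep(tr, 2, dr[k, ], "+")
      dr[k, ] <- cand[which.min(rowSums(cand^2)), ]
    }
  }
  if (vec_in) drop(dr) else dr
}

#' Enumerate lattice translations within a radius
#'
#' All integer-combination translations `T` with `|T| <= r_max + diameter`,
#' where `diameter` is the periodic repeat-box diagonal, so that every atom
#' pair with separation up to `r_max` is covered. The zero translation comes
#' first; order is deterministic (by `|T|`, ties broken lexicographically).
#'
#' @param cell a [cell].
#' @param r_max positive radius, Angstrom.
#' @param pad extra margin added to the search radius, Angstrom.
#' @return m x 3 matrix of translation vectors, Angstrom.
#' @export
lattice_images_within <- function(cell, r_max, pad = cell_diameter(cell)) {
  stopifnot(r_max > 0)
  if (cell$pdim == 0L) return(matrix(0, 1, 3))
  d <- cell$pdim
  L <- cell$lattice[seq_len(d), , drop = FALSE]
  rcut <- r_max + pad
  # bound on integer indices: project rcut onto the reciprocal directions
  gram_inv <- solve(L %*% t(L))
  nmax <- ceiling(rcut * sqrt(diag(gram_inv))) + 1L
  grids <- lapply(seq_len(d), function(i) -nmax[i]:nmax[i])
  idx <- as.matrix(expand.grid(grids))
  tr <- idx %*% L
  keep <- sqrt(rowSums(tr^2)) <= rcut + 1e-12
  tr <- tr[keep, , drop = FALSE]
  ord <- order(round(sqrt(rowSums(tr^2)), 9), tr[, 1], tr[, 2], tr[, 3])
  tr[ord, , drop = FALSE]
}

#' Wigner-Seitz cell membership
#'
#' Tests whether a displacement lies in the Wigner-Seitz cell of the lattice:
#' strictly closer to the origin than to any non-zero lattice translation.
#' Boundary ties (equal distances within 1e-9 A) are resolved by
#' lexicographic comparison of the candidate image vectors, so that exactly
#' one image of any displacement is accepted.
#'
#' @param cell a periodic [cell].
#' @param dr displacement vector, Angstrom.
#' @return logical.
#' @export
in_wigner_seitz <- function(cell, dr) {
  stopifnot(cell$pdim > 0L)
  dr <- as.numeric(dr)
  tr <- .shell_translations(cell)
  cand <- sweep(tr, 2, dr, "+")
  n2 <- rowSums(cand^2)
  best <- .ws_pick(cand, n2)
  isTRUE(all.equal(cand[best, ], dr, tolerance = 1e-12,
                   check.attributes = FALSE))
}

# Deterministic representative among near-degenerate minimum images:
# smallest |v|, ties within 1e-9 A broken lexicographically on (x, y, z).
.ws_pick <- function(cand, n2) {
  r <- sqrt(n2)
  tied <- which(r <= min(r) + 1e-9)
  if (length(tied) == 1L) return(tied)
  o <- tied[order(cand[tied, 1], cand[tied, 2], cand[tied, 3])]
  o[1L]
}

#' Expand a cell into a supercell
#'
#' Replicates the atoms over an `n1 x n2 x n3` block of lattice translations
#' and scales the lattice vectors accordingly. Atom ordering is
#' deterministic: translation-major, original order within each copy.
#'
#' @param cell a periodic [cell].
#' @param repeats integer vector of length `pdim` (or 3; extra entries must
#'   be 1 for non-periodic directions).
#' @return the expanded [cell].
#' @export
supercell <- function(cell, repeats) {
  d <- cell$pdim
  stopifnot(d > 0L)
  repeats <- as.integer(repeats)
  if (length(repeats) < d) repeats <- c(repeats, rep(1L, d - length(repeats)))
  stopifnot(all(repeats >= 1L))
  L <- cell$lattice
  grids <- lapply(seq_len(d), function(i) 0:(repeats[i] - 1L))
  idx <- as.matrix(expand.grid(grids))
  # translation-major deterministic order
  idx <- idx[do.call(order, as.data.frame(idx)[rev(seq_len(d))]), ,
             drop = FALSE]
  tr <- idx %*% L[seq_len(d), , drop = FALSE]
  xyz <- cell_coords(cell)
  coords <- do.call(rbind, lapply(seq_len(nrow(tr)), function(k) {
    sweep(xyz, 2, tr[k, ], "+")
  }))
  elements <- rep(cell$atoms$element, times = nrow(tr))
  newlat <- L
  for (i in seq_len(d)) newlat[i, ] <- L[i, ] * repeats[i]
  cell(elements, coords, newlat, charge = cell$charge * prod(repeats))
}
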
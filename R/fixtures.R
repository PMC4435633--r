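# Programmatic crystal and molecular fixtures. Lattice constants are
# standard literature values and are overridable; they serve as test
# scaffolding, not as fitted quantities.

#' Generate a crystal or molecular-box fixture
#'
#' Builds one of the stock structures used throughout the test-suite and the
#' examples: the conventional 8-atom diamond cell, rocksalt NaCl, wurtzite
#' ZnO, or a molecular box (a molecule centered in a cubic periodic box),
#' optionally expanded to an `n1 x n2 x n3` supercell.
#'
#' @param kind one of `"diamond"`, `"rocksalt"`, `"wurtzite"`,
#'   `"molecular_box"`.
#' @param repeats integer repetition counts, default `c(1, 1, 1)`.
#' @param a,c_axis lattice constants in Angstrom (defaults: diamond
#'   a = 3.567; NaCl a = 5.64; ZnO a = 3.25, c = 5.207).
#' @param molecule for `"molecular_box"`: a [cell] (non-periodic) to center
#'   in the box; defaults to the water fixture.
#' @param box_edge for `"molecular_box"`: cubic box edge, Angstrom.
#' @return a periodic [cell].
#' @examples
#' crystal_fixture("diamond", c(2, 2, 2))  # the 64-atom diamond cell
#' @export
crystal_fixture <- function(kind, repeats = c(1L, 1L, 1L), a = NULL,
                            c_axis = NULL, molecule = NULL,
                            box_edge = 70) {
  kind <- match.arg(kind, c("diamond", "rocksalt", "wurtzite",
                            "molecular_box"))
  base <- switch(kind,
    diamond = {
      if (is.null(a)) a <- 3.567
      fc <- rbind(c(0, 0, 0), c(0, .5, .5), c(.5, 0, .5), c(.5, .5, 0))
      frac <- rbind(fc, sweep(fc, 2, c(.25, .25, .25), "+"))
      cell(rep("C", 8L), frac %*% diag(rep(a, 3)), diag(rep(a, 3)))
    },
    rocksalt = {
      if (is.null(a)) a <- 5.64
      na <- rbind(c(0, 0, 0), c(.5, .5, 0), c(.5, 0, .5), c(0, .5, .5))
      cl <- rbind(c(.5, 0, 0), c(0, .5, 0), c(0, 0, .5), c(.5, .5, .5))
      cell(c(rep("Na", 4L), rep("Cl", 4L)),
           rbind(na, cl) %*% diag(rep(a, 3)), diag(rep(a, 3)))
    },
    wurtzite = {
      if (is.null(a)) a <- 3.25
      if (is.null(c_axis)) c_axis <- 5.207
      u <- 0.382
      L <- rbind(c(a, 0, 0),
                 c(-a / 2, a * sqrt(3) / 2, 0),
                 c(0, 0, c_axis))
      frac <- rbind(c(1 / 3, 2 / 3, 0), c(2 / 3, 1 / 3, 0.5),   # Zn
                    c(1 / 3, 2 / 3, u), c(2 / 3, 1 / 3, 0.5 + u)) # O
      cell(c("Zn", "Zn", "O", "O"), frac %*% L, L)
    },
    molecular_box = {
      if (is.null(molecule)) molecule <- molecule_fixture("water_am1")
      stopifnot(inherits(molecule, "cell"), molecule$pdim == 0L)
      xyz <- cell_coords(molecule)
      ctr <- colMeans(xyz)
      xyz <- sweep(xyz, 2, ctr - box_edge / 2, "-")
      cell(molecule$atoms$element, xyz, diag(rep(box_edge, 3)),
           charge = molecule$charge)
    })
  if (all(repeats == 1L)) base else supercell(base, repeats)
}

#' Stock molecular geometries
#'
#' Small gas-phase molecules at fixed reference geometries. The `_am1`
#' variants use the published AM1 equilibrium geometries (water: r(OH) =
#' 0.961 A, angle 103.5 deg; methane: r(CH) = 1.112 A, tetrahedral), so that
#' single-point energies are directly comparable with the method literature.
#'
#' @param name one of `"water_am1"`, `"methane_am1"`, `"h2"`, `"nacl"`.
#' @return a non-periodic [cell].
#' @export
molecule_fixture <- function(name) {
  name <- match.arg(name, c("water_am1", "methane_am1", "h2", "nacl"))
  switch(name,
    water_am1 = {
      r <- 0.961; half <- (103.5 / 2) * pi / 180
      cell(c("O", "H", "H"),
           rbind(c(0, 0, 0),
                 c(r * sin(half), 0, r * cos(half)),
                 c(-r * sin(half), 0, r * cos(half))))
    },
    methane_am1 = {
      r <- 1.112; s <- r / sqrt(3)
      cell(c("C", "H", "H", "H", "H"),
           rbind(c(0, 0, 0), c(s, s, s), c(s, -s, -s),
                 c(-s, s, -s), c(-s, -s, s)))
    },
    h2 = cell(c("H", "H"), rbind(c(0, 0, 0), c(0, 0, 0.677))),
    nacl = cell(c("Na", "Cl"), rbind(c(0, 0, 0), c(0, 0, 2.36)))
  )
}

#' Wurtzite ZnO (10-10) slab fixture
#'
#' A two-dimensionally periodic slab exposing the non-polar (10-10) surface,
#' built from the wurtzite cell, optionally with one surface ZnO dimer
#' removed (the most abundant point defect on this surface). With the
#' default dimensions the defective slab contains 766 atoms and 3064
#' valence electrons.
#'
#' @param n_c repetitions along the c axis (periodic).
#' @param n_a repetitions along the surface a axis (periodic).
#' @param n_layers repetitions along the surface normal (not periodic).
#' @param vacancy remove one surface ZnO dimer?
#' @param a,c_axis wurtzite lattice constants, Angstrom.
#' @return a 2-D periodic [cell].
#' @examples
#' slab <- zno_slab_fixture()
#' nrow(slab$atoms)                # 766
#' valence_electron_count(slab)    # 3064
#' @export
zno_slab_fixture <- function(n_c = 8L, n_a = 6L, n_layers = 4L,
                             vacancy = TRUE, a = 3.25, c_axis = 5.207) {
  bulk <- crystal_fixture("wurtzite", c(n_a, n_layers, n_c),
                          a = a, c_axis = c_axis)
  # periodic along lattice vectors 1 (a) and 3 (c); direction 2 becomes the
  # surface normal
  slab <- cell(bulk$atoms$element, cell_coords(bulk),
               bulk$lattice[c(1, 3), , drop = FALSE])
  if (vacancy) {
    xyz <- cell_coords(slab)
    nrm <- slab$atoms$element   # pick the outermost Zn and its O partner
    depth <- xyz %*% c(0, 1, 0)
    zn <- which(nrm == "Zn")[which.max(depth[nrm == "Zn"])]
    ox <- which(nrm == "O")
    ox <- ox[which.min(rowSums(sweep(xyz[ox, , drop = FALSE], 2,
                                     xyz[zn, ], "-")^2))]
    keep <- setdiff(seq_len(nrow(xyz)), c(zn, ox))
    slab <- cell(slab$atoms$element[keep], xyz[keep, , drop = FALSE],
                 slab$lattice)
  }
  slab
}
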
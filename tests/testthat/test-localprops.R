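test_that("density grid integrates to the electron count", {
  st <- scf(molecule_fixture("water_am1"))
  spec <- grid_spec(c(-6, -6, -5), diag(c(12, 12, 11)), c(48, 48, 44))
  g <- local_property_grid(st, "density", spec)
  dv <- prod(c(12, 12, 11) / c(48, 48, 44))
  expect_equal(sum(g$values) * dv, st$n_electrons, tolerance = 0.02 * 8)
  expect_true(all(g$values >= 0))
  expect_true(all(is.finite(g$values)))
})

test_that("grids refuse unconverged states and unknown kinds", {
  st <- scf(molecule_fixture("h2"))
  st_bad <- st; st_bad$converged <- FALSE
  expect_error(local_property_grid(st_bad, "density"), "not converged")
  expect_error(local_property_grid(st, "banana"))
})

test_that("local ionization energy collapses for a one-orbital spectrum", {
  st <- scf(cell("Zn", matrix(0, 1, 3)))
  g <- local_property_grid(st, "ie_local",
                           grid_spec(c(-2, -2, -2), diag(4, 3), c(5, 5, 5)))
  expect_lt(diff(range(g$values)), 1e-9)
  expect_equal(g$values[1, 1, 1], -23.061 * homo_lumo(st)[["homo"]],
               tolerance = 1e-6)
})

test_that("local ionization energy is bounded by the occupied spectrum", {
  st <- scf(molecule_fixture("water_am1"))
  g <- local_property_grid(st, "ie_local",
                           grid_spec(c(-3, -3, -2), diag(c(6, 6, 5)),
                                     c(9, 9, 9)))
  eo <- st$orbital_energies[seq_len(st$n_occ)]
  expect_gte(min(g$values), -23.061 * max(eo) - 1e-6)
  expect_lte(max(g$values), -23.061 * min(eo) + 1e-6)
  # derived grids: electronegativity and hardness combine IE_L and EA_L
  ea <- local_property_grid(st, "ea_local",
                            grid_spec(c(-3, -3, -2), diag(c(6, 6, 5)),
                                      c(9, 9, 9)))
  en <- local_property_grid(st, "electronegativity",
                            grid_spec(c(-3, -3, -2), diag(c(6, 6, 5)),
                                      c(9, 9, 9)))
  expect_equal(en$values, (g$values + ea$values) / 2, tolerance = 1e-9)
})

test_that("electrostatic potential has the physical sign structure", {
  st <- scf(molecule_fixture("water_am1"))
  xyz <- cell_coords(st$cell)
  # probe just outside an H atom along the O-H bond, and behind O
  vh <- xyz[2, ] + (xyz[2, ] - xyz[1, ]) * 0.8
  vo <- xyz[1, ] - c(0, 0, 1.0)
  pts <- rbind(vh, vo, c(0, 50, 0))
  v <- cycluster:::mep_cpp(st$apar, xyz, matrix(0, 0, 3), pts, st$p,
                           st$offsets, 15) * 27.21 * 23.061
  expect_gt(v[1], 0)
  expect_lt(v[2], 0)
  expect_lt(abs(v[3]), 0.01)     # neutral molecule: potential dies off
})

test_that("periodic grids are exactly lattice-periodic", {
  d <- crystal_fixture("diamond")
  st <- scf(d)
  set.seed(31)
  pts <- matrix(runif(15, 0, 3.5), 5, 3)
  for (shift in list(d$lattice[1, ], d$lattice[2, ] + d$lattice[3, ])) {
    p1 <- cycluster:::basis_matrix_cpp(st$apar, cell_coords(d), d$lattice,
                                       pts, 12)
    p2 <- cycluster:::basis_matrix_cpp(st$apar, cell_coords(d), d$lattice,
                                       sweep(pts, 2, shift, "+"), 12)
    r1 <- rowSums((p1 %*% st$p) * p1)
    r2 <- rowSums((p2 %*% st$p) * p2)
    expect_equal(r1, r2, tolerance = 1e-8)
    v1 <- cycluster:::mep_cpp(st$apar, cell_coords(d), d$lattice, pts,
                              st$p, st$offsets, 15)
    v2 <- cycluster:::mep_cpp(st$apar, cell_coords(d), d$lattice,
                              sweep(pts, 2, shift, "+"), st$p, st$offsets,
                              15)
    expect_equal(v1, v2, tolerance = 1e-8)
  }
})

test_that("slices partition the grid and re-stack losslessly", {
  st <- scf(molecule_fixture("water_am1"))
  g <- local_property_grid(st, "density",
                           grid_spec(c(-4, -4, -3), diag(c(8, 8, 7)),
                                     c(6, 7, 8)))
  for (axis in 1:3) {
    rebuilt <- array(NA_real_, dim = g$spec$npts)
    for (i in seq_len(g$spec$npts[axis])) {
      sl <- extract_slice(g, axis, i)$values
      if (axis == 1) rebuilt[i, , ] <- sl
      if (axis == 2) rebuilt[, i, ] <- sl
      if (axis == 3) rebuilt[, , i] <- sl
    }
    expect_identical(rebuilt, g$values)
  }
  expect_error(extract_slice(g, 2, 99), "out of range")
  # a constant grid slices to a constant
  gc <- g; gc$values[] <- 3.25
  expect_true(all(extract_slice(gc, 2, 3)$values == 3.25))
  # a slice equals direct re-evaluation of the property at those points
  sub <- g$spec
  sub$origin <- sub$origin + (4 - 1) / g$spec$npts[3] * g$spec$axes[3, ]
  direct <- local_property_grid(st, "density",
                                grid_spec(sub$origin, sub$axes,
                                          g$spec$npts))
  expect_equal(extract_slice(g, 3, 4)$values, direct$values[, , 1],
               tolerance = 1e-10)
})

test_that("cube files round-trip through the package reader", {
  st <- scf(molecule_fixture("water_am1"))
  g <- local_property_grid(st, "mep",
                           grid_spec(c(-4, -4, -3), diag(c(8, 8, 7)),
                                     c(6, 6, 6)))
  f <- tempfile(fileext = ".cube")
  write_cube(g, st$cell, f)
  rc <- read_cube(f)
  expect_identical(rc$spec$npts, g$spec$npts)
  expect_equal(rc$spec$axes, g$spec$axes, tolerance = 1e-4)
  expect_equal(rc$values, g$values, tolerance = 1e-4)
  expect_identical(nrow(rc$atoms), 3L)
  unlink(f)
  # slice export as tab-separated text round-trips
  sl <- extract_slice(g, 3, 2)
  f2 <- tempfile(fileext = ".tsv")
  write_slice_tsv(sl, f2)
  back <- as.matrix(read.delim(f2, header = FALSE))
  expect_equal(unname(back), unname(sl$values), tolerance = 1e-10)
  unlink(f2)
})
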
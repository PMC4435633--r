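test_that("core Hamiltonian: isolated one-orbital atom and hermiticity", {
  h1 <- build_core_hamiltonian(cell("H", matrix(0, 1, 3)))
  expect_equal(dim(h1), c(1L, 1L))
  expect_equal(h1[1, 1], element_params("H", "AM1")$uss, tolerance = 1e-12)
  set.seed(21)
  m <- cell(c("C", "O", "H", "H"), matrix(rnorm(12, sd = 1.2), 4, 3) +
              matrix(rep(c(0, 1.3, -1.2, 2.2), 3), 4, 3))
  H <- build_core_hamiltonian(m)
  expect_lt(max(abs(H - t(H))), 1e-10)
  d <- crystal_fixture("diamond")
  Hd <- build_core_hamiltonian(d)
  expect_lt(max(abs(Hd - t(Hd))), 1e-10)
  # overlapping atoms rejected
  expect_error(build_core_hamiltonian(
    cell(c("C", "C"), rbind(c(0, 0, 0), c(0, 0, 0.1)))), "0.5 bohr")
})

test_that("open shells and charged periodic cells are refused", {
  expect_error(scf(cell("H", matrix(0, 1, 3))), "open shell")
  d <- crystal_fixture("diamond")
  d$charge <- 2L
  expect_error(scf(d), "neutral")
})

test_that("an isolated closed-shell atom converges immediately and exactly", {
  st <- scf(cell("Zn", matrix(0, 1, 3)))
  expect_true(st$converged)
  expect_lte(nrow(st$history), 3)
  p <- element_params("Zn", "AM1")
  expect_equal(st$e_total, p$eisol, tolerance = 1e-8)
  expect_equal(st$hf, p$hf_atom, tolerance = 1e-8)
})

test_that("the Fock energy agrees with an explicit supermatrix resummation", {
  for (fix in c("h2", "water_am1")) {
    st <- scf(molecule_fixture(fix))
    H <- build_core_hamiltonian(st$cell)
    e1 <- sum(st$p * H)
    e2 <- r_two_electron_energy(st)
    expect_equal(st$e_electronic, e1 + e2, tolerance = 1e-8)
  }
})

test_that("a huge periodic box reproduces the gas-phase Fock and energy", {
  w <- molecule_fixture("water_am1")
  box <- crystal_fixture("molecular_box", molecule = w, box_edge = 70)
  st_gas <- scf(w)
  p <- st_gas$p
  f_gas <- build_fock(w, p)
  f_box <- build_fock(box, p)
  expect_lt(max(abs(f_gas$F - f_box$F)), 1e-10)
  expect_lt(abs(scf(box)$e_total - st_gas$e_total), 1e-6)
})

test_that("published AM1 results are reproduced at published geometries", {
  # reference values from the AM1 method literature
  stw <- scf(molecule_fixture("water_am1"))
  expect_true(stw$converged)
  expect_equal(heat_of_formation(stw), -59.2, tolerance = 0.1)
  ch <- coulson_charges(stw)
  expect_lt(ch$charge[1], 0)            # oxygen negative
  expect_gt(ch$charge[2], 0)
  expect_equal(ch$charge[2], ch$charge[3], tolerance = 1e-8)
  expect_equal(dipole_moment(stw)$total, 1.86, tolerance = 0.02)
  stm <- scf(molecule_fixture("methane_am1"))
  expect_equal(heat_of_formation(stm), -8.8, tolerance = 0.1)
  chm <- coulson_charges(stm)
  expect_equal(sum(chm$charge), 0, tolerance = 1e-8)
  expect_equal(chm$charge[1], -4 * chm$charge[2], tolerance = 1e-7)
})

test_that("density matrix trace and idempotency hold at convergence", {
  for (fix in list(molecule_fixture("water_am1"), crystal_fixture("diamond"))) {
    st <- scf(fix)
    expect_equal(sum(diag(st$p)), st$n_electrons, tolerance = 1e-8)
    expect_lt(max(abs(st$p %*% st$p / 2 - st$p)), 1e-5)
    expect_true(all(diff(st$orbital_energies) >= -1e-10))
  }
})

test_that("compensated summation survives adversarial cancellation", {
  expect_identical(compensated_sum(numeric(0)), 0)
  expect_equal(compensated_sum(c(1e16, 1, -1e16)), 1)
  expect_equal(compensated_sum(rep(0.1, 1e6)), 1e5, tolerance = 1e-9)
  # exact oracle: dyadic values sum exactly
  v <- c(2^-c(1:40), -2^-c(1:40), 1)
  expect_identical(compensated_sum(v), 1)
  set.seed(4)
  big <- rnorm(500) * 1e12
  small <- rnorm(500)
  v <- sample(c(big, -big, small))
  expect_equal(compensated_sum(v), compensated_sum(small), tolerance = 1e-9)
})

test_that("heat of formation bookkeeping is exact and extensive", {
  expect_error(heat_of_formation(structure(list(converged = FALSE),
                                           class = "scf_state")),
               "converge")
  # extensivity on a molecular box: doubling the box doubles the heat of
  # formation exactly (all image interactions beyond every cutoff)
  b <- crystal_fixture("molecular_box", box_edge = 70)
  h1 <- scf(b)$hf
  h2 <- scf(supercell(b, c(2, 1, 1)))$hf
  expect_equal(h2 / h1, 2, tolerance = 1e-6)
})

test_that("Coulson charges conserve the net charge on every fixture", {
  fixtures <- list(molecule_fixture("water_am1"),
                   crystal_fixture("diamond"),
                   crystal_fixture("rocksalt"),
                   crystal_fixture("wurtzite"))
  for (fx in fixtures) {
    st <- scf(fx)
    expect_true(st$converged)
    expect_equal(sum(coulson_charges(st)$charge), 0, tolerance = 1e-8)
  }
  # homonuclear diatomic: symmetry-equal charges
  sth <- scf(molecule_fixture("h2"))
  expect_equal(coulson_charges(sth)$charge, c(0, 0), tolerance = 1e-9)
})

test_that("the periodic energy is invariant under translation and relabeling", {
  set.seed(1)
  d <- crystal_fixture("diamond")
  e0 <- scf(d)$e_total
  d_tr <- cell(d$atoms$element,
               sweep(cell_coords(d), 2, c(0.37, -1.21, 0.55), "+"),
               d$lattice)
  expect_lt(abs(scf(d_tr)$e_total - e0), 1e-8)
  perm <- sample(nrow(d$atoms))
  d_pm <- cell(d$atoms$element[perm], cell_coords(d)[perm, ], d$lattice)
  expect_lt(abs(scf(d_pm)$e_total - e0), 5e-9)
  rs <- crystal_fixture("rocksalt")
  e1 <- scf(rs)$e_total
  perm2 <- sample(nrow(rs$atoms))
  rs_pm <- cell(rs$atoms$element[perm2], cell_coords(rs)[perm2, ],
                rs$lattice)
  expect_lt(abs(scf(rs_pm)$e_total - e1), 5e-9)
})

test_that("tidy and glance summarize a fitted state", {
  st <- scf(molecule_fixture("h2"))
  td <- tidy(st)
  expect_identical(nrow(td), 2L)
  expect_identical(td$occupation, c(2, 0))
  gl <- glance(st)
  expect_identical(gl$converged, TRUE)
  expect_identical(gl$n_electrons, 2L)
  expect_lt(gl$homo, gl$lumo)
})
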
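test_that("parameter records satisfy their structural invariants", {
  for (el in supported_elements()) {
    for (h in c("AM1", "MNDO")) {
      p <- element_params(el, h)
      expect_gte(p$zv, 1)
      expect_gt(p$zs, 0)
      expect_gt(p$gmono, 0)
      expect_equal(p$rho0, 1 / (2 * p$gmono), tolerance = 1e-12)
      expect_equal(p$gmono, p$gss / 27.21, tolerance = 1e-12)
      if (el == "H") {
        expect_identical(p$nbasis, 1L)
      } else {
        expect_identical(p$nbasis, 4L)
        expect_gt(p$zp, 0)
        expect_gt(p$rho1, 0)
        expect_gt(p$rho2, 0)
      }
    }
  }
})

test_that("hydrogen and carbon have the expected basis and valence", {
  h <- element_params("H", "AM1")
  expect_identical(h$nbasis, 1L)
  expect_identical(h$zv, 1L)
  c4 <- element_params("C", "AM1")
  expect_identical(c4$nbasis, 4L)
  expect_identical(c4$zv, 4L)
})

test_that("unsupported species raise a naming error", {
  expect_error(element_params("Xx", "AM1"), "unsupported species.*Xx")
  expect_error(element_params("C", "PM3"), "unsupported species.*PM3")
})

test_that("derived multipole geometry matches independent quadrature", {
  # oracle: D1 = <ns|z|npz> via numerical radial integration; D2 from <r^2>
  for (el in c("C", "O", "Zn")) {
    p <- element_params(el, "AM1")
    n <- p$nq; zs <- p$zs; zp <- p$zp
    ns_c <- (2 * zs)^(n + 0.5) / sqrt(factorial(2 * n))
    np_c <- (2 * zp)^(n + 0.5) / sqrt(factorial(2 * n))
    rad <- integrate(function(r) ns_c * np_c * r^(2 * n + 1) *
                       exp(-(zs + zp) * r), 0, Inf,
                     rel.tol = 1e-12)$value
    expect_equal(p$d1, rad / sqrt(3), tolerance = 1e-10)
    r2 <- integrate(function(r) (np_c * r^(n - 1) * exp(-zp * r))^2 * r^4,
                    0, Inf, rel.tol = 1e-12)$value
    expect_equal(p$d2, sqrt(r2 / 5), tolerance = 1e-10)
  }
})

test_that("doubling both Slater exponents halves the dipole separation", {
  p <- element_params("C", "AM1")
  d1 <- function(zs, zp, n) {
    (2 * n + 1) / sqrt(3) * (4 * zs * zp)^(n + 0.5) / (zs + zp)^(2 * n + 2)
  }
  expect_equal(d1(2 * p$zs, 2 * p$zp, p$nq), 0.5 * d1(p$zs, p$zp, p$nq),
               tolerance = 1e-12)
  expect_error(multipole_distances(element_params("H")), "s-only")
  d <- multipole_distances(p)
  expect_gt(d[["d1"]], 0)
  expect_gt(d[["d2"]], 0)
})

test_that("electron and orbital counting reproduce the published tallies", {
  slab <- zno_slab_fixture()
  expect_identical(nrow(slab$atoms), 766L)
  expect_identical(valence_electron_count(slab), 3064L)
  expect_identical(valence_electron_count("H2O"), 8L)
  expect_identical(valence_electron_count("C32H64NO8P"), 250L)
  expect_identical(orbital_count(crystal_fixture("diamond", c(4, 4, 4))),
                   2048L)
  # 96 formula units of ZnO carry 8 orbitals each
  zno96 <- supercell(crystal_fixture("wurtzite"), c(4, 4, 3))
  expect_identical(orbital_count(zno96), 96L * 8L)
  expect_identical(orbital_count(cell(c("H", "H"),
                                      rbind(c(0, 0, 0), c(0, 0, 0.7)))), 2L)
  expect_identical(membrane_composition(128, 3840)$atoms, 25088L)
})

test_that("counting operations are additive over disjoint unions", {
  a <- crystal_fixture("diamond")
  b <- crystal_fixture("rocksalt")
  joint <- c(a$atoms$element, b$atoms$element)
  expect_identical(valence_electron_count(joint),
                   valence_electron_count(a) + valence_electron_count(b))
  expect_identical(orbital_count(joint), orbital_count(a) + orbital_count(b))
  for (n in c(1, 2, 3, 4)) {
    expect_identical(orbital_count(crystal_fixture("diamond", rep(n, 3))),
                     as.integer(4 * 8 * n^3))
  }
})

test_that("isolated-atom energies reproduce published tabulations", {
  # EISOL is derived from the one-center integrals; the derivation must hit
  # the literature values where those are published
  expect_equal(element_params("C", "MNDO")$eisol, -120.500606,
               tolerance = 1e-6)
  expect_equal(element_params("O", "MNDO")$eisol, -317.868506,
               tolerance = 1e-6)
  expect_equal(element_params("O", "AM1")$eisol, -316.099520,
               tolerance = 1e-6)
  expect_equal(element_params("Zn", "AM1")$eisol, -30.280016,
               tolerance = 1e-6)
})

test_that("additive radii reproduce the printed AD/AQ constants for carbon", {
  p <- element_params("C", "AM1")
  expect_equal(1 / (2 * p$rho1), 0.6082946, tolerance = 2e-7)
  expect_equal(1 / (2 * p$rho2), 0.6423492, tolerance = 2e-7)
  expect_equal(p$d1, 0.8236736, tolerance = 1e-7)
  expect_equal(p$d2, 0.7268015, tolerance = 1e-7)
})

test_that("the parameter table dump covers every element and Hamiltonian", {
  tb <- params_table()
  expect_identical(nrow(tb), 2L * length(supported_elements()))
  expect_true(all(tb$gss > 0))
})
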
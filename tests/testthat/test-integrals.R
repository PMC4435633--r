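test_that("klopman kernel: coincidence limit, asymptote, symmetry", {
  expect_equal(klopman_pair_term(1, 1, 0, 0.5, 0.5), 1.0)
  expect_equal(klopman_pair_term(1, 1, 1e4, 0.3, 0.7) * 1e4, 1,
               tolerance = 1e-7)
  set.seed(2)
  for (k in 1:20) {
    q <- runif(2, -1, 1); r <- runif(1, 0, 5); rho <- runif(2, 0, 2)
    expect_equal(klopman_pair_term(q[1], q[2], r, rho[1], rho[2]),
                 q[1] * q[2] / sqrt(r^2 + sum(rho)^2), tolerance = 1e-14)
    expect_identical(klopman_pair_term(q[1], q[2], r, rho[1], rho[2]),
                     klopman_pair_term(q[2], q[1], r, rho[2], rho[1]))
  }
})

test_that("damped gamma: worked values, limits, monotonicity", {
  # alternate grouping reproduces its closed-form value at the onset
  expect_equal(gamma_damped(10, 1, 1, 10, convention = "product-squared"),
               1 / 14, tolerance = 1e-12)
  # far from the onset both conventions give the bare Coulomb tail
  for (g in c(0.2, 0.45, 1, 2)) {
    expect_equal(gamma_damped(20, g, g, 10), 0.05, tolerance = 1e-10)
    expect_equal(gamma_damped(20, g, g, 10, convention = "product-squared"),
                 0.05, tolerance = 1e-10)
  }
  expect_lt(abs(100 * gamma_damped(100, 0.45, 0.45) - 1), 1e-12)
  # strictly decreasing away from the damping onset; across the onset
  # window the printed functional form has a small documented bump
  r_in <- seq(0.5, 10, by = 0.05)
  expect_true(all(diff(gamma_damped(r_in, 0.45, 0.5)) < 0))
  r_out <- seq(12, 40, by = 0.05)
  expect_true(all(diff(gamma_damped(r_out, 0.45, 0.5)) < 0))
  r_on <- seq(10, 12, by = 0.01)
  expect_lt(max(diff(gamma_damped(r_on, 0.45, 0.5))), 5e-4)
  expect_error(gamma_damped(-1, 1, 1))
})

test_that("damped gamma is approximately continuous at the onset", {
  # documented contract: 5e-3 hartree for all pairs not involving alkali
  # metals, 1.2e-2 hartree for Na pairs (soft monopole constant)
  els <- supported_elements()
  for (a in els) for (b in els) {
    ga <- element_params(a)$gmono; gb <- element_params(b)$gmono
    jump <- abs(gamma_damped(10 - 1e-9, ga, gb) -
                  gamma_damped(10 + 1e-9, ga, gb))
    tol <- if (a == "Na" || b == "Na") 1.2e-2 else 5e-3
    expect_lt(jump, tol)
  }
})

test_that("eri blocks match an independent pure-R re-evaluation", {
  pC <- element_params("C", "AM1")
  pO <- element_params("O", "AM1")
  pH <- element_params("H", "AM1")
  for (r in c(1.5, 2.5, 4.0, 8.0)) {
    G <- eri_block(pC, pO, c(0, 0, r))
    expect_equal(G, r_eri_local(pC, pO, r), tolerance = 1e-9)
  }
  # hydrogen pair: single monopole channel
  G <- eri_block(pH, pH, c(0, 0, 2))
  expect_equal(G[1, 1] / 27.21,
               klopman_pair_term(1, 1, 2, pH$rho0, pH$rho0),
               tolerance = 1e-12)
  expect_true(all(G[-1, ] == 0) && all(G[, -1] == 0))
})

test_that("eri blocks are rotationally invariant", {
  set.seed(7)
  pC <- element_params("C", "AM1")
  pO <- element_params("O", "AM1")
  for (k in 1:5) {
    Q <- random_rotation()
    dr <- runif(3, -3, 3)
    G1 <- eri_block(pC, pO, dr)
    G2 <- eri_block(pC, pO, as.vector(Q %*% dr))
    K <- pair_transform(Q)
    expect_lt(max(abs(K %*% G1 %*% t(K) - G2)), 1e-10)
  }
})

test_that("monopole channel beyond the cutoff equals the damped gamma", {
  pC <- element_params("C", "AM1")
  pO <- element_params("O", "AM1")
  for (r in c(12, 20, 25)) {
    expect_equal(eri_block(pC, pO, c(0, 0, r), screen = FALSE)[1, 1] / 27.21,
                 gamma_damped(r, pC$gmono, pO$gmono), tolerance = 1e-13)
  }
})

test_that("monopole two-electron integrals are positive, blocks symmetric", {
  set.seed(9)
  pC <- element_params("C", "AM1")
  pS <- element_params("S", "AM1")
  for (k in 1:10) {
    dr <- runif(3, -4, 4)
    G <- eri_block(pC, pS, dr)
    Gt <- eri_block(pS, pC, -dr)
    expect_gt(G[1, 1], 0)
    expect_gt(G[5, 5], 0)   # (xx|xx) channel carries the monopole
    expect_equal(G, t(Gt), tolerance = 1e-11)
  }
})

test_that("neutral-atom potential decays faster than 1/r^2 beyond the cutoff", {
  # core monopole against the summed valence channels: the monopole parts
  # cancel exactly (identical damped kernel); what survives is the
  # quadrupole remnant, which must fall off at least as 1/r^3
  pC <- element_params("C", "AM1")
  v <- vapply(c(12, 24, 48), function(r) {
    G <- eri_block(pC, pC, c(0, 0, r), screen = FALSE)
    pC$zv * G[1, 1] - (G[1, 1] + G[1, 5] + G[1, 8] + G[1, 10])
  }, numeric(1))
  expect_lt(abs(v[1]), 5e-2)                 # already tiny, eV scale
  expect_lt(abs(v[2]), abs(v[1]) / 4)        # faster than 1/r^2
  expect_lt(abs(v[3]), abs(v[2]) / 4)
})

test_that("exact Slater overlaps match the closed 1s-1s form and decay", {
  r <- 1.4
  pH <- element_params("H", "AM1")
  z <- pH$zs
  rho <- z * r
  closed <- exp(-rho) * (1 + rho + rho^2 / 3)
  S <- overlap_resonance(pH, pH, c(0, 0, r))$S
  expect_equal(S[1, 1], closed, tolerance = 2e-3)  # well within contract
  expect_equal(S[1, 1], closed, tolerance = 1e-10) # analytic, hence exact
  # unit-exponent reference value
  expect_equal(cycluster:::sto_overlap_cpp(1, 0, 1, 0, 1, 1, 1.4, 0),
               exp(-1.4) * (1 + 1.4 + 1.4^2 / 3), tolerance = 1e-12)
  # decay floor
  pC <- element_params("C", "AM1")
  S2 <- overlap_resonance(pC, pC, c(0, 0, 25))$S
  expect_true(all(S2 == 0))
})

test_that("co-centered Slater basis overlaps are orthonormal", {
  expect_equal(cycluster:::sto_overlap_cpp(2, 0, 2, 0, 1.808665, 1.808665,
                                           0, 0), 1, tolerance = 1e-12)
  expect_equal(cycluster:::sto_overlap_cpp(2, 0, 2, 1, 1.808665, 1.685116,
                                           0, 0), 0, tolerance = 1e-12)
})

test_that("core repulsion is symmetric and Coulombic at long range", {
  pC <- element_params("C", "AM1")
  pH <- element_params("H", "AM1")
  pO <- element_params("O", "AM1")
  e <- core_core_energy(pC, pO, 100, screen = FALSE)
  expect_equal(e / (27.21 * 4 * 6 / 100), 1, tolerance = 1e-9)
  for (r in c(2, 3.5, 6)) {
    expect_equal(core_core_energy(pC, pO, r),
                 core_core_energy(pO, pC, r), tolerance = 1e-12)
    expect_equal(core_core_energy(pH, pO, r),
                 core_core_energy(pO, pH, r), tolerance = 1e-12)
  }
})
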
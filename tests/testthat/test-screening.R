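test_that("effective distance honors the three-zone boundary conditions", {
  a <- 15
  expect_identical(effective_distance(15, a), 15)
  expect_identical(effective_distance(30, a), 22.5)
  expect_equal(effective_distance(22.5, a), -7.5 + 45 - 22.5^2 / 30)
  expect_identical(effective_distance(100, a), 1.5 * a)
  # continuity and monotonicity
  r <- seq(0, 40, by = 0.01)
  v <- effective_distance(r, a)
  expect_true(all(diff(v) >= -1e-12))
  expect_lt(max(abs(diff(v))), 0.021)   # no jumps on a 0.01 grid
})

test_that("effective distance is C1 at alpha and flat approaching 2 alpha", {
  a <- 15; h <- 1e-6
  slope_in <- (effective_distance(a + h, a) - effective_distance(a - h, a)) /
    (2 * h)
  expect_equal(slope_in, 1, tolerance = 1e-5)
  slope_out <- (effective_distance(2 * a - h, a) -
                  effective_distance(2 * a - 3 * h, a)) / (2 * h)
  expect_equal(slope_out, 0, tolerance = 1e-4)
})

test_that("multipole contraction equals the derivative of the relocation", {
  a <- 15
  expect_identical(multipole_contraction(15, a), 1)
  expect_identical(multipole_contraction(30, a), 0)
  expect_equal(multipole_contraction(22.5, a), 0.5)
  for (r in seq(15.5, 29.5, by = 0.7)) {
    h <- 1e-5
    num <- (effective_distance(r + h, a) - effective_distance(r - h, a)) /
      (2 * h)
    expect_lt(abs(multipole_contraction(r, a) - num), 1e-8)
  }
})

test_that("multipole charge sets have the canonical structure", {
  mono <- multipole_charge_set(0, rho = 0.9)
  expect_identical(length(mono$q), 1L)
  expect_true(all(mono$offsets == 0))
  dip <- multipole_charge_set(1, d = 0.8, axis = c(0, 0, 1))
  expect_identical(length(dip$q), 2L)
  expect_equal(sum(dip$q), 0)
  expect_equal(sqrt(rowSums(dip$offsets^2)), c(0.8, 0.8))
  qd <- multipole_charge_set(2, d = 0.7,
                             axis = rbind(c(1, 0, 0), c(0, 1, 0)))
  expect_identical(length(qd$q), 4L)
  expect_equal(sum(qd$q), 0)
  expect_equal(colSums(qd$q * qd$offsets), c(0, 0, 0))  # no net dipole
  expect_error(multipole_charge_set(3), "order")
})

test_that("screen_pair conserves charge and collapses distant multipoles", {
  dip <- multipole_charge_set(1, d = 0.8, rho = 0.5, axis = c(1, 0, 0))
  qd <- multipole_charge_set(2, d = 0.7, rho = 0.4,
                             axis = rbind(c(1, 0, 0), c(0, 1, 0)))
  below <- screen_pair(dip, qd, 10, 15)
  expect_identical(below$r_eff, 10)
  expect_equal(below$set_a$offsets, dip$offsets)
  far <- screen_pair(dip, qd, 40, 15)
  expect_equal(sum(far$set_a$q), sum(dip$q))
  expect_true(all(far$set_a$offsets == 0))
  pt <- multipole_charge_set(0)
  e <- charge_set_interaction(far$set_a,
                              screen_pair(pt, dip, 40, 15)$set_b,
                              c(0, 0, far$r_eff), bare = TRUE)
  expect_equal(e, 0, tolerance = 1e-14)
})

test_that("contracted multipoles track the exact per-charge relocation", {
  # point charge vs dipole: the scaled error never exceeds the unscaled one
  alpha <- 15
  pt <- multipole_charge_set(0)
  dip <- multipole_charge_set(1, d = 0.5, axis = c(0, 0, 1))
  for (r in seq(alpha + 1e-3, 2 * alpha, length.out = 40)) {
    e_exact <- sum(vapply(seq_along(dip$q), function(i) {
      ri <- sqrt(sum((c(0, 0, r) + dip$offsets[i, ])^2))
      dip$q[i] / effective_distance(ri, alpha)
    }, numeric(1)))
    sc <- screen_pair(pt, dip, r, alpha)
    e_scaled <- charge_set_interaction(sc$set_a, sc$set_b,
                                       c(0, 0, sc$r_eff), bare = TRUE)
    e_unscaled <- charge_set_interaction(pt, dip,
                                         c(0, 0, effective_distance(r, alpha)),
                                         bare = TRUE)
    expect_lte(abs(e_scaled - e_exact), abs(e_unscaled - e_exact) + 1e-15)
  }
  # at the inner boundary the scaled and center-only schemes coincide
  sc <- screen_pair(pt, dip, alpha, alpha)
  e_scaled <- charge_set_interaction(sc$set_a, sc$set_b, c(0, 0, sc$r_eff),
                                     bare = TRUE)
  e_unscaled <- charge_set_interaction(pt, dip,
                                       c(0, 0, effective_distance(alpha,
                                                                  alpha)),
                                       bare = TRUE)
  expect_equal(e_scaled, e_unscaled, tolerance = 1e-13)
})

test_that("screened lattice sums are independent of the enumeration radius", {
  # neutral arrangement of +/-1 charges on a cubic lattice: enlarging the
  # enumeration changes the screened potential by complete neutral cells only
  a <- 6; alpha <- 15
  cl <- cell(c("Na", "Cl"), rbind(c(0, 0, 0), c(a / 2, 0, 0)), diag(a, 3))
  probe <- c(1.3, 0.7, 0.2)
  pot <- function(rmax) {
    tr <- lattice_images_within(cl, rmax, pad = 0)
    v <- 0
    for (i in seq_len(nrow(tr))) {
      for (at in 1:2) {
        pos <- cell_coords(cl)[at, ] + tr[i, ]
        r <- sqrt(sum((pos - probe)^2))
        q <- c(1, -1)[at]
        v <- v + q / effective_distance(r, alpha)
      }
    }
    v
  }
  base <- pot(2 * alpha + 3 * a)
  expect_lt(abs(pot(2 * alpha + 6 * a) - base), 1e-10)
  expect_lt(abs(pot(2 * alpha + 9 * a) - base), 1e-10)
})
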
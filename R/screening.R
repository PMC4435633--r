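# Three-zone electrostatic screening of distant interactions.
#
# Distant charges are relocated to an effective distance r_eff(r) and the
# point charges of distributed multipoles are contracted toward their center
# by lambda(r) = d r_eff / d r, so that beyond 2*alpha every multipole
# collapses to a point charge at the fixed radius 1.5*alpha and the
# contributions of distant neutral cells cancel by symmetry.

#' Effective distance of a screened interaction
#'
#' Piecewise scaling of the center-to-center distance: identity below
#' `alpha`, the quadratic `-alpha/2 + 2 r - r^2/(2 alpha)` between `alpha`
#' and `2 alpha`, and the constant plateau `1.5 alpha` beyond. The function
#' is continuous, has slope 1 at `alpha` and slope 0 approaching `2 alpha`.
#'
#' @param r distance(s), Angstrom (or any consistent length unit).
#' @param alpha screening parameter in the same unit (the config keyword
#'   `ScreeningR` sets `2*alpha`; default `ScreeningR = 30` A).
#' @return effective distance(s), same unit.
#' @examples
#' effective_distance(c(15, 22.5, 30, 100), alpha = 15)
#' @export
effective_distance <- function(r, alpha) {
  stopifnot(alpha > 0, all(r >= 0))
  ifelse(r < alpha, r,
         ifelse(r <= 2 * alpha,
                -alpha / 2 + 2 * r - r^2 / (2 * alpha),
                1.5 * alpha))
}

#' Multipole contraction factor
#'
#' The factor by which the point-charge offsets of a distributed multipole
#' are shrunk toward its center: 1 below `alpha`, `2 - r/alpha` between
#' `alpha` and `2 alpha`, 0 beyond. On the middle zone it equals the
#' derivative of [effective_distance], which is what makes the contraction
#' consistent with relocating each constituent charge individually to first
#' order in the multipole extent.
#'
#' @inheritParams effective_distance
#' @return dimensionless factor(s) in `[0, 1]`.
#' @export
multipole_contraction <- function(r, alpha) {
  stopifnot(alpha > 0, all(r >= 0))
  ifelse(r < alpha, 1, pmax(0, 2 - r / alpha))
}

#' Apply screening to a pair of multipole charge sets
#'
#' Replaces the center separation by [effective_distance] and multiplies all
#' point-charge offsets of both sets by [multipole_contraction]. Charge
#' magnitudes are untouched, so the total charge of each set is conserved
#' exactly; beyond `2 alpha` every multipole of order >= 1 collapses to
#' coincident charges and a neutral multipole ceases to interact.
#'
#' @param set_a,set_b multipole charge sets as produced by
#'   [multipole_charge_set]: lists with elements `q` (charges, e) and
#'   `offsets` (k x 3 matrix, any consistent length unit).
#' @param r center separation.
#' @param alpha screening parameter, same unit as `r` and the offsets.
#' @return list with `r_eff`, `set_a`, `set_b` (scaled copies).
#' @export
screen_pair <- function(set_a, set_b, r, alpha) {
  lam <- multipole_contraction(r, alpha)
  scale_set <- function(s) {
    s$offsets <- s$offsets * lam
    s
  }
  list(r_eff = effective_distance(r, alpha),
       set_a = scale_set(set_a), set_b = scale_set(set_b))
}

#' Construct a distributed-multipole point-charge set
#'
#' The NDDO representation of an orbital-pair charge distribution as a small
#' set of point charges: a monopole (one charge, zero offset), a dipole (two
#' opposite charges at `+/- d1` along an axis) or a square quadrupole (four
#' alternating charges spanning `d2`).
#'
#' @param order multipole order, 0, 1 or 2.
#' @param d charge separation (`d1` for dipoles, `d2` for quadrupoles), any
#'   length unit.
#' @param rho additive Klopman radius associated with the set, same unit.
#' @param axis for `order = 1`: offset axis (length-3 unit vector). For
#'   `order = 2`: a 2 x 3 matrix whose rows span the quadrupole plane.
#' @return a multipole charge set (list with `order`, `q`, `offsets`,
#'   `rho`).
#' @export
multipole_charge_set <- function(order, d = 0, rho = 0,
                                 axis = c(0, 0, 1)) {
  if (order == 0) {
    list(order = 0L, q = 1, offsets = matrix(0, 1, 3), rho = rho)
  } else if (order == 1) {
    ax <- axis / sqrt(sum(axis^2))
    list(order = 1L, q = c(0.5, -0.5),
         offsets = rbind(d * ax, -d * ax), rho = rho)
  } else if (order == 2) {
    stopifnot(is.matrix(axis), nrow(axis) == 2L)
    e1 <- axis[1, ] / sqrt(sum(axis[1, ]^2))
    e2 <- axis[2, ] / sqrt(sum(axis[2, ]^2))
    list(order = 2L, q = c(0.25, 0.25, -0.25, -0.25),
         offsets = rbind(d * (e1 + e2), -d * (e1 + e2),
                         d * (e1 - e2), -d * (e1 - e2)) / 1,
         rho = rho)
  } else {
    stop("multipole order must be 0, 1 or 2", call. = FALSE)
  }
}

#' Electrostatic interaction energy of two point-charge sets
#'
#' Klopman-smoothed (or bare Coulomb when `bare = TRUE`) interaction of two
#' multipole charge sets with centers separated by `r_vec`. Used for the
#' screening error analysis; the production integral path lives in compiled
#' code.
#'
#' @param set_a,set_b multipole charge sets ([multipole_charge_set]).
#' @param r_vec center-to-center displacement vector.
#' @param bare ignore the additive radii?
#' @return interaction energy (atomic units when inputs are in bohr).
#' @export
charge_set_interaction <- function(set_a, set_b, r_vec, bare = FALSE) {
  e <- 0
  for (i in seq_along(set_a$q)) {
    for (j in seq_along(set_b$q)) {
      dvec <- r_vec + set_b$offsets[j, ] - set_a$offsets[i, ]
      d2 <- sum(dvec^2)
      rho_sum <- if (bare) 0 else (set_a$rho + set_b$rho)
      e <- e + set_a$q[i] * set_b$q[j] / sqrt(d2 + rho_sum^2)
    }
  }
  e
}
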
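# Shared helpers: small geometries and independent (pure-R) re-evaluation
# routes used as oracles for the compiled integral code.

pair_index_map <- function() {
  list(PI = c(1, 1, 1, 1, 2, 2, 2, 3, 3, 4),
       PJ = c(1, 2, 3, 4, 2, 3, 4, 3, 4, 4))
}

# Independent pure-R evaluation of a two-center ERI block (no screening,
# below the damping cutoff): distributed point-charge configurations plus
# Klopman kernels, evaluated in the local frame with dr along +z.
r_eri_local <- function(pa, pb, r) {
  cfgs <- function(p, idx) {
    d1 <- p$d1; d2 <- p$d2
    mono <- list(q = 1, o = matrix(0, 1, 3), rho = p$rho0)
    lin <- function(k) {
      o <- matrix(0, 3, 3); o[1, k] <- 2 * d2; o[2, k] <- -2 * d2
      list(q = c(0.25, 0.25, -0.5), o = o, rho = p$rho2)
    }
    sq <- function(k, l) {
      o <- matrix(0, 4, 3)
      o[1, c(k, l)] <- d2; o[2, c(k, l)] <- -d2
      o[3, k] <- d2; o[3, l] <- -d2; o[4, k] <- -d2; o[4, l] <- d2
      list(q = c(0.25, 0.25, -0.25, -0.25), o = o, rho = p$rho2)
    }
    dipole <- function(k) {
      o <- matrix(0, 2, 3); o[1, k] <- d1; o[2, k] <- -d1
      list(q = c(0.5, -0.5), o = o, rho = p$rho1)
    }
    switch(idx,
           list(mono),                 # ss
           list(dipole(1)),            # s px
           list(dipole(2)),            # s py
           list(dipole(3)),            # s pz
           list(mono, lin(1)),         # xx
           list(sq(1, 2)),             # xy
           list(sq(1, 3)),             # xz
           list(mono, lin(2)),         # yy
           list(sq(2, 3)),             # yz
           list(mono, lin(3)))         # zz
  }
  G <- matrix(0, 10, 10)
  for (ip in 1:10) for (jp in 1:10) {
    v <- 0
    for (ca in cfgs(pa, ip)) for (cb in cfgs(pb, jp)) {
      for (i in seq_along(ca$q)) for (j in seq_along(cb$q)) {
        dv <- c(0, 0, r) + cb$o[j, ] - ca$o[i, ]
        v <- v + klopman_pair_term(ca$q[i], cb$q[j], sqrt(sum(dv^2)),
                                   ca$rho, cb$rho)
      }
    }
    G[ip, jp] <- v
  }
  G[6, 6] <- 0.5 * (G[5, 5] - G[5, 8])   # axial gauge identity
  G * 27.21
}

# Full molecular two-electron energy by explicit supermatrix resummation
# (independent of the Fock path): 0.5 sum P P [(uv|ls) - 0.5 (ul|vs)].
r_two_electron_energy <- function(state) {
  cellx <- state$cell
  stopifnot(cellx$pdim == 0L)
  els <- cellx$atoms$element
  xyz <- cell_coords(cellx) / 0.529167
  nb <- ifelse(toupper(els) == "H", 1L, 4L)
  off <- state$offsets
  n <- sum(nb)
  idx <- pair_index_map()
  ERI <- array(0, c(n, n, n, n))
  for (a in seq_along(els)) {
    pp <- element_params(els[a], state$hamiltonian)
    o <- off[a]
    if (nb[a] == 1L) {
      ERI[o + 1, o + 1, o + 1, o + 1] <- pp$gss
    } else {
      for (m in 1:4) for (l in 1:4) {
        v <- if (m == 1 && l == 1) pp$gss
             else if (m == 1 || l == 1) pp$gsp
             else if (m == l) pp$gpp else pp$gp2
        ERI[o + m, o + m, o + l, o + l] <- v
      }
      hpp <- 0.5 * (pp$gpp - pp$gp2)
      for (k in 2:4) {
        for (perm in list(c(1, k, 1, k), c(k, 1, 1, k),
                          c(1, k, k, 1), c(k, 1, k, 1))) {
          ERI[o + perm[1], o + perm[2], o + perm[3], o + perm[4]] <- pp$hsp
        }
      }
      for (k in 2:4) for (l in 2:4) if (k != l) {
        ERI[o + k, o + l, o + k, o + l] <- hpp
        ERI[o + k, o + l, o + l, o + k] <- hpp
      }
    }
  }
  na <- length(els)
  for (a in seq_len(na - 1)) for (b in (a + 1):na) {
    pa <- element_params(els[a], state$hamiltonian)
    pb <- element_params(els[b], state$hamiltonian)
    G <- eri_block(pa, pb, xyz[b, ] - xyz[a, ])
    for (ip in 1:10) for (jp in 1:10) {
      m <- idx$PI[ip]; nu <- idx$PJ[ip]; l <- idx$PI[jp]; s <- idx$PJ[jp]
      if (m > nb[a] || nu > nb[a] || l > nb[b] || s > nb[b]) next
      oa <- off[a]; ob <- off[b]
      for (mm in list(c(m, nu), c(nu, m))) for (ll in list(c(l, s),
                                                           c(s, l))) {
        ERI[oa + mm[1], oa + mm[2], ob + ll[1], ob + ll[2]] <- G[ip, jp]
        ERI[ob + ll[1], ob + ll[2], oa + mm[1], oa + mm[2]] <- G[ip, jp]
      }
    }
  }
  p <- state$p
  e2 <- 0
  for (m in 1:n) for (nu in 1:n) for (l in 1:n) for (s in 1:n) {
    e2 <- e2 + 0.5 * p[m, nu] * p[l, s] *
      (ERI[m, nu, l, s] - 0.5 * ERI[m, l, nu, s])
  }
  e2
}

random_rotation <- function() {
  ang <- runif(3, 0, 2 * pi)
  Rz <- function(t) matrix(c(cos(t), -sin(t), 0, sin(t), cos(t), 0,
                             0, 0, 1), 3, 3, byrow = TRUE)
  Rx <- function(t) matrix(c(1, 0, 0, 0, cos(t), -sin(t),
                             0, sin(t), cos(t)), 3, 3, byrow = TRUE)
  Rz(ang[1]) %*% Rx(ang[2]) %*% Rz(ang[3])
}

pair_transform <- function(Q) {
  U <- matrix(0, 4, 4); U[1, 1] <- 1; U[2:4, 2:4] <- Q
  idx <- pair_index_map()
  K <- matrix(0, 10, 10)
  for (gp in 1:10) for (lp in 1:10) {
    m <- idx$PI[gp]; n <- idx$PJ[gp]; cc <- idx$PI[lp]; e <- idx$PJ[lp]
    v <- U[m, cc] * U[n, e]
    if (cc != e) v <- v + U[m, e] * U[n, cc]
    K[gp, lp] <- v
  }
  K
}
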
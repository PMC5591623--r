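# Shared fixtures and independent oracles for the test suite.

rabbit_annulus <- function() fixture("rabbit_omega_r")
rabbit_sector <- function() fixture("rabbit_omega0")

nh_layer <- function(c0 = 1)
  hgo_layer(c = c0, k1 = 0, k2 = 1, beta = 0)

nh_materials <- function(c_m = 1, c_a = c_m)
  wall_materials(nh_layer(c_m), nh_layer(c_a))

# Full 3x3 tensor oracle: build F, B and the push-forward structure
# tensors of both fibre families explicitly and assemble the Cauchy
# stress, fixing the Lagrange multiplier from a prescribed radial
# stress.  Fibre directions follow the plane-strain convention (axial
# component dropped, not renormalised).
tensor_stress_oracle <- function(lam_r, lam_t, lam_z, layer,
                                 s_rr = 0) {
  F <- diag(c(lam_r, lam_t, lam_z))
  B <- F %*% t(F)
  b <- layer$beta * pi / 180
  fib <- matrix(0, 3, 3)
  for (A in list(c(0, cos(b), 0), c(0, cos(b), 0))) {
    M <- A %o% A
    I4 <- sum((t(F) %*% F) * M)
    wp <- if (I4 > 1) layer$k1 * (I4 - 1) * exp(layer$k2 * (I4 - 1)^2)
          else 0
    fib <- fib + 2 * wp * (F %*% M %*% t(F))
  }
  sig0 <- 2 * layer$c * B + fib
  p <- sig0[1, 1] - s_rr
  sig0 - p * diag(3)
}

# Seeded random incompressible plane-strain deformation states.
random_points <- function(n, seed) {
  set.seed(seed)
  lam_t <- exp(runif(n, log(0.6), log(1.6)))
  deformation_point(lam_r = 1 / lam_t, lam_t = lam_t, lam_z = 1)
}

# Runge-Kutta shooting oracle for the radial equilibrium ODE
# d(s_rr)/dr = (s_tt - s_rr)/r across both layers of a closing
# deformation parameterised by (sector, r_i candidate).  Independent
# of the package's quadrature path.
shoot_srr <- function(sector, r_i, materials, n_steps = 4000) {
  k <- 2 * pi / (2 * pi - sector$alpha * pi / 180)
  r_m <- sqrt((sector$R_m^2 - sector$R_i^2) / k + r_i^2)
  r_o <- sqrt((sector$R_o^2 - sector$R_i^2) / k + r_i^2)
  rhs <- function(r, y, parms) {
    layer <- if (r <= r_m) materials$media else materials$adventitia
    R <- sqrt(k * (r^2 - r_i^2) + sector$R_i^2)
    lt <- k * r / R
    pt <- deformation_point(1 / lt, lt, 1)
    list(stress_difference(pt, layer) / r)
  }
  grid1 <- seq(r_i, r_m, length.out = n_steps / 2)
  grid2 <- seq(r_m, r_o, length.out = n_steps / 2)
  o1 <- deSolve::ode(c(s = 0), grid1, rhs, NULL, method = "rk4")
  o2 <- deSolve::ode(c(s = unname(o1[nrow(o1), "s"])), grid2, rhs,
                     NULL, method = "rk4")
  list(r = c(grid1, grid2), s_rr = c(o1[, "s"], o2[, "s"]),
       end = o2[nrow(o2), "s"])
}
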
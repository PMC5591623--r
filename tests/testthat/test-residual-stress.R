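test_that("wall residual vanishes for the undeformed configuration", {
  mats <- nh_materials()
  sec0 <- open_sector(1, 1.2, 1.3, 0)
  expect_equal(wall_residual(sec0, r_i_candidate = 1, mats), 0,
               tolerance = 1e-14)
  expect_error(wall_residual(sec0, -1, mats), "degenerate")
})

test_that("integral-equation root agrees with an ODE shooting oracle", {
  # single-material neo-Hookean ring: c identical in both layers makes
  # the wall effectively one layer
  mats <- nh_materials(1, 1)
  sec <- open_sector(1, 1.1, 1.2, 90)

  sol <- solve_unloaded(sec, mats, n_nodes = 101)
  # oracle: Runge-Kutta integration of the equilibrium ODE, root of
  # the end-point radial stress over the candidate inner radius
  oracle_root <- uniroot(function(ri) shoot_srr(sec, ri, mats)$end,
                         c(0.5, 1.2), tol = 1e-12)$root
  expect_equal(sol$annulus$r_i, oracle_root, tolerance = 1e-8)

  # profile agrees pointwise with the shooting oracle
  sh <- shoot_srr(sec, sol$annulus$r_i, mats)
  sh_at <- approx(sh$r, sh$s_rr, xout = sol$state$r_mm,
                  ties = "ordered")$y
  expect_lt(max(abs(sol$state$sigma_rr_kPa - sh_at)), 1e-8)
})

test_that("closing the rabbit sector yields a traction-free annulus", {
  fx <- rabbit_sector()
  sol <- solve_unloaded(fx$sector, fx$materials)
  st <- sol$state
  c_m <- fx$materials$media$c

  # traction-free surfaces
  expect_lt(abs(st$sigma_rr_kPa[1]), 1e-8 * c_m)
  expect_lt(abs(st$sigma_rr_kPa[nrow(st)]), 1e-8 * c_m)
  expect_lt(abs(sol$info$residual), 1e-10 * c_m)
  # quadrature refinement agrees
  expect_lt(abs(sol$info$residual_refined - sol$info$residual),
            1e-10 * c_m)

  # 401 unique radii, interface duplicated
  expect_equal(nrow(st), 402)
  expect_equal(sum(st$layer == "media") + sum(st$layer == "adventitia"),
               402)
  i_med <- max(which(st$layer == "media"))
  expect_equal(st$r_mm[i_med], st$r_mm[i_med + 1])
  # radial stress continuous across the interface, hoop stress jumps
  expect_lt(abs(st$sigma_rr_kPa[i_med] - st$sigma_rr_kPa[i_med + 1]),
            1e-12)
  expect_gt(abs(st$sigma_tt_kPa[i_med] - st$sigma_tt_kPa[i_med + 1]),
            0.01)

  # compression at the media inner surface, tension at the adventitia
  # outer surface
  expect_lt(st$sigma_tt_kPa[1], 0)
  expect_gt(st$sigma_tt_kPa[nrow(st)], 0)

  # finite-difference equilibrium residual within each layer
  for (l in c("media", "adventitia")) {
    s <- st[st$layer == l, ]
    n <- nrow(s)
    i <- 2:(n - 1)
    lhs <- (s$sigma_rr_kPa[i + 1] - s$sigma_rr_kPa[i - 1]) /
      (s$r_mm[i + 1] - s$r_mm[i - 1])
    rhs <- (s$sigma_tt_kPa[i] - s$sigma_rr_kPa[i]) / s$r_mm[i]
    expect_lt(max(abs(lhs - rhs)), 1e-4)
  }
})

test_that("zero opening angle produces a stress-free closed state", {
  mats <- nh_materials(2, 0.5)
  sec0 <- open_sector(0.8, 1.0, 1.1, 0)
  sol <- solve_unloaded(sec0, mats, n_nodes = 51)
  expect_equal(sol$annulus$r_i, 0.8, tolerance = 1e-10)
  expect_equal(sol$annulus$r_o, 1.1, tolerance = 1e-10)
  expect_lt(max(abs(sol$state$sigma_rr_kPa)), 1e-12)
  expect_lt(max(abs(sol$state$sigma_tt_kPa)), 1e-12)

  inv <- solve_stress_free(closed_annulus(0.8, 1.0, 1.1), 0, mats,
                           n_nodes = 51)
  expect_equal(inv$sector$R_i, 0.8)
  expect_lt(max(abs(inv$state$sigma_tt_kPa)), 1e-12)
})

test_that("forward and inverse solves are mutual inverses", {
  fx <- rabbit_sector()
  fwd <- solve_unloaded(fx$sector, fx$materials, n_nodes = 51)
  back <- solve_stress_free(fwd$annulus, fx$sector$alpha, fx$materials,
                            n_nodes = 51)
  expect_lt(abs(back$sector$R_i - fx$sector$R_i), 1e-6)
  expect_lt(abs(back$sector$R_m - fx$sector$R_m), 1e-6)
  expect_lt(abs(back$sector$R_o - fx$sector$R_o), 1e-6)

  # and over seeded random parameter sets
  for (s in 1:25) {
    d <- draw_parameter_set(s)
    fwd <- solve_unloaded(d$sector, d$materials, n_nodes = 31)
    back <- solve_stress_free(fwd$annulus, d$alpha, d$materials,
                              n_nodes = 31)
    expect_lt(abs(back$sector$R_i - d$sector$R_i), 1e-6)
    expect_lt(abs(back$sector$R_o - d$sector$R_o), 1e-6)
  }
})

test_that("hoop-stress severity grows with the opening angle", {
  fx <- rabbit_annulus()
  peak <- vapply(c(0, 40, 80, 120, 160, 200), function(a) {
    inv <- solve_stress_free(fx$annulus, a, fx$materials,
                             n_nodes = 201)
    max(abs(inv$state$sigma_tt_kPa))
  }, numeric(1))
  expect_true(all(diff(peak) >= 0))
})

test_that("open-sector thickness trends hold across fibre angles", {
  fx <- rabbit_annulus()
  t_a0 <- fx$annulus$r_o - fx$annulus$r_m
  alphas <- c(40, 120, 200)
  free <- wall_materials(
    hgo_layer(1.5, 0, 1, 0), hgo_layer(0.15, 0, 1, 0))
  Ri_free <- vapply(alphas, function(a)
    solve_stress_free(fx$annulus, a, free, n_nodes = 31)$sector$R_i,
    numeric(1))
  for (beta in c(0, 20, 60, 90)) {
    mats <- wall_materials(
      hgo_layer(1.5, 2.3632, 0.8393, beta),
      hgo_layer(0.15, 0.5620, 0.7112, beta))
    Ta_norm <- vapply(alphas, function(a) {
      s <- solve_stress_free(fx$annulus, a, mats, n_nodes = 31)$sector
      (s$R_o - s$R_m) / t_a0
    }, numeric(1))
    # normalized adventitia thickness increases with opening angle
    expect_true(all(diff(Ta_norm) > 0))
    if (beta == 90) {
      # circumferentially-blind fibres reproduce the fibre-free wall
      Ri <- vapply(alphas, function(a)
        solve_stress_free(fx$annulus, a, mats,
                          n_nodes = 31)$sector$R_i, numeric(1))
      expect_equal(Ri, Ri_free, tolerance = 1e-12)
    }
  }
})

test_that("relative profile error behaves as a scaled L2 norm", {
  fx <- rabbit_annulus()
  inv <- solve_stress_free(fx$annulus, 160, fx$materials,
                           n_nodes = 101)
  st <- inv$state
  expect_equal(relative_error_profiles(st, st), 0)

  scaled <- st
  scaled$sigma_rr_kPa <- 1.01 * st$sigma_rr_kPa
  scaled$sigma_tt_kPa <- 1.01 * st$sigma_tt_kPa
  expect_equal(relative_error_profiles(scaled, st), 0.01,
               tolerance = 1e-12)

  # hand-computed norm ratio with a perturbation in one component
  pert <- st
  pert$sigma_tt_kPa <- st$sigma_tt_kPa + 0.05
  want <- sqrt(sum((pert$sigma_tt_kPa - st$sigma_tt_kPa)^2)) /
    sqrt(sum(st$sigma_tt_kPa^2))
  expect_equal(relative_error_profiles(pert, st), want,
               tolerance = 1e-12)

  zero <- st
  zero$sigma_rr_kPa <- zero$sigma_tt_kPa <- rep(0, nrow(st))
  expect_error(relative_error_profiles(st, zero), "zero norm")
})

test_that("opening angle is recoverable from its stress profile", {
  fx <- rabbit_annulus()
  inv <- solve_stress_free(fx$annulus, 160, fx$materials,
                           n_nodes = 101)
  rec <- recover_opening_angle(inv$state, fx$annulus, fx$materials)
  expect_lt(abs(rec$alpha - 160), 0.5)
  expect_false(rec$multimodal)

  # the all-zero profile identifies the unopened state
  zero <- inv$state
  zero$sigma_rr_kPa <- zero$sigma_tt_kPa <- zero$sigma_zz_kPa <-
    rep(0, nrow(zero))
  expect_equal(recover_opening_angle(zero, fx$annulus,
                                     fx$materials)$alpha, 0)

  # 1% multiplicative noise moves the estimate by well under 2 degrees
  inv120 <- solve_stress_free(fx$annulus, 120, fx$materials,
                              n_nodes = 101)
  errs <- vapply(1:10, function(s) {
    np <- noisy_profile(inv120$state, 0.01, seed = s)
    recover_opening_angle(np, fx$annulus, fx$materials)$alpha - 120
  }, numeric(1))
  expect_lt(mean(abs(errs)), 2)
})

test_that("inconsistent configuration pairs are rejected", {
  fx <- rabbit_sector()
  sol <- solve_unloaded(fx$sector, fx$materials, n_nodes = 51)
  wrong <- closed_annulus(sol$annulus$r_i * 1.05,
                          sol$annulus$r_m * 1.05,
                          sol$annulus$r_o * 1.05)
  expect_error(
    residual_stress_profile(fx$sector, wrong, fx$materials, 51),
    "inconsistent")
})
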
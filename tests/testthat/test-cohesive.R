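test_that("two parameters determine the triangular law", {
  # published rabbit values: the triangle area reproduces the printed
  # separation energies (kPa mm -> N/mm conversion)
  med <- cohesive_law(T_c = 3, du_c = 0.667)
  expect_equal(med$G_c, 0.0010005, tolerance = 1e-12)
  adv <- cohesive_law(T_c = 0.3, du_c = 0.667)
  expect_equal(adv$G_c, 0.00010005, tolerance = 1e-12)

  expect_equal(cohesive_law(T_c = 2, G_c = 0.001)$du_c, 1)

  # involutive: recomputing any held-out parameter returns the input
  full <- cohesive_law(T_c = 3, du_c = 0.667)
  expect_equal(cohesive_law(T_c = full$T_c, G_c = full$G_c)$du_c,
               full$du_c, tolerance = 1e-12)
  expect_equal(cohesive_law(G_c = full$G_c, du_c = full$du_c)$T_c,
               full$T_c, tolerance = 1e-12)

  expect_error(cohesive_law(T_c = 3), "two of")
  expect_error(cohesive_law(), "two of")
  expect_error(cohesive_law(T_c = 3, G_c = 0.002, du_c = 0.667),
               "inconsistent")
  # consistent triple is accepted
  expect_silent(cohesive_law(T_c = 3, G_c = 0.0010005, du_c = 0.667))
})

test_that("traction follows the envelope and secant unloading", {
  law <- cohesive_law(T_c = 3, du_c = 0.667)

  virgin <- cohesive_traction(0, law)
  expect_equal(virgin$traction, 3)  # initially rigid intercept

  expect_equal(cohesive_traction(law$du_c, law)$traction, 0)
  expect_equal(cohesive_traction(2 * law$du_c, law)$traction, 0)

  # load to du_c/2, then unload to du_c/4: secant stiffness gives T_c/4
  s1 <- cohesive_traction(law$du_c / 2, law)
  expect_equal(s1$traction, law$T_c / 2)
  s2 <- cohesive_traction(law$du_c / 4, law, s1$state)
  expect_equal(s2$traction, law$T_c / 4)
  # state not degraded by unloading
  expect_equal(s2$state$du_max_seen, law$du_c / 2)

  expect_error(cohesive_traction(-0.1, law), "non-negative")
})

test_that("damage is irreversible and traction continuous", {
  law <- cohesive_law(T_c = 2, du_c = 1)
  set.seed(42)
  for (rep in 1:20) {
    hist <- runif(30, 0, 1.4)
    state <- damage_state()
    dmg_prev <- 0
    t_prev <- NULL
    du_prev <- NULL
    for (du in hist) {
      out <- cohesive_traction(du, law, state)
      state <- out$state
      dmg <- cohesive_damage(state, law)
      expect_gte(dmg, dmg_prev)
      dmg_prev <- dmg
      # continuity: traction change bounded by the steepest slope
      if (!is.null(t_prev)) {
        slope_max <- law$T_c / law$du_c +
          law$T_c / max(state$du_max_seen, 1e-9)
        expect_lte(abs(out$traction - t_prev),
                   slope_max * abs(du - du_prev) + 1e-12)
      }
      t_prev <- out$traction
      du_prev <- du
    }
    expect_lte(dmg_prev, 1)
  }
})

test_that("dissipated energy integrates the traction path", {
  law <- cohesive_law(T_c = 3, du_c = 0.667)

  expect_equal(dissipated_energy(numeric(0), law), 0)
  # monotone loading to full separation releases exactly G_c
  expect_equal(dissipated_energy(c(law$du_c), law), law$G_c,
               tolerance = 1e-12)
  expect_equal(dissipated_energy(seq(0.1, 1, by = 0.1) * law$du_c,
                                 law), law$G_c, tolerance = 1e-12)

  # load to du_c/2 then unload to 0: envelope work 3/8 T_c du_c minus
  # secant recovery 1/8 T_c du_c leaves T_c du_c / 4 = G_c / 2
  expect_equal(dissipated_energy(c(law$du_c / 2, 0), law),
               law$G_c / 2, tolerance = 1e-12)

  # reload along the secant re-stores the elastic part: the path
  # integral ends loaded, carrying 1/8 T_c du_c of recoverable energy
  expect_equal(
    dissipated_energy(c(law$du_c / 2, 0, law$du_c / 2), law),
    0.75 * law$G_c, tolerance = 1e-12)

  # no admissible history dissipates more than G_c; equality requires
  # reaching full separation
  set.seed(9)
  for (rep in 1:25) {
    hist <- runif(12, 0, 1.5 * law$du_c)
    e <- dissipated_energy(hist, law)
    expect_lte(e, law$G_c + 1e-12)
    if (max(hist) >= law$du_c)
      expect_equal(e, law$G_c, tolerance = 1e-12)
    else
      expect_lt(e, law$G_c)
  }
})

test_that("initiation and propagation criteria read the stress state", {
  law <- cohesive_law(T_c = 3, du_c = 0.667)

  chk <- initiation_check(c(0, 0, 0), law)
  expect_false(chk$initiated)
  expect_equal(chk$margin, -3)

  # the criterion boundary is inclusive
  expect_true(initiation_check(c(0, 3, 0), law)$initiated)

  chk <- initiation_check(c(-1, 2, 0.5), 1)
  expect_true(chk$initiated)
  expect_equal(chk$margin, 1)

  expect_identical(propagation_direction(c(0.1, 2)), "radial")
  expect_identical(propagation_direction(c(2, 0.1)), "circumferential")
  expect_identical(propagation_direction(c(-1, -2)), "none")

  # a hoop-dominated wall state propagates radially
  fx <- rabbit_sector()
  st <- cauchy_stress(deformation_point(1 / 1.2, 1.2, 1),
                      fx$materials$media, s_rr_known = 0)
  expect_identical(propagation_direction(st), "radial")
})
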
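test_that("hydraulic resistance follows the Poiseuille form", {
  # 128 * 1e-3 * 4e-3 / (pi * (5e-6)^4), evaluated by hand
  expect_equal(hydraulic_resistance(1e-3, 4e-3, 5e-6), 2.607594587e17,
               tolerance = 1e-6)
  R1 <- hydraulic_resistance(1e-3, 4e-3, 5e-6)
  expect_equal(hydraulic_resistance(1e-3, 4e-3, 1e-5) / R1, 1 / 16)
  expect_equal(hydraulic_resistance(2e-3, 4e-3, 5e-6) / R1, 2)
  expect_error(hydraulic_resistance(0, 4e-3, 5e-6), "> 0")
})

test_that("Starling filtration and ISF velocity match hand arithmetic", {
  p <- default_parameters()
  expect_equal(capillary_filtration(p), 6.5e-10 * 1.5e-8 * 33)
  expect_equal(capillary_filtration(default_parameters(PISF = 30)), 0)
  expect_equal(capillary_filtration(default_parameters(Lpc = 1.3e-9)),
               2 * capillary_filtration(p))
  expect_equal(isf_velocity(3.2175e-16, 2.2e-8), 1.4625e-8)
  expect_equal(isf_velocity(0, 2.2e-8), 0)
  expect_equal(isf_velocity(3.2175e-16, 1.1e-8),
               2 * isf_velocity(3.2175e-16, 2.2e-8))
  expect_error(isf_velocity(1e-16, 0), "> 0")
})

test_that("Darcy gland flow reproduces the passive velocity calibration", {
  p <- default_parameters()
  R <- hydraulic_resistance(p$mu, p$L, p$d)
  deltaP <- p$u_passive * p$Asg * R
  expect_equal(deltaP, 1.533265e3, tolerance = 1e-6)
  gf <- gland_flow(p, deltaP, R)
  expect_equal(gf$u_sg, 3e-4)
  expect_equal(gf$u_sg_n, 1)
  z <- gland_flow(p, 0, R)
  expect_identical(c(z$Q_water_sg, z$u_sg, z$u_sg_n), c(0, 0, 0))
  g2 <- gland_flow(default_parameters(u_sweat_n = 2), deltaP, R)
  expect_equal(g2$u_sg, 2 * gf$u_sg)
  expect_equal(g2$u_sg_n, 2 * gf$u_sg_n)
  expect_error(gland_flow(p, 10, 0), "R")
  expect_error(gland_flow(p, -1, R), "deltaP")
})

test_that("plasma-to-ISF flux and wall flux density follow their laws", {
  p <- default_parameters()
  expect_equal(plasma_to_isf_flux(10, 2, p), 1.2e-3 * 8 * 3.02e-13)
  expect_equal(plasma_to_isf_flux(5, 5, p), 0)
  expect_equal(plasma_to_isf_flux(2, 10, p), -plasma_to_isf_flux(10, 2, p))
  expect_equal(wall_flux_density(10, 0, p), 3.01e-10 * 10 / 5e-5)
  expect_equal(wall_flux_density(7, 7, p), 0)
  expect_equal(wall_flux_density(10, 0, default_parameters(hsg = 1e-4)),
               wall_flux_density(10, 0, p) / 2)
})

test_that("dilution correction is the printed hyperbola", {
  expect_equal(dilute_concentration(7, 2.5, 1), 2)
  expect_equal(dilute_concentration(7, 0, 1), 7)          # Kwu = 0: identity
  expect_equal(dilute_concentration(7, 2.5, 1e9), 7, tolerance = 1e-8)
  u <- c(0.5, 1, 2, 4, 8)
  expect_true(all(diff(dilute_concentration(7, 2.5, u)) > 0))  # monotone
  expect_error(dilute_concentration(7, 2.5, 0), "u_sg_n")
})

test_that("pressure balance: fixed calibration and balanced root", {
  p <- default_parameters()
  fx <- solve_pressure_balance(p, "fixed")
  expect_equal(fx$PISF_effective, -3)
  expect_equal(fx$deltaP, 1.533265e3, tolerance = 1e-6)
  bal <- solve_pressure_balance(p, "balanced")
  # defining property: capillary inflow equals gland outflow
  R <- hydraulic_resistance(p$mu, p$L, p$d)
  Q_in <- p$Lpc * p$Ac * (p$Pc - bal$PISF_effective)
  Q_out <- bal$deltaP / R
  expect_lt(abs(Q_in - Q_out) / Q_in, 1e-6)
  expect_gt(bal$PISF_effective, p$PISF)
  expect_lt(bal$PISF_effective, p$Pc)
  # blocked gland (R -> Inf via viscosity): interstitial pressure approaches
  # the capillary pressure and filtration ceases
  blocked <- solve_pressure_balance(default_parameters(mu = 1e6), "balanced")
  expect_equal(blocked$PISF_effective, 30, tolerance = 1e-4)
})

test_that("simulated readout matches the closed-form solution", {
  g <- simulation_grid()
  for (cb in c(0, 3, 6.4, 20)) {
    for (s in c(0, 0.21, 0.36)) {
      for (un in c(1, 2.8)) {
        p <- default_parameters(S = s, u_sweat_n = un)
        expect_equal(simulate_sweat(cb, p, g)$C_sweat,
                     analytic_sweat(cb, p), tolerance = 1e-8)
      }
    }
  }
})

test_that("degenerate and qualitative simulation behaviour", {
  g <- simulation_grid()
  expect_identical(simulate_sweat(0, default_parameters(), g)$C_sweat, 0)
  # purely passive transport plus dilution cannot exceed the blood level
  for (cb in c(0.5, 6.4, 20, 45)) {
    expect_lt(simulate_sweat(cb, default_parameters(), g)$C_sweat, cb)
  }
  # the active term lifts sweat above blood at the physiological operating
  # point (frozen regression value, equal to the closed form)
  sim <- simulate_sweat(6.4, op_params(), simulation_grid())
  expect_gt(sim$C_sweat, 6.4)
  expect_equal(sim$C_sweat, 6.6204855, tolerance = 1e-7)
  expect_true(sim$converged)
  expect_error(simulate_sweat(-1, default_parameters(), g), "C_blood")
  expect_error(simulate_sweat(1, default_parameters(d = -1), g), "invalid")
})

test_that("external dilution of the undiluted exit value is bit-identical", {
  g <- simulation_grid()
  for (cb in c(2, 6.4, 20)) {
    sim <- simulate_sweat(cb, op_params(), g)
    expect_identical(
      dilute_concentration(sim$C_sg_exit, 2.5, sim$flows$u_sg_n),
      sim$C_sweat)
  }
})

test_that("S-mode bookkeeping behaves as documented", {
  g <- simulation_grid()
  # literal mode at high S drains the ISF (positivity-clamped), shutting the
  # passive pathway
  sl <- simulate_sweat(6.4, op_params(), g, s_mode = "literal")
  expect_equal(max(sl$C_ISF_profile$C), 0)
  sb <- simulate_sweat(6.4, op_params(), g)
  expect_lt(sl$C_sweat, sb$C_sweat)
  # literal mode at tiny S keeps the ISF near (Cp - S/k) as printed
  p_small <- default_parameters(S = 1e-4)
  sl2 <- simulate_sweat(6.4, p_small, g, s_mode = "literal")
  k_isf <- p_small$kDE * p_small$Vp / p_small$VISF
  expect_equal(mean(sl2$C_ISF_profile$C), 6.4 - 1e-4 / k_isf,
               tolerance = 1e-6)
  # conservative mode: plasma inflow balances gland outflow
  sc <- simulate_sweat(6.4, default_parameters(S = 5e-4), g,
                       s_mode = "conservative")
  expect_lt(sc$mass_balance_residual, 1e-3)
})

test_that("flow state invariants hold at the defaults", {
  fl <- compute_flows(default_parameters())
  expect_gt(fl$R, 0)
  expect_true(all(c(fl$Q_water, fl$u_ISF, fl$Q_water_sg, fl$u_sg) >= 0))
  expect_equal(fl$u_sg_n, fl$u_sg / 3e-4)
})
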
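test_that("squared error is the symmetric quadratic of the stopping rule", {
  expect_identical(squared_error(7, 7), 0)
  expect_equal(squared_error(7, 6.9), 0.01)
  expect_identical(squared_error(3, 5), squared_error(5, 3))
})

test_that("loop 1 inverts the forward model on its bracket", {
  g <- simulation_grid()
  p <- op_params()
  meas <- simulate_sweat(20, p, g)$C_sweat
  cb <- update_blood_estimate(meas, p, c(0, 60), g)
  expect_lt(abs(cb - 20) / 20, 1e-3)
  expect_false(attr(cb, "at_edge"))
  # degenerate zero measurement with passive parameters
  cb0 <- update_blood_estimate(0, default_parameters(), c(0, 60), g)
  expect_identical(as.numeric(cb0), 0)
  # unattainably high measurement returns the upper edge with a warning
  expect_warning(
    cb_hi <- update_blood_estimate(1e4, default_parameters(), c(0, 60), g),
    "above")
  expect_identical(as.numeric(cb_hi), 60)
  expect_true(attr(cb_hi, "at_edge"))
  # a measurement below the active floor returns the lower edge
  expect_warning(
    cb_lo <- update_blood_estimate(0.1, p, c(0, 60), g), "below")
  expect_identical(as.numeric(cb_lo), 0)
  # result always inside the supplied bracket
  for (m in c(1, 5, 12)) {
    v <- suppressWarnings(
      as.numeric(update_blood_estimate(m, p, c(0, 30), g)))
    expect_gte(v, 0)
    expect_lte(v, 30)
  }
})

test_that("loop 2 reduces its objective and recovers a generating S", {
  g <- simulation_grid()
  meas <- simulate_sweat(6.4, default_parameters(S = 0.3), g)$C_sweat
  cfg <- estimation_config(s_anchor = 0.3)
  th0 <- default_parameters()  # S starts at 0
  obj <- function(th) {
    e <- squared_error(meas, simulate_sweat(6.4, th, g)$C_sweat)
    e  # prior part is zero at the anchor, so e bounds the objective there
  }
  th1 <- update_parameters(meas, 6.4, th0, cfg, g)
  expect_gt(th1$S, 0)
  expect_lt(abs(th1$S - 0.3), 0.3)      # moved toward the generating value
  expect_lt(obj(th1), obj(th0))
  # an overwhelming prior pins the parameters at their anchors
  cfg_inf <- estimation_config(s_anchor = 0.36, prior_weight = 1e12)
  th_pinned <- update_parameters(meas, 6.4, default_parameters(S = 0.36),
                                 cfg_inf, g)
  expect_equal(th_pinned$S, 0.36, tolerance = 1e-4)
  expect_equal(th_pinned$Dsw, 1.38e-9, tolerance = 1e-4)
})

test_that("the double loop recovers self-consistent measurements", {
  g <- simulation_grid()
  # initialization equals the truth: first loop-1 pass is already exact
  meas <- simulate_sweat(6.4, op_params(), g)$C_sweat
  est <- estimate_blood_urea(meas)
  expect_equal(est$C_blood_final, 6.4, tolerance = 1e-3)
  expect_true(est$converged)
  expect_lt(utils::tail(est$error_trace, 1), 0.01)
  # pre-dialysis-like sample, anchored at the pre-dialysis S level
  meas2 <- simulate_sweat(20, default_parameters(S = 0.51), g)$C_sweat
  est2 <- estimate_blood_urea(meas2,
                              config = estimation_config(s_anchor = 0.51))
  expect_lt(abs(est2$C_blood_final - 20) / 20, 0.1)
})

test_that("the error trace never increases and runs are deterministic", {
  g <- simulation_grid()
  meas <- simulate_sweat(13, default_parameters(S = 0.4), g)$C_sweat
  est <- estimate_blood_urea(meas, config = estimation_config(s_anchor = 0.4))
  expect_true(all(diff(est$error_trace) <= 0))
  est_b <- estimate_blood_urea(meas,
                               config = estimation_config(s_anchor = 0.4))
  expect_identical(est[c("C_blood_final", "error_trace", "iterations")],
                   est_b[c("C_blood_final", "error_trace", "iterations")])
})

test_that("passive-mode estimation freezes S and overestimates", {
  g <- simulation_grid()
  truth <- 6.4
  meas <- simulate_sweat(truth, op_params(), g)$C_sweat  # sweat > blood
  expect_gt(meas, truth)
  full <- estimate_blood_urea(meas)
  pas <- estimate_blood_urea(meas, mode = "passive")
  expect_identical(pas$theta_final$S, 0)
  expect_identical(pas$mode, "passive")
  # only dilution-compensating inflation of blood urea can explain a sweat
  # value above blood when S is excluded
  expect_gt(pas$C_blood_final, full$C_blood_final)
  expect_gt(pas$C_blood_final, truth * 2)
})

test_that("cohort estimation is tibble-in tibble-out with the schema", {
  co <- tiny_cohort(n = 3, noise = 0, missing = 0)
  est <- estimate_cohort(co$samples, truth = co$truth)
  expect_s3_class(est, "tbl_df")
  expect_identical(nrow(est), nrow(co$samples))
  expect_true(all(c("C_blood_est", "S_est", "error", "iterations",
                    "converged") %in% names(est)))
  # the fixed-S identifiability protocol pins S at its true value
  expect_equal(est$S_est, co$truth$S_true)
  # a missing sweat measurement propagates NA estimates
  co2 <- co$samples
  co2$sweat_urea_mmol_per_L[1] <- NA
  est2 <- estimate_cohort(co2[1, ], truth = co$truth)
  expect_true(is.na(est2$C_blood_est))
})
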
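test_that("a linear pass-through parameter inherits the draw CV", {
  # with S = 0 the readout is exactly proportional to plasma urea, so the
  # output CV must equal the CV of the Gaussian input draws (closed form:
  # the draws themselves)
  g <- simulation_grid(n_isf = 8, n_sg = 8)
  res <- parameter_cv("Cp", default_parameters(), g, C_blood = 6.4,
                      n_draws = 100, rel_sd = 0.10, seed = 99)
  set.seed(99)
  draws <- rnorm(100, 6.4, 0.64)
  expect_equal(res$cv_output, sd(draws) / mean(draws) * 100,
               tolerance = 1e-8)
  # ... and lies within Monte-Carlo error of the nominal 10%
  expect_gt(res$cv_output, 8)
  expect_lt(res$cv_output, 12)
})

test_that("perturbation analysis is seed-deterministic", {
  g <- simulation_grid(n_isf = 8, n_sg = 8)
  a <- parameter_cv("S", op_params(), g, seed = 5)
  b <- parameter_cv("S", op_params(), g, seed = 5)
  expect_identical(a, b)
  c2 <- parameter_cv("S", op_params(), g, seed = 6)
  expect_false(identical(a$cv_output, c2$cv_output))
})

test_that("parameters without a path to the readout have ~zero CV", {
  # in fixed-pressure mode the capillary area does not reach the readout
  g <- simulation_grid(n_isf = 8, n_sg = 8)
  res <- parameter_cv("Ac", op_params(), g, seed = 3)
  expect_lt(res$cv_output, 1e-6)
  expect_error(parameter_cv("nonsense", op_params(), g), "nonsense")
  expect_error(parameter_cv("S", default_parameters(), g), "baseline")
})

test_that("output CV scales ~linearly with the input spread (local", {
  g <- simulation_grid(n_isf = 8, n_sg = 8)
  cv05 <- parameter_cv("S", op_params(), g, rel_sd = 0.05,
                       seed = 11)$cv_output
  cv10 <- parameter_cv("S", op_params(), g, rel_sd = 0.10,
                       seed = 11)$cv_output
  expect_gt(cv05 / cv10, 0.4)
  expect_lt(cv05 / cv10, 0.6)
})

test_that("sensitivity ranking at the operating point is reproducible", {
  g <- simulation_grid(n_isf = 8, n_sg = 8)
  sens <- sensitivity_analysis(params_baseline = op_params(), grid = g,
                               seed = 1)
  cv <- setNames(sens$cv_output, sens$parameter)
  # the active source dominates, the dilution ratio and plasma level follow,
  # geometry trails far behind
  expect_gt(cv[["S"]], cv[["Kwu"]])
  expect_gt(cv[["Cp"]], cv[["hsg"]])
  expect_gt(cv[["Kwu"]], cv[["hsg"]])
  expect_identical(sens$cv_output, sort(sens$cv_output, decreasing = TRUE))
})

test_that("initialization sweeps leave the estimates unchanged", {
  co <- tiny_cohort(n = 1, noise = 0, missing = 0, seed = 21)
  rob <- initialization_robustness(co$samples,
                                   init_values = c(0, 25, 50))
  expect_lt(rob$cv_rmspe, 0.1)
  expect_lt(rob$estimate_cv, 0.1)
  expect_identical(nrow(rob$per_init), 3L)
  # a single init value trivially has zero spread
  rob1 <- initialization_robustness(co$samples, init_values = 10)
  expect_identical(rob1$cv_rmspe, 0)
})
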
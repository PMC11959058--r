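# Independent oracles and shared fixtures for the test suite.

# Closed-form steady-state sweat readout for the default ("buffered",
# fixed-pressure) model, derived by hand from the flow calibration, the coil
# Robin balance, the junction dilution and the linear duct profile:
#   u_sg   = u_passive * u_sweat_n
#   dil    = 1 + Kwu / u_sweat_n
#   u_coil = u_sg / dil
#   x      = u_coil * Asg * hsg / (Dsg_wall * pi * d * L)
#   C_sweat = (Cp / (1 + x)) / dil + S * L / u_sg
analytic_sweat <- function(C_blood, params = default_parameters()) {
  u_sg <- params$u_passive * params$u_sweat_n
  dil <- 1 + params$Kwu / params$u_sweat_n
  u_coil <- u_sg / dil
  x <- u_coil * params$Asg * params$hsg /
    (params$Dsg_wall * pi * params$d * params$L)
  (C_blood / (1 + x)) / dil + params$S * params$L / u_sg
}

# Exact two-sided signed-rank p-value by exhaustive enumeration over all
# 2^n sign assignments (no ties, no zeros).
enumerate_signed_rank_p <- function(d) {
  d <- d[d != 0]
  n <- length(d)
  stopifnot(n >= 1, n <= 12, !any(duplicated(abs(d))))
  r <- rank(abs(d))
  w_obs <- sum(r[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  w_all <- as.vector(signs %*% r)
  p_le <- mean(w_all <= w_obs)
  p_ge <- mean(w_all >= w_obs)
  min(1, 2 * min(p_le, p_ge))
}

# small deterministic cohort helpers
tiny_cohort <- function(n = 6, noise = 0, missing = 0, seed = 101) {
  generate_cohort(cohort_spec(n_patients = n, sweat_noise_cv = noise,
                              missing_sweat_fraction = missing, seed = seed))
}

op_params <- function() default_parameters(S = 0.36)
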
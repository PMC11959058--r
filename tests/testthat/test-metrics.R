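test_that("rmse and rmspe match hand arithmetic and their invariants", {
  expect_identical(rmse(c(1, 2, 3), c(1, 2, 3)), 0)
  expect_identical(rmse(3, 0), 3)
  expect_equal(rmse(c(0, 4), c(0, 0)), sqrt(8))
  expect_identical(rmse(c(1, 5), c(2, 3)), rmse(c(2, 3), c(1, 5)))
  expect_error(rmse(1:3, 1:2), "length")
  expect_error(rmse(numeric(0), numeric(0)), "length")

  expect_equal(rmspe(110, 100), 10)
  expect_identical(rmspe(c(3, 7), c(3, 7)), 0)
  expect_equal(rmspe(c(90, 120), c(100, 100)),
               100 * sqrt((0.01 + 0.04) / 2))
  # scale invariance under joint rescaling
  expect_equal(rmspe(c(90, 120) * 3.7, c(100, 100) * 3.7),
               rmspe(c(90, 120), c(100, 100)))
  expect_error(rmspe(c(1, 2), c(1, 0)), "> 0")
})

test_that("Pearson correlation and its Fisher CI behave", {
  x <- c(1, 2, 3, 4, 5)
  pc <- pearson_with_ci(x, 2 * x + 1)
  expect_equal(pc$r, 1)
  expect_equal(pearson_with_ci(x, -x)$r, -1)
  y <- c(1.2, 1.9, 3.4, 3.9, 5.4)
  pc2 <- pearson_with_ci(x, y)
  expect_gte(pc2$r, pc2$ci_lo)
  expect_lte(pc2$r, pc2$ci_hi)
  expect_gte(pc2$ci_lo, -1)
  expect_lte(pc2$ci_hi, 1)
  # agrees with the base implementation it wraps
  ct <- cor.test(x, y)
  expect_equal(pc2$ci_lo, ct$conf.int[1])
  expect_error(pearson_with_ci(x, rep(1, 5)), "constant")
  expect_error(pearson_with_ci(1:3, 1:3), "n >= 4")
})

test_that("Bland-Altman bias and limits of agreement", {
  ba0 <- bland_altman(c(1, 2, 3), c(1, 2, 3))
  expect_identical(c(ba0$bias, ba0$loa_lo, ba0$loa_hi), c(0, 0, 0))
  # differences {-1, +1}: bias 0, limits +/- 1.96 * sqrt(2)
  ba <- bland_altman(c(0, 2), c(1, 1))
  expect_equal(ba$bias, 0)
  expect_equal(ba$loa_hi, 1.96 * sqrt(2))
  expect_equal(ba$loa_lo, -1.96 * sqrt(2))
  # adding a constant shifts the bias, not the width
  est <- c(3, 5, 9, 12)
  meas <- c(2, 6, 8, 13)
  b1 <- bland_altman(est, meas)
  b2 <- bland_altman(est + 2.5, meas)
  expect_equal(b2$bias, b1$bias + 2.5)
  expect_equal(b2$loa_half_width, b1$loa_half_width)
  # swapping the arguments negates the bias exactly
  b3 <- bland_altman(meas, est)
  expect_identical(b3$bias, -b1$bias)
  expect_error(bland_altman(1, 1), "n >= 2")
})

test_that("signed-rank p-values equal exhaustive sign enumeration", {
  expect_warning(p_id <- wilcoxon_signed_rank(c(1, 2, 3), c(1, 2, 3)),
                 "zero")
  expect_identical(p_id, 1)
  # n = 5, all differences positive: the most extreme table entry
  a <- c(5, 6, 7, 8, 9)
  b <- c(1, 2.5, 3.2, 3.9, 4.1)
  expect_equal(wilcoxon_signed_rank(a, b), enumerate_signed_rank_p(a - b))
  # randomized paired cases, n <= 10, tie-free
  set.seed(42)
  for (i in 1:8) {
    n <- sample(5:10, 1)
    d <- round(rnorm(n), 3)
    d <- d[d != 0]
    if (any(duplicated(abs(d))) || length(d) < 5) next
    expect_equal(wilcoxon_signed_rank(d, rep(0, length(d))),
                 enumerate_signed_rank_p(d))
  }
  # two-tailed symmetry under swapping the inputs
  expect_equal(wilcoxon_signed_rank(a, b), wilcoxon_signed_rank(b, a))
})

test_that("GFR stratification uses the documented boundary convention", {
  samples <- tibble::tibble(
    sample_id = paste0("s", 1:6),
    timepoint = "pre",
    blood_urea_mmol_per_L = c(10, 12, 14, 16, 18, 20),
    gfr = c(4.9, 5, 6.5, 8, 8.1, NA))
  est <- samples$blood_urea_mmol_per_L * 1.1
  expect_message(strat <- stratify_by_gfr(samples, est), "without GFR")
  expect_setequal(as.character(strat$gfr_group),
                  c("low (<5)", "mid (5-8)", "high (>8)"))
  # group sizes partition the samples that carry a GFR
  expect_identical(sum(strat$n), 5L)
  low <- strat[strat$gfr_group == "low (<5)", ]
  mid <- strat[strat$gfr_group == "mid (5-8)", ]
  high <- strat[strat$gfr_group == "high (>8)", ]
  expect_identical(low$n, 1L)    # 4.9
  expect_identical(mid$n, 3L)    # 5, 6.5 and 8 are mid (bounds inclusive)
  expect_identical(high$n, 1L)   # 8.1
  expect_equal(strat$rmspe, rep(10, nrow(strat)))
})

test_that("the cohort report assembles all statistics coherently", {
  set.seed(7)
  n <- 12L
  meas <- runif(n, 5, 25)
  est <- meas * (1 + rnorm(n, 0, 0.05))
  df <- tibble::tibble(
    sample_id = paste0("s", 1:n),
    timepoint = rep(c("pre", "post"), each = n / 2),
    blood_urea_mmol_per_L = meas,
    C_blood_est = est,
    gfr = runif(n, 2, 12))
  rep <- evaluate_estimates(df)
  expect_s3_class(rep, "sweat_metrics")
  expect_equal(rep$overall$rmse, rmse(est, meas))
  expect_equal(rep$overall$rmspe, rmspe(est, meas))
  expect_equal(rep$overall$bias, mean(est - meas))
  expect_identical(rep$overall$n, n)
  expect_identical(nrow(rep$by_timepoint), 2L)
  expect_true(!is.null(rep$by_gfr))
  expect_gte(rep$overall$r, rep$overall$ci_lo)
  expect_lte(rep$overall$r, rep$overall$ci_hi)
})
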
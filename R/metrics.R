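#' Root mean square error
#'
#' @param estimated,measured numeric vectors of equal, non-zero length
#'   (mmol/L).
#' @return `sqrt(mean((estimated - measured)^2))` in mmol/L.
#' @examples
#' rmse(c(0, 4), c(0, 0))
#' @export
rmse <- function(estimated, measured) {
  if (length(estimated) != length(measured) || length(estimated) == 0) {
    stop("estimated and measured must have equal, non-zero length",
         call. = FALSE)
  }
  sqrt(mean((estimated - measured)^2))
}

#' Root mean square percentage error
#'
#' @param estimated,measured numeric vectors of equal, non-zero length; all
#'   `measured` must be strictly positive (they are the denominators).
#' @return `100 * sqrt(mean(((estimated - measured) / measured)^2))` in
#'   percent.
#' @examples
#' rmspe(c(110), c(100))
#' @export
rmspe <- function(estimated, measured) {
  if (length(estimated) != length(measured) || length(estimated) == 0) {
    stop("estimated and measured must have equal, non-zero length",
         call. = FALSE)
  }
  if (any(measured <= 0)) {
    stop("all measured values must be > 0 for a percentage error",
         call. = FALSE)
  }
  100 * sqrt(mean(((estimated - measured) / measured)^2))
}

#' Pearson correlation with Fisher-z confidence interval
#'
#' Sample Pearson correlation with the confidence interval obtained by the
#' Fisher z-transform (the conventional choice when no method is otherwise
#' specified). A Spearman coefficient is also reported for reference, as
#' rank correlations are common in method-comparison work; Pearson is
#' primary.
#'
#' @param x,y numeric vectors, `n >= 4`, neither constant.
#' @param level confidence level (default 0.95).
#' @return A one-row tibble with `r`, `ci_lo`, `ci_hi`, `spearman_rho`, `n`.
#' @export
pearson_with_ci <- function(x, y, level = 0.95) {
  if (length(x) != length(y) || length(x) < 4) {
    stop("need paired vectors with n >= 4", call. = FALSE)
  }
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("correlation undefined for constant input", call. = FALSE)
  }
  ct <- stats::cor.test(x, y, method = "pearson", conf.level = level)
  rho <- suppressWarnings(stats::cor(x, y, method = "spearman"))
  tibble::tibble(r = unname(ct$estimate),
                 ci_lo = ct$conf.int[1], ci_hi = ct$conf.int[2],
                 spearman_rho = rho, n = length(x))
}

#' Bland-Altman agreement analysis
#'
#' Bias (mean difference estimated minus measured) and 95% limits of
#' agreement `bias +/- 1.96 * SD` of the differences (sample SD, `n - 1`
#' denominator).
#'
#' @param estimated,measured paired numeric vectors, `n >= 2`.
#' @return A one-row tibble with `bias`, `loa_lo`, `loa_hi`,
#'   `loa_half_width`, `n` (all concentration columns in mmol/L).
#' @examples
#' bland_altman(c(1, 3), c(2, 2))
#' @export
bland_altman <- function(estimated, measured) {
  if (length(estimated) != length(measured) || length(estimated) < 2) {
    stop("need paired vectors with n >= 2", call. = FALSE)
  }
  d <- estimated - measured
  bias <- mean(d)
  half <- 1.96 * stats::sd(d)
  tibble::tibble(bias = bias, loa_lo = bias - half, loa_hi = bias + half,
                 loa_half_width = half, n = length(d))
}

#' Two-tailed Wilcoxon signed-rank test on paired values
#'
#' Paired two-tailed signed-rank test, used to compare the estimation errors
#' of two competing models on the same samples. Zero differences are
#' discarded (standard practice); the exact null distribution is used for
#' n <= 25 without ties, and the normal approximation with tie correction
#' otherwise.
#'
#' @param errors_a,errors_b paired numeric vectors.
#' @return The two-tailed p-value. All-zero differences return `p = 1` with
#'   a warning.
#' @export
wilcoxon_signed_rank <- function(errors_a, errors_b) {
  if (length(errors_a) != length(errors_b)) {
    stop("paired vectors must have equal length", call. = FALSE)
  }
  d <- errors_a - errors_b
  d <- d[d != 0]
  if (length(d) == 0) {
    warning("all paired differences are zero; p = 1", call. = FALSE)
    return(1)
  }
  exact <- length(d) <= 25 && !any(duplicated(abs(d)))
  wt <- suppressWarnings(
    stats::wilcox.test(d, alternative = "two.sided", exact = exact,
                       correct = !exact)
  )
  min(1, unname(wt$p.value))
}

gfr_group <- function(gfr) {
  dplyr::case_when(
    is.na(gfr) ~ NA_character_,
    gfr < 5 ~ "low (<5)",
    gfr <= 8 ~ "mid (5-8)",   # boundary values 5 and 8 belong to the mid group
    TRUE ~ "high (>8)"
  )
}

#' GFR-stratified error summaries
#'
#' Stratifies samples into residual-kidney-function groups — low
#' (GFR < 5), mid (5-8, boundaries inclusive), high (> 8 mL/min/1.73 m^2) —
#' and reports per-group, per-timepoint RMSE and RMSPE of the blood-urea
#' estimates. Samples without a GFR value are excluded (their count is
#' reported as a message).
#'
#' @param samples cohort tibble with `sample_id`, `timepoint`,
#'   `blood_urea_mmol_per_L` and `gfr`.
#' @param estimates vector of estimated blood urea aligned with `samples`,
#'   or a tibble containing `C_blood_est`.
#' @return A tibble with one row per (GFR group, timepoint) and columns
#'   `gfr_group`, `timepoint`, `n`, `rmse`, `rmspe`.
#' @export
stratify_by_gfr <- function(samples, estimates) {
  samples <- tibble::as_tibble(samples)
  if (is.data.frame(estimates)) estimates <- estimates$C_blood_est
  stopifnot(length(estimates) == nrow(samples),
            all(c("gfr", "timepoint", "blood_urea_mmol_per_L") %in%
                  names(samples)))
  df <- dplyr::mutate(samples, .est = estimates)
  df <- dplyr::filter(df, !is.na(.data$.est),
                      !is.na(.data$blood_urea_mmol_per_L))
  n_missing <- sum(is.na(df$gfr))
  if (n_missing > 0) {
    message(n_missing, " sample(s) without GFR excluded from stratification")
  }
  df <- dplyr::filter(df, !is.na(.data$gfr))
  df$gfr_group <- factor(gfr_group(df$gfr),
                         levels = c("low (<5)", "mid (5-8)", "high (>8)"))
  dplyr::summarise(
    dplyr::group_by(df, .data$gfr_group, .data$timepoint),
    n = dplyr::n(),
    rmse = rmse(.data$.est, .data$blood_urea_mmol_per_L),
    rmspe = rmspe(.data$.est, .data$blood_urea_mmol_per_L),
    .groups = "drop"
  )
}

#' Full validation report for a cohort of estimates
#'
#' Assembles the method-comparison statistics used to validate the inverse
#' model against measured blood urea: overall and per-timepoint RMSE/RMSPE,
#' Pearson correlation with 95% CI, Bland-Altman bias and limits of
#' agreement, and GFR-stratified summaries when GFR is available.
#'
#' @param estimates a tibble as returned by [estimate_cohort()] (must contain
#'   `C_blood_est`, `blood_urea_mmol_per_L`, `timepoint`; optionally `gfr`).
#' @return An object of class `sweat_metrics`: a list with `overall` (one-row
#'   tibble: `n`, `rmse`, `rmspe`, `r`, `ci_lo`, `ci_hi`, `bias`, `loa_lo`,
#'   `loa_hi`), `by_timepoint` (per-timepoint tibble with RMSE/RMSPE and
#'   Bland-Altman columns) and `by_gfr` (tibble or NULL).
#' @export
evaluate_estimates <- function(estimates) {
  df <- tibble::as_tibble(estimates)
  stopifnot(all(c("C_blood_est", "blood_urea_mmol_per_L", "timepoint") %in%
                  names(df)))
  df <- dplyr::filter(df, !is.na(.data$C_blood_est),
                      !is.na(.data$blood_urea_mmol_per_L))
  if (nrow(df) < 4) stop("need at least 4 complete pairs", call. = FALSE)
  pc <- pearson_with_ci(df$C_blood_est, df$blood_urea_mmol_per_L)
  ba <- bland_altman(df$C_blood_est, df$blood_urea_mmol_per_L)
  overall <- tibble::tibble(
    n = nrow(df),
    rmse = rmse(df$C_blood_est, df$blood_urea_mmol_per_L),
    rmspe = rmspe(df$C_blood_est, df$blood_urea_mmol_per_L),
    r = pc$r, ci_lo = pc$ci_lo, ci_hi = pc$ci_hi,
    bias = ba$bias, loa_lo = ba$loa_lo, loa_hi = ba$loa_hi
  )
  by_tp <- dplyr::summarise(
    dplyr::group_by(df, .data$timepoint),
    n = dplyr::n(),
    rmse = rmse(.data$C_blood_est, .data$blood_urea_mmol_per_L),
    rmspe = rmspe(.data$C_blood_est, .data$blood_urea_mmol_per_L),
    bias = mean(.data$C_blood_est - .data$blood_urea_mmol_per_L),
    loa_half_width = 1.96 *
      stats::sd(.data$C_blood_est - .data$blood_urea_mmol_per_L),
    .groups = "drop"
  )
  by_gfr <- NULL
  if ("gfr" %in% names(df) && any(!is.na(df$gfr))) {
    by_gfr <- stratify_by_gfr(df, df$C_blood_est)
  }
  structure(list(overall = overall, by_timepoint = by_tp, by_gfr = by_gfr),
            class = "sweat_metrics")
}

#' @export
print.sweat_metrics <- function(x, ...) {
  cat("<sweat_metrics> estimated vs measured blood urea\n")
  print(x$overall)
  cat("by timepoint:\n")
  print(x$by_timepoint)
  if (!is.null(x$by_gfr)) {
    cat("by GFR group:\n")
    print(x$by_gfr)
  }
  invisible(x)
}
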
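#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a forward simulation into its concentration profiles
#'
#' @param x a `sweat_simulation` object.
#' @param ... unused.
#' @return A tibble with one row per grid node: `compartment` (`"isf"` or
#'   `"gland"`), `node`, `y` (m) and `C` (mmol/L; the gland profile is the
#'   diluted concentration).
#' @export
tidy.sweat_simulation <- function(x, ...) {
  dplyr::bind_rows(
    dplyr::mutate(x$C_ISF_profile, compartment = "isf", .before = 1),
    dplyr::mutate(x$C_sg_dil_profile, compartment = "gland", .before = 1)
  )
}

#' One-row summary of a forward simulation
#'
#' @param x a `sweat_simulation` object.
#' @param ... unused.
#' @return A one-row tibble: `C_blood`, `C_sweat`, `C_sg_exit`, `u_sg`,
#'   `u_sg_n`, `J_source`, `converged`, `steps`, `mass_balance_residual`.
#' @export
glance.sweat_simulation <- function(x, ...) {
  tibble::tibble(C_blood = x$C_blood, C_sweat = x$C_sweat,
                 C_sg_exit = x$C_sg_exit, u_sg = x$flows$u_sg,
                 u_sg_n = x$flows$u_sg_n, J_source = x$J_source,
                 converged = x$converged, steps = x$steps,
                 mass_balance_residual = x$mass_balance_residual)
}

#' Tidy an estimation run into its error trace
#'
#' @param x a `sweat_estimate` object.
#' @param ... unused.
#' @return A tibble with `iteration` and `error` (running best squared
#'   error, mmol^2 L^-2).
#' @export
tidy.sweat_estimate <- function(x, ...) {
  tibble::tibble(iteration = seq_along(x$error_trace),
                 error = x$error_trace)
}

#' One-row summary of an estimation run
#'
#' @param x a `sweat_estimate` object.
#' @param ... unused.
#' @return A one-row tibble: `C_blood_final`, `S_final`, `error`,
#'   `iterations`, `converged`, `mode`, `at_edge`.
#' @export
glance.sweat_estimate <- function(x, ...) {
  tibble::tibble(C_blood_final = x$C_blood_final,
                 S_final = x$theta_final$S,
                 error = utils::tail(x$error_trace, 1),
                 iterations = x$iterations, converged = x$converged,
                 mode = x$mode, at_edge = x$at_edge)
}

#' Tidy a metrics report
#'
#' @param x a `sweat_metrics` object.
#' @param ... unused.
#' @return The per-timepoint metric tibble (with GFR strata appended when
#'   present, distinguished by the `stratum` column).
#' @export
tidy.sweat_metrics <- function(x, ...) {
  tp <- dplyr::mutate(x$by_timepoint, stratum = "timepoint", .before = 1)
  if (is.null(x$by_gfr)) return(tp)
  gfr <- dplyr::mutate(
    dplyr::rename(x$by_gfr, group = "gfr_group"),
    stratum = "gfr", .before = 1)
  dplyr::bind_rows(tp, gfr)
}

#' One-row summary of a metrics report
#'
#' @param x a `sweat_metrics` object.
#' @param ... unused.
#' @return The overall one-row tibble (`n`, `rmse`, `rmspe`, `r`, CI,
#'   Bland-Altman bias and limits).
#' @export
glance.sweat_metrics <- function(x, ...) x$overall
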
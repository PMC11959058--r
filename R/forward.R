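#' Simulation grid for the two transport domains
#'
#' Discretization of the one-dimensional interstitial-fluid (ISF) and sweat
#' gland domains. Vertex-centred grids are used (first node at the domain
#' entrance, last node at the exit), so the gland exit readout sits exactly at
#' `y = sg_length`.
#'
#' The default ISF extent is `VISF / AISF` (~2.73e-5 m), the length consistent
#' with the tabulated compartment volume and cross-sectional area; the gland
#' length equals the parameter `L`.
#'
#' @param n_isf,n_sg node counts (>= 8).
#' @param isf_length,sg_length domain lengths in m; `NULL` means derive from
#'   `params` at simulation time.
#' @param convergence_tol relative steady-state tolerance of the pseudo-time
#'   integration, in (0, 1e-2].
#' @param max_steps pseudo-time iteration cap.
#' @return An object of class `sweat_grid`.
#' @export
simulation_grid <- function(n_isf = 32, n_sg = 64,
                            isf_length = NULL, sg_length = NULL,
                            convergence_tol = 1e-8, max_steps = 500) {
  stopifnot(n_isf >= 8, n_sg >= 8,
            convergence_tol > 0, convergence_tol <= 1e-2, max_steps >= 1)
  if (!is.null(isf_length)) stopifnot(isf_length > 0)
  if (!is.null(sg_length)) stopifnot(sg_length > 0)
  structure(list(n_isf = as.integer(n_isf), n_sg = as.integer(n_sg),
                 isf_length = isf_length, sg_length = sg_length,
                 convergence_tol = convergence_tol,
                 max_steps = as.integer(max_steps)),
            class = "sweat_grid")
}

#' Poiseuille hydraulic resistance of the gland duct
#'
#' `R = 128 mu L / (pi d^4)` for a cylindrical duct, in Pa s m^-3.
#'
#' @param mu water viscosity (Pa s).
#' @param L duct length (m).
#' @param d luminal diameter (m).
#' @return Hydraulic resistance in Pa s m^-3.
#' @examples
#' hydraulic_resistance(1e-3, 4e-3, 5e-6)
#' @export
hydraulic_resistance <- function(mu, L, d) {
  if (any(c(mu, L, d) <= 0)) stop("mu, L and d must be > 0", call. = FALSE)
  128 * mu * L / (pi * d^4)
}

#' Starling capillary filtration rate
#'
#' Trans-capillary water flow `Q_water = Lpc * Ac * (Pc - PISF)` in m^3 s^-1.
#' A negative pressure difference yields negative (reverse) filtration; the
#' value is not clamped.
#'
#' @param params a `sweat_params` object.
#' @return Water flow in m^3 s^-1.
#' @export
capillary_filtration <- function(params) {
  params$Lpc * params$Ac * (params$Pc - params$PISF)
}

#' ISF water velocity
#'
#' @param Q_water capillary filtration rate (m^3 s^-1).
#' @param AISF ISF cross-sectional area (m^2).
#' @return Velocity `Q_water / AISF` in m s^-1.
#' @export
isf_velocity <- function(Q_water, AISF) {
  if (AISF <= 0) stop("AISF must be > 0", call. = FALSE)
  Q_water / AISF
}

#' Darcy flow through the sweat gland
#'
#' `Q_water_sg = deltaP / R`; the duct water velocity is corrected by the
#' normalized experimental sweat velocity: `u_sg = Q_water_sg * u_sweat_n /
#' Asg`, and `u_sg_n = u_sg / u_passive`.
#'
#' @param params a `sweat_params` object.
#' @param deltaP driving pressure across the gland (Pa), >= 0.
#' @param R hydraulic resistance (Pa s m^-3), > 0.
#' @return A list with `Q_water_sg` (m^3 s^-1), `u_sg` (m s^-1) and the
#'   dimensionless `u_sg_n`.
#' @export
gland_flow <- function(params, deltaP, R) {
  if (R <= 0) stop("R must be > 0", call. = FALSE)
  if (deltaP < 0) stop("deltaP must be >= 0", call. = FALSE)
  Q <- deltaP / R
  u_sg <- Q * params$u_sweat_n / params$Asg
  list(Q_water_sg = Q, u_sg = u_sg, u_sg_n = u_sg / params$u_passive)
}

#' Plasma-to-ISF urea flow
#'
#' `J_source = kDE * (Cp - C_ISF) * Vp` in mol s^-1; the sign follows the
#' concentration gradient.
#'
#' @param Cp plasma urea concentration (mol m^-3).
#' @param C_ISF ISF urea concentration (mol m^-3).
#' @param params a `sweat_params` object.
#' @return Urea flow in mol s^-1.
#' @export
plasma_to_isf_flux <- function(Cp, C_ISF, params) {
  params$kDE * (Cp - C_ISF) * params$Vp
}

#' Trans-wall urea flux density (Fick)
#'
#' `Dsg_wall * (C_ISF - C_sg) / hsg` per unit wall area, mol m^-2 s^-1. The
#' caller multiplies by the exchange area to obtain mol s^-1.
#'
#' @param C_ISF,C_sg concentrations on either side of the gland wall
#'   (mol m^-3).
#' @param params a `sweat_params` object.
#' @return Flux density in mol m^-2 s^-1.
#' @export
wall_flux_density <- function(C_ISF, C_sg, params) {
  if (params$hsg <= 0) stop("hsg must be > 0", call. = FALSE)
  params$Dsg_wall * (C_ISF - C_sg) / params$hsg
}

#' Dilution correction for co-transported water
#'
#' `C_sg / (1 + Kwu / u_sg_n)`: the gland urea concentration reduced by the
#' water co-transported into the duct, governed by the water/urea volumetric
#' flow ratio and the normalized sweat velocity. Monotone increasing in
#' `u_sg_n`; the identity when `Kwu = 0`.
#'
#' @param C_sg undiluted gland urea concentration (mol m^-3).
#' @param Kwu water/urea volumetric flow ratio (>= 0).
#' @param u_sg_n normalized duct water velocity (> 0).
#' @return Diluted concentration in mol m^-3.
#' @examples
#' dilute_concentration(7, 2.5, 1) # 2.0
#' @export
dilute_concentration <- function(C_sg, Kwu, u_sg_n) {
  if (any(u_sg_n <= 0)) stop("u_sg_n must be > 0", call. = FALSE)
  if (any(Kwu < 0)) stop("Kwu must be >= 0", call. = FALSE)
  C_sg / (1 + Kwu / u_sg_n)
}

#' Interstitial pressure and gland driving pressure
#'
#' In `"fixed"` mode (default) the interstitial pressure stays at its
#' tabulated value and the gland driving pressure is calibrated so that the
#' passive duct velocity equals `u_passive` (`deltaP = u_passive * Asg * R`).
#' In `"balanced"` mode the interstitial pressure is solved so that capillary
#' inflow (Starling) equals gland outflow (Darcy) at steady state, realising
#' the feedback narrative in which rising interstitial pressure throttles
#' filtration; as the duct blocks (`R -> Inf`) the balanced pressure tends to
#' the capillary pressure and flow ceases.
#'
#' @param params a `sweat_params` object.
#' @param mode `"fixed"` or `"balanced"`.
#' @return A list with `PISF_effective` (mmHg) and `deltaP` (Pa).
#' @export
solve_pressure_balance <- function(params, mode = c("fixed", "balanced")) {
  mode <- match.arg(mode)
  R <- hydraulic_resistance(params$mu, params$L, params$d)
  if (mode == "fixed") {
    return(list(PISF_effective = params$PISF,
                deltaP = params$u_passive * params$Asg * R))
  }
  # balanced: Lpc*Ac*(Pc - p) = max(p, 0)*MMHG_PA / R, p in mmHg
  f <- function(p) {
    params$Lpc * params$Ac * (params$Pc - p) - max(p, 0) * MMHG_PA / R
  }
  lo <- min(params$PISF, 0)
  if (f(lo) <= 0 || f(params$Pc) >= 0) {
    stop("no pressure balance in (", lo, ", ", params$Pc, ") mmHg; ",
         "f(lo) = ", f(lo), ", f(Pc) = ", f(params$Pc), call. = FALSE)
  }
  p <- stats::uniroot(f, c(lo, params$Pc), tol = 1e-13)$root
  list(PISF_effective = p, deltaP = max(p, 0) * MMHG_PA)
}

#' Water-flow state of the transport model
#'
#' Convenience wrapper assembling all flow quantities: Starling filtration,
#' ISF velocity, duct resistance, driving pressure, Darcy flow and duct
#' velocity.
#'
#' @param params a `sweat_params` object.
#' @param pressure_mode `"fixed"` or `"balanced"`; see
#'   [solve_pressure_balance()].
#' @return A list with `Q_water`, `u_ISF`, `R`, `deltaP`, `PISF_effective`,
#'   `Q_water_sg`, `u_sg`, `u_sg_n`.
#' @export
compute_flows <- function(params, pressure_mode = c("fixed", "balanced")) {
  pressure_mode <- match.arg(pressure_mode)
  R <- hydraulic_resistance(params$mu, params$L, params$d)
  pb <- solve_pressure_balance(params, pressure_mode)
  p2 <- params
  p2$PISF <- pb$PISF_effective
  Q_water <- capillary_filtration(p2)
  gf <- gland_flow(params, pb$deltaP, R)
  c(list(Q_water = Q_water,
         u_ISF = isf_velocity(Q_water, params$AISF),
         R = R, deltaP = pb$deltaP, PISF_effective = pb$PISF_effective),
    gf)
}

# implicit pseudo-time integration of dc/dt = A c + b to steady state,
# with a geometrically growing step (unconditionally stable); optional
# positivity projection for clamped sink modes. Without a clamp the system is
# linear and the steady state is taken in a single infinite implicit step
# (a direct solve of A c = -b).
pseudo_time_steady <- function(A, b, c0, tol, max_steps, clamp = FALSE,
                               dt0 = 1) {
  if (!clamp) {
    c_st <- solve(A, -b)
    return(list(c = c_st, converged = all(is.finite(c_st)), steps = 1L))
  }
  n <- length(c0)
  c_cur <- c0
  dt <- dt0
  I_n <- diag(n)
  steps <- 0L
  converged <- FALSE
  for (k in seq_len(max_steps)) {
    M <- I_n / dt - A
    c_new <- solve(M, c_cur / dt + b)
    if (clamp) c_new <- pmax(c_new, 0)
    steps <- k
    delta <- max(abs(c_new - c_cur)) / max(max(abs(c_new)), 1e-300)
    c_cur <- c_new
    if (delta < tol) {
      converged <- TRUE
      break
    }
    dt <- min(dt * 4, 1e14)
  }
  list(c = c_cur, converged = converged, steps = steps)
}

#' Steady-state forward simulation: blood urea to sweat urea
#'
#' Integrates the coupled transport system to steady state and returns the
#' sweat urea concentration read at the gland exit.
#'
#' The model has three stages:
#' \enumerate{
#'   \item \strong{ISF compartment}: 1-D convection-diffusion with a
#'     distributed plasma source `J_source / VISF` (the plasma compartment is
#'     0-D; the spatial mean of the ISF profile drives the source) and an
#'     active-transport sink whose bookkeeping depends on `s_mode` (below).
#'     Zero-diffusive-flux boundaries at both ends.
#'   \item \strong{Secretory coil}: passive trans-wall equilibration (Fick,
#'     [wall_flux_density()]) between the ISF and the water entering the
#'     gland, as a Robin flux balance over the wall exchange area `pi d L`;
#'     the coil concentration is then diluted once by the co-transported
#'     water ([dilute_concentration()]) where the water influx enters, at the
#'     coil-duct junction.
#'   \item \strong{Duct}: 1-D convection-diffusion in the diluted
#'     concentration with the active source `S` distributed along the duct
#'     (urea pumped by transporters in the duct membrane enters downstream of
#'     the water influx and is not re-diluted), Dirichlet inlet at the coil
#'     value, purely advective outflow at the exit.
#' }
#'
#' Active-transport bookkeeping (`s_mode`):
#' \describe{
#'   \item{`"buffered"` (default)}{the ISF sink is treated as drawn from the
#'     epidermal urea reservoir rather than the bulk ISF, which is therefore
#'     not depleted. At reported physiological values of `S` the capillary
#'     supply rate (`kDE Vp / VISF` ~ 6e-4 /s) is orders of magnitude below
#'     `S`, so a literal bulk sink admits no non-negative steady state.}
#'   \item{`"literal"`}{the sink `-S` appears in the ISF equation exactly as
#'     written, with a positivity projection; at large `S` the ISF drains to
#'     zero and the passive pathway shuts off.}
#'   \item{`"conservative"`}{molar-matched: the duct source is rescaled by
#'     `VISF / (Asg L)` and both the sink and the coil wall flux are debited
#'     from the ISF balance, so plasma inflow equals gland outflow exactly at
#'     steady state (mass-balance residual below 1e-3).}
#' }
#'
#' @param C_blood non-negative blood (plasma) urea concentration, mol m^-3
#'   (== mmol/L).
#' @param params a `sweat_params` object.
#' @param grid a [simulation_grid()].
#' @param pressure_mode `"fixed"` or `"balanced"`.
#' @param s_mode `"buffered"`, `"literal"` or `"conservative"`.
#' @return An object of class `sweat_simulation`: a list with `C_sweat`
#'   (mol m^-3), `C_sg_exit` (undiluted gland exit concentration, so that
#'   `dilute_concentration(C_sg_exit, Kwu, u_sg_n)` reproduces `C_sweat`
#'   bit-identically), profiles `C_ISF_profile` and `C_sg_dil_profile` with
#'   node coordinates, `flows`, `J_source` (mol s^-1), `converged`, `steps`,
#'   and `mass_balance_residual` (relative molar imbalance of configured
#'   inflows vs the advective outflow; bounded by the solver tolerance only
#'   in `"conservative"` mode, reported diagnostically in the others).
#' @examples
#' sim <- simulate_sweat(6.4, default_parameters(S = 0.36), simulation_grid())
#' sim$C_sweat
#' @export
simulate_sweat <- function(C_blood, params, grid = simulation_grid(),
                           pressure_mode = c("fixed", "balanced"),
                           s_mode = c("buffered", "literal", "conservative")) {
  pressure_mode <- match.arg(pressure_mode)
  s_mode <- match.arg(s_mode)
  if (C_blood < 0) stop("C_blood must be >= 0", call. = FALSE)
  viol <- validate_parameters(params)
  if (length(viol)) stop("invalid parameters: ",
                         paste(viol, collapse = "; "), call. = FALSE)

  fl <- compute_flows(params, pressure_mode)
  if (fl$u_sg <= 0) stop("duct velocity is zero; no sweat is produced",
                         call. = FALSE)

  L_isf <- if (is.null(grid$isf_length)) params$VISF / params$AISF else
    grid$isf_length
  L_sg <- if (is.null(grid$sg_length)) params$L else grid$sg_length

  # coil geometry: wall exchange area along the gland, pre-dilution velocity
  A_wall <- pi * params$d * params$L
  dil_factor <- 1 + params$Kwu / fl$u_sg_n
  u_coil <- fl$u_sg / dil_factor
  # coil Robin balance: u_coil*Asg*C_coil = wall_flux_density * A_wall
  #   => C_coil = C_isf_mean / (1 + x)
  x_coil <- u_coil * params$Asg * params$hsg / (params$Dsg_wall * A_wall)
  coil_gain <- 1 / (1 + x_coil)

  ## --- ISF domain -------------------------------------------------------
  n <- grid$n_isf
  dy <- L_isf / (n - 1)
  k_isf <- params$kDE * params$Vp / params$VISF   # plasma exchange rate, 1/s
  # central diffusion with zero-flux ghosts; upwind advection (u_ISF >= 0)
  Dd <- params$DISF / dy^2
  u <- max(fl$u_ISF, 0)
  main <- rep(-2 * Dd - u / dy, n)
  main[1] <- main[1] + Dd + u / dy  # zero-gradient ghost at the entrance
  main[n] <- main[n] + Dd           # zero-flux ghost at the far end
  A <- diag(main)
  ii <- seq_len(n - 1)
  A[cbind(ii + 1, ii)] <- Dd + u / dy
  A[cbind(ii, ii + 1)] <- Dd
  # distributed plasma source k_isf*(Cp - mean(c)): rank-one mean coupling
  A <- A - k_isf * matrix(1 / n, n, n)
  b <- rep(k_isf * C_blood, n)
  clamp <- FALSE
  if (s_mode %in% c("literal", "conservative")) {
    b <- b - params$S
    clamp <- TRUE
  }
  if (s_mode == "conservative") {
    # coil wall flux debited from the ISF balance (per ISF volume), linear in
    # the ISF mean: J_coil = u_coil*Asg*coil_gain * mean(c)
    g_coil <- u_coil * params$Asg * coil_gain / params$VISF
    A <- A - g_coil * matrix(1 / n, n, n)
  }
  # slowest ISF rate sets the initial pseudo-time step
  dt0 <- 1 / max(k_isf, 1e-12)
  isf <- pseudo_time_steady(A, b, rep(0, n), grid$convergence_tol,
                            grid$max_steps, clamp = clamp, dt0 = dt0 / 10)
  C_isf <- isf$c
  C_isf_mean <- mean(C_isf)

  ## --- coil and duct ----------------------------------------------------
  C_coil <- coil_gain * C_isf_mean
  c_in <- dilute_concentration(C_coil, params$Kwu, fl$u_sg_n)

  m <- grid$n_sg
  dz <- L_sg / (m - 1)
  s_src <- if (s_mode == "conservative") {
    params$S * params$VISF / (params$Asg * params$L)
  } else {
    params$S
  }
  Dg <- params$Dsw / dz^2
  ug <- fl$u_sg
  Ag <- diag(rep(-2 * Dg - ug / dz, m))
  jj <- seq_len(m - 1)
  Ag[cbind(jj + 1, jj)] <- Dg + ug / dz
  Ag[cbind(jj, jj + 1)] <- Dg
  bg <- rep(s_src, m)
  # node 1: Dirichlet inlet (held at the diluted coil concentration)
  Ag[1, ] <- 0
  Ag[1, 1] <- -1
  bg[1] <- c_in
  # exit node: purely advective outflow (no diffusive flux across the exit)
  Ag[m, ] <- 0
  Ag[m, m - 1] <- ug / dz
  Ag[m, m] <- -ug / dz
  duct <- pseudo_time_steady(Ag, bg, rep(0, m), grid$convergence_tol,
                             grid$max_steps, clamp = FALSE,
                             dt0 = dz / ug)
  C_dil <- duct$c

  ## --- readout and bookkeeping -----------------------------------------
  C_sg_exit <- C_dil[m] * dil_factor
  C_sweat <- dilute_concentration(C_sg_exit, params$Kwu, fl$u_sg_n)
  J_source <- plasma_to_isf_flux(C_blood, C_isf_mean, params)
  J_coil <- wall_flux_density(C_isf_mean, C_coil, params) * A_wall
  J_out <- ug * params$Asg * C_dil[m]
  J_active <- s_src * params$Asg * L_sg
  J_in <- if (s_mode == "conservative") J_source else J_source + J_active
  residual <- abs(J_in - J_out) / max(abs(J_in), abs(J_out), 1e-300)

  structure(list(
    C_sweat = C_sweat,
    C_sg_exit = C_sg_exit,
    C_ISF_profile = tibble::new_tibble(
      list(node = seq_len(n), y = (seq_len(n) - 1) * dy, C = C_isf),
      nrow = n),
    C_sg_dil_profile = tibble::new_tibble(
      list(node = seq_len(m), y = (seq_len(m) - 1) * dz, C = C_dil),
      nrow = m),
    C_coil = C_coil,
    flows = fl,
    J_source = J_source,
    J_coil = J_coil,
    converged = isf$converged && duct$converged,
    steps = isf$steps + duct$steps,
    mass_balance_residual = residual,
    C_blood = C_blood,
    pressure_mode = pressure_mode,
    s_mode = s_mode
  ), class = "sweat_simulation")
}

#' @export
print.sweat_simulation <- function(x, ...) {
  cat("<sweat_simulation>\n")
  cat(sprintf("  C_blood  %.4g mmol/L  ->  C_sweat  %.4g mmol/L\n",
              x$C_blood, x$C_sweat))
  cat(sprintf("  u_sg %.3g m/s (u_sg_n %.3g), dilution x%.3g\n",
              x$flows$u_sg, x$flows$u_sg_n,
              1 + (x$C_sg_exit / max(x$C_sweat, 1e-300) - 1)))
  cat(sprintf("  modes: pressure %s, S %s; converged %s in %d steps; ",
              x$pressure_mode, x$s_mode, x$converged, x$steps))
  cat(sprintf("mass residual %.3g\n", x$mass_balance_residual))
  invisible(x)
}
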
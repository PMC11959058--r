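#' Default urea-transport model parameters
#'
#' Canonical registry of the physical constants of the blood-to-sweat urea
#' transport model: capillary filtration (Starling), dermal urea clearance,
#' diffusivities, compartment geometry, duct hydraulics, the water/urea
#' dilution ratio, the active urea transport rate `S`, and the normalized
#' experimental sweat velocity.
#'
#' Unit conventions: concentrations are held in mol m^-3, which is numerically
#' identical to mmol L^-1, so clinical values can be used unchanged. Pressures
#' are stored in mmHg (as conventionally tabulated for Starling terms) and
#' converted to Pa (1 mmHg = 133.322 Pa) only where they meet Darcy's law,
#' whose hydraulic resistance is in Pa s m^-3.
#'
#' `S` defaults to 0 (purely passive transport) because no literature
#' reference value exists; `u_sweat_n` defaults to 1, the passive sweating
#' condition; `u_passive` is the reference passive sweat velocity
#' (3e-4 m s^-1) against which sweat velocities are normalized, exposed as a
#' parameter so the normalization is auditable.
#'
#' @param ... named overrides of individual parameter values, e.g.
#'   `default_parameters(S = 0.36, u_sweat_n = 2)`.
#'
#' @return An object of class `sweat_params`: a named list with fields
#'   `Pc`, `PISF` (mmHg), `Lpc` (m s^-1 mmHg^-1), `kDE` (s^-1), `Dsg_wall`,
#'   `DISF`, `Dsw` (m^2 s^-1), `Asg`, `Ac`, `AISF` (m^2), `Vp`, `VISF` (m^3),
#'   `d`, `L`, `hsg` (m), `Kwu` (dimensionless), `mu` (Pa s),
#'   `S` (mol m^-3 s^-1), `u_sweat_n` (dimensionless), `u_passive` (m s^-1).
#'
#' @examples
#' p <- default_parameters()
#' p$kDE
#' default_parameters(S = 0.36)$S
#' @export
default_parameters <- function(...) {
  p <- list(
    Pc        = 30,        # capillary hydrostatic pressure, mmHg
    PISF      = -3,        # interstitial hydrostatic pressure, mmHg
    Lpc       = 6.5e-10,   # capillary hydraulic conductivity, m s^-1 mmHg^-1
    kDE       = 1.2e-3,    # dermal clearance constant of urea, s^-1
    Dsg_wall  = 3.01e-10,  # urea diffusivity across the gland wall, m^2 s^-1
    DISF      = 9.29e-10,  # urea diffusivity in ISF, m^2 s^-1
    Dsw       = 1.38e-9,   # urea diffusivity in sweat, m^2 s^-1
    Asg       = 1.96e-11,  # gland luminal cross-section, m^2
    Ac        = 1.5e-8,    # capillary exchange surface area, m^2
    AISF      = 2.2e-8,    # ISF cross-sectional area, m^2
    Vp        = 3.02e-13,  # capillary compartment volume, m^3
    VISF      = 6.0e-13,   # ISF compartment volume, m^3
    d         = 5e-6,      # gland luminal diameter, m
    L         = 4e-3,      # gland length, m
    Kwu       = 2.5,       # water/urea volumetric flow ratio, dimensionless
    hsg       = 5e-5,      # gland wall thickness, m
    mu        = 1e-3,      # water viscosity, Pa s
    S         = 0,         # active urea transport rate, mol m^-3 s^-1
    u_sweat_n = 1,         # normalized experimental sweat velocity
    u_passive = 3e-4       # reference passive sweat velocity, m s^-1
  )
  dots <- list(...)
  if (length(dots)) {
    bad <- setdiff(names(dots), names(p))
    if (length(bad) || is.null(names(dots)) || any(names(dots) == "")) {
      stop("unknown parameter name(s): ", paste(bad, collapse = ", "),
           call. = FALSE)
    }
    p[names(dots)] <- dots
  }
  structure(p, class = "sweat_params")
}

# 1 mmHg in Pa; used wherever Starling (mmHg) meets Darcy (Pa)
MMHG_PA <- 133.322

#' Validate a parameter set
#'
#' Checks the physical invariants of a [default_parameters()] object and
#' reports violations rather than raising, so callers can collect and display
#' them.
#'
#' @param params a `sweat_params` object (or named list with the same fields).
#' @return A character vector of violation descriptions, each naming the
#'   offending field; empty (`character(0)`) when all invariants hold.
#' @examples
#' validate_parameters(default_parameters())
#' validate_parameters(default_parameters(d = 0))
#' @export
validate_parameters <- function(params) {
  v <- character(0)
  need <- names(default_parameters())
  missing_f <- setdiff(need, names(params))
  if (length(missing_f)) {
    return(paste0("missing field: ", missing_f))
  }
  pos <- c("Lpc", "kDE", "Dsg_wall", "DISF", "Dsw", "Asg", "Ac", "AISF",
           "Vp", "VISF", "d", "L", "hsg", "mu", "u_passive", "u_sweat_n")
  for (f in pos) {
    x <- params[[f]]
    if (!is.numeric(x) || length(x) != 1 || !is.finite(x) || x <= 0) {
      v <- c(v, paste0(f, " must be a strictly positive number"))
    }
  }
  for (f in c("S", "Kwu")) {
    x <- params[[f]]
    if (!is.numeric(x) || length(x) != 1 || !is.finite(x) || x < 0) {
      v <- c(v, paste0(f, " must be a non-negative number"))
    }
  }
  for (f in c("Pc", "PISF")) {
    x <- params[[f]]
    if (!is.numeric(x) || length(x) != 1 || !is.finite(x)) {
      v <- c(v, paste0(f, " must be a finite number"))
    }
  }
  v
}

#' Replace one parameter value, copy-on-write
#'
#' Returns a copy of `params` with the single field `name` replaced; the
#' input is never mutated. This is the primitive behind the Gaussian
#' perturbation sensitivity analysis.
#'
#' @param params a `sweat_params` object.
#' @param name a single parameter name (see [default_parameters()]).
#' @param value the new numeric value.
#' @return A new `sweat_params` object.
#' @examples
#' p <- perturb_parameter(default_parameters(), "Dsw", 1.5e-9)
#' p$Dsw
#' @export
perturb_parameter <- function(params, name, value) {
  stopifnot(length(name) == 1)
  if (!name %in% names(params)) {
    stop("unknown parameter name: '", name, "'", call. = FALSE)
  }
  params[[name]] <- value
  params
}

#' @export
print.sweat_params <- function(x, ...) {
  cat("<sweat_params> urea transport model parameters\n")
  print(tidy_params(x), n = Inf)
  invisible(x)
}

#' Parameter set as a tibble
#'
#' @param params a `sweat_params` object.
#' @return A tibble with columns `parameter` and `value`.
#' @export
tidy_params <- function(params) {
  tibble::tibble(parameter = names(params),
                 value = vapply(params, as.numeric, numeric(1)))
}

#' Read / write parameter files
#'
#' Parameters are stored either as a flat JSON object keyed by field name, or
#' as a CSV dialect with columns `symbol,value,unit`. JSON round-trips are
#' bit-exact (full double precision is written).
#'
#' @param params a `sweat_params` object.
#' @param path file path; format chosen by extension (`.json` or `.csv`).
#' @return `write_parameters()` returns `path` invisibly; `read_parameters()`
#'   returns a `sweat_params` object.
#' @examples
#' f <- tempfile(fileext = ".json")
#' write_parameters(default_parameters(), f)
#' identical(read_parameters(f), default_parameters())
#' @export
write_parameters <- function(params, path) {
  stopifnot(inherits(params, "sweat_params"))
  if (grepl("\\.csv$", path, ignore.case = TRUE)) {
    df <- data.frame(symbol = names(params),
                     value = vapply(params, format_full, character(1)),
                     unit = param_units()[names(params)],
                     stringsAsFactors = FALSE)
    utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  } else {
    jsonlite::write_json(lapply(unclass(params), format_full), path,
                         auto_unbox = TRUE)
  }
  invisible(path)
}

#' @rdname write_parameters
#' @export
read_parameters <- function(path) {
  if (grepl("\\.csv$", path, ignore.case = TRUE)) {
    df <- utils::read.csv(path, stringsAsFactors = FALSE)
    vals <- as.list(as.numeric(df$value))
    names(vals) <- df$symbol
  } else {
    vals <- jsonlite::read_json(path)
    vals <- lapply(vals, as.numeric)
  }
  p <- default_parameters()
  bad <- setdiff(names(vals), names(p))
  if (length(bad)) {
    stop("unknown parameter name(s) in ", path, ": ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  p[names(vals)] <- vals
  v <- validate_parameters(p)
  if (length(v)) stop("invalid parameter file ", path, ": ",
                      paste(v, collapse = "; "), call. = FALSE)
  p
}

# full-precision decimal representation (17 significant digits round-trips
# IEEE doubles exactly)
format_full <- function(x) format(as.numeric(x), digits = 17, scientific = TRUE)

param_units <- function() {
  c(Pc = "mmHg", PISF = "mmHg", Lpc = "m s-1 mmHg-1", kDE = "s-1",
    Dsg_wall = "m2 s-1", DISF = "m2 s-1", Dsw = "m2 s-1", Asg = "m2",
    Ac = "m2", AISF = "m2", Vp = "m3", VISF = "m3", d = "m", L = "m",
    Kwu = "-", hsg = "m", mu = "Pa s", S = "mol m-3 s-1", u_sweat_n = "-",
    u_passive = "m s-1")
}
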
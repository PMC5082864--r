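# Physical transport parameters and the linearized oxygen-hemoglobin model.
#
# Internal unit system: micrometres, seconds, Pascals, grams. Dissolved
# oxygen concentrations are stored in g/um^3 (2.24 g/m^3 = 2.24e-18 g/um^3);
# oxygen transfer rates are reported in ug/s.

#' Molar mass of molecular oxygen (g/mol), used for mol/m3 conversions
#' @noRd
.O2_MOLAR_MASS <- 32

#' Transport parameters for capillary oxygen transfer
#'
#' Bundles the physical constants governing oxygen transport in a
#' feto-placental capillary: the diffusion coefficient of oxygen in plasma
#' `D`, the plasma dynamic viscosity `mu`, the dissolved-oxygen
#' concentration of maternal blood in the intervillous space `c_mat`, the
#' hemoglobin advection-enhancement factor `B`, and the slope `K` of the
#' linearized fetal oxygen-hemoglobin dissociation curve.
#'
#' Advection enhancement arises because oxygen bound to fetal hemoglobin is
#' carried with the flow but only dissolved oxygen diffuses. With the
#' dissociation curve linearized through the origin (saturation S = K * P_O2),
#' the bound concentration is proportional to the dissolved one and the
#' advective term of the transport equation is amplified by the constant
#' factor `B = 1 + c_max * K * k_hn / rho_bl`. The defaults `B = 141` and
#' `K = 0.019` per mmHg correspond to fetal blood exposed to partial
#' pressures between 0 and 60 mmHg.
#'
#' @param D Oxygen diffusion coefficient in plasma (um^2/s).
#' @param mu Dynamic viscosity of plasma (Pa s).
#' @param c_mat_mol_per_m3 Maternal dissolved-oxygen concentration in mol/m^3
#'   (converted with molar mass 32 g/mol). Default 0.07 mol/m^3, i.e.
#'   2.24 g/m^3, corresponding to about 52.5 mmHg.
#' @param c_mat_g_per_m3 Alternative specification in g/m^3; overrides
#'   `c_mat_mol_per_m3` when given.
#' @param B Advection-enhancement factor (dimensionless, >= 1). If all of
#'   `c_max`, `K`, `k_hn`, `rho_bl` are supplied, `B` may be omitted and is
#'   then computed from them; if both are given they must agree to within
#'   relative 1e-12.
#' @param K Slope of the linearized dissociation curve (mmHg^-1).
#' @param c_max Oxygen content of fetal blood at full hemoglobin saturation
#'   (same units as `rho_bl` times mmHg/k_hn; only the ratio enters `B`).
#' @param k_hn Henry's law coefficient relating dissolved concentration to
#'   partial pressure, P_O2 = k_hn * c / rho_bl (mmHg).
#' @param rho_bl Density of blood (units consistent with `c_max`/`k_hn`).
#' @param saturation_law Optional function `P_O2 (mmHg) -> S in [0, 1]` used
#'   by the nonlinear transport mode; must be nondecreasing on [0, 60] mmHg
#'   with S(0) = 0. See [hill_saturation()] for a documented example.
#' @return An object of class `transport_params`: a list with elements
#'   `D`, `mu`, `c_mat` (g/um^3), `B`, `K`, and the optional constituents.
#' @examples
#' tp <- transport_params()
#' tp$B          # 141
#' tp$c_mat      # 2.24e-18 g/um^3
#' @export
transport_params <- function(D = 1.7e3, mu = 1e-3,
                             c_mat_mol_per_m3 = 0.07,
                             c_mat_g_per_m3 = NULL,
                             B = 141, K = 0.019,
                             c_max = NULL, k_hn = NULL, rho_bl = NULL,
                             saturation_law = NULL) {
  if (!is.null(c_mat_g_per_m3)) {
    c_mat_g_m3 <- c_mat_g_per_m3
  } else {
    c_mat_g_m3 <- c_mat_mol_per_m3 * .O2_MOLAR_MASS
  }
  c_mat <- c_mat_g_m3 * 1e-18  # g/m^3 -> g/um^3

  if (!is.numeric(D) || length(D) != 1L || D <= 0) stop("D must be a positive scalar")
  if (!is.numeric(mu) || length(mu) != 1L || mu <= 0) stop("mu must be a positive scalar")
  if (c_mat < 0) stop("c_mat must be nonnegative")

  have_constituents <- !is.null(c_max) && !is.null(k_hn) && !is.null(rho_bl)
  if (have_constituents) {
    B_from <- advection_enhancement(c_max, K, k_hn, rho_bl)
    if (is.null(B)) {
      B <- B_from
    } else if (abs(B - B_from) > 1e-12 * max(1, abs(B))) {
      stop(sprintf(
        "B = %.15g inconsistent with constituents (1 + c_max*K*k_hn/rho_bl = %.15g)",
        B, B_from
      ))
    }
  }
  if (is.null(B)) stop("B must be given, or computable from c_max, K, k_hn, rho_bl")
  if (B < 1) stop("B must be >= 1")
  if (K < 0) stop("K must be nonnegative")

  if (!is.null(saturation_law)) {
    stopifnot(is.function(saturation_law))
    p <- seq(0, 60, length.out = 121)
    s <- vapply(p, saturation_law, numeric(1))
    if (abs(s[1]) > 1e-9) stop("saturation_law must satisfy S(0) = 0 (within 1e-9)")
    if (any(diff(s) < -1e-12)) stop("saturation_law must be nondecreasing on [0, 60] mmHg")
  }

  structure(
    list(D = D, mu = mu, c_mat = c_mat, B = B, K = K,
         c_max = c_max, k_hn = k_hn, rho_bl = rho_bl,
         saturation_law = saturation_law),
    class = "transport_params"
  )
}

#' @export
print.transport_params <- function(x, ...) {
  cat("Transport parameters (um, s, Pa, g internal units)\n")
  cat(sprintf("  D      %.4g um^2/s\n", x$D))
  cat(sprintf("  mu     %.4g Pa s\n", x$mu))
  cat(sprintf("  c_mat  %.4g g/um^3  (%.4g g/m^3)\n", x$c_mat, x$c_mat * 1e18))
  cat(sprintf("  B      %.4g\n", x$B))
  cat(sprintf("  K      %.4g mmHg^-1\n", x$K))
  if (!is.null(x$saturation_law)) cat("  nonlinear saturation law attached\n")
  invisible(x)
}

#' Linearize an oxygen-hemoglobin dissociation curve through the origin
#'
#' Least-squares fit of `S = K * P_O2` to sampled saturation values,
#' constrained to pass through the origin, over partial pressures up to
#' `p_max` (the highest partial pressure fetal blood is expected to see;
#' 60 mmHg by default). The constrained fit has the closed form
#' `K = sum(P * S) / sum(P^2)` over the retained samples.
#'
#' @param p Partial pressures of oxygen (mmHg).
#' @param s Saturations in `[0, 1]` at those pressures.
#' @param p_max Upper end of the fitting window (mmHg).
#' @return The fitted slope `K` (mmHg^-1).
#' @examples
#' linearize_dissociation(c(10, 20, 30), 0.02 * c(10, 20, 30))  # exactly 0.02
#' @export
linearize_dissociation <- function(p, s, p_max = 60) {
  if (length(p) != length(s)) stop("p and s must have equal length")
  if (!is.numeric(p_max) || p_max <= 0) stop("p_max must be positive")
  keep <- is.finite(p) & is.finite(s) & p <= p_max
  p <- p[keep]; s <- s[keep]
  if (length(p) == 0L) stop("degenerate fit: no samples with P <= p_max")
  sp2 <- sum(p^2)
  if (sp2 == 0) stop("degenerate fit: all sampled partial pressures are zero")
  sum(p * s) / sp2
}

#' Hemoglobin advection-enhancement factor from its constituents
#'
#' `B = 1 + c_max * K * k_hn / rho_bl`: the factor by which oxygen binding
#' to fetal hemoglobin amplifies advective transport relative to dissolved
#' oxygen alone, under the linearized dissociation curve with slope `K`.
#'
#' @param c_max Oxygen content of blood at full saturation.
#' @param K Linearized dissociation slope (mmHg^-1), `K >= 0`.
#' @param k_hn Henry's law coefficient (mmHg).
#' @param rho_bl Density of blood.
#' @return Dimensionless `B >= 1`.
#' @examples
#' advection_enhancement(2, 3, 5, 10)  # 4
#' @export
advection_enhancement <- function(c_max, K, k_hn, rho_bl) {
  if (any(c(c_max, k_hn) <= 0)) stop("c_max and k_hn must be positive")
  if (rho_bl <= 0) stop("rho_bl must be positive")
  if (K < 0) stop("K must be nonnegative")
  1 + c_max * K * k_hn / rho_bl
}

#' Effective Peclet number of hemoglobin-enhanced oxygen transport
#'
#' `Pe_eff = B * u0 * R0 / D`: the ratio of (hemoglobin-enhanced) advective
#' to diffusive oxygen transport in a capillary of radius `R0` with
#' characteristic flow speed `u0`.
#'
#' @param params A [transport_params()] object.
#' @param u0 Characteristic flow speed (um/s), `>= 0`.
#' @param R0 Capillary radius (um), `> 0`.
#' @return Dimensionless effective Peclet number.
#' @examples
#' effective_peclet(transport_params(), u0 = 300, R0 = 4.7)  # about 117
#' @export
effective_peclet <- function(params, u0, R0) {
  stopifnot(inherits(params, "transport_params"))
  if (u0 < 0) stop("u0 must be nonnegative")
  if (R0 <= 0) stop("R0 must be positive")
  params$B * u0 * R0 / params$D
}

#' Example Hill-type saturation law
#'
#' Returns a Hill curve `S(P) = P^n / (P50^n + P^n)` suitable as the
#' `saturation_law` of [transport_params()] for nonlinear transport runs.
#' This is a generic sigmoidal stand-in for a measured fetal dissociation
#' curve, not a fitted physiological law.
#'
#' @param p50 Half-saturation partial pressure (mmHg).
#' @param n Hill exponent.
#' @return A function of `P_O2` (mmHg) returning saturation in `[0, 1)`.
#' @examples
#' S <- hill_saturation(p50 = 20, n = 2.5)
#' S(20)  # 0.5
#' @export
hill_saturation <- function(p50 = 20, n = 2.5) {
  force(p50); force(n)
  function(p) ifelse(p <= 0, 0, p^n / (p50^n + p^n))
}

#' Read transport parameters from a JSON config file
#'
#' Flat key-value JSON with keys `D_um2_per_s`, `mu_Pa_s`, one of
#' `c_mat_mol_per_m3` / `c_mat_g_per_m3`, `B`, `K_per_mmHg`. Missing keys
#' fall back to the package defaults.
#'
#' @param path Path to a UTF-8 JSON file.
#' @return A [transport_params()] object.
#' @export
read_transport_config <- function(path) {
  cfg <- jsonlite::read_json(path, simplifyVector = TRUE)
  args <- list()
  if (!is.null(cfg$D_um2_per_s)) args$D <- cfg$D_um2_per_s
  if (!is.null(cfg$mu_Pa_s)) args$mu <- cfg$mu_Pa_s
  if (!is.null(cfg$c_mat_g_per_m3)) {
    args$c_mat_g_per_m3 <- cfg$c_mat_g_per_m3
  } else if (!is.null(cfg$c_mat_mol_per_m3)) {
    args$c_mat_mol_per_m3 <- cfg$c_mat_mol_per_m3
  }
  if (!is.null(cfg$B)) args$B <- cfg$B
  if (!is.null(cfg$K_per_mmHg)) args$K <- cfg$K_per_mmHg
  do.call(transport_params, args)
}

#' Write transport parameters to a JSON config file
#'
#' @param params A [transport_params()] object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_transport_config <- function(params, path) {
  stopifnot(inherits(params, "transport_params"))
  jsonlite::write_json(
    list(D_um2_per_s = params$D, mu_Pa_s = params$mu,
         c_mat_g_per_m3 = params$c_mat * 1e18,
         B = params$B, K_per_mmHg = params$K),
    path, auto_unbox = TRUE, digits = NA
  )
  invisible(path)
}
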
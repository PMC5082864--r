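# Closed-form reduced-order model of capillary oxygen transfer: Poiseuille
# resistance, the Graetz-Leveque and equilibrated flow-limited scalings, the
# diffusion-limited annular bound, a regression equation bridging the
# regimes, and a villous-volume correction.
#
# All oxygen transfer rates N are returned in ug/s; lengths in um,
# pressures in Pa, resistances in Pa s/um^3.

.G_PER_S_TO_UG_PER_S <- 1e6

#' Leveque prefactor for developed tube flow
#'
#' The constant `alpha = (12 pi^2)^(1/3) / Gamma(4/3)` (about 5.5) arising
#' from the similarity solution of the thin concentration boundary layer at
#' the wall of a tube carrying developed Poiseuille flow at high Peclet
#' number.
#'
#' @return The dimensionless prefactor.
#' @examples
#' alpha_leveque()  # 5.50...
#' @export
alpha_leveque <- function() {
  (12 * pi^2)^(1 / 3) / gamma(4 / 3)
}

#' Poiseuille resistance of a straight capillary
#'
#' `R = 8 mu L / (pi R0^4)` for fully developed flow.
#'
#' @param mu Dynamic viscosity (Pa s).
#' @param L Capillary length (um).
#' @param R0 Capillary radius (um).
#' @return Vascular resistance (Pa s/um^3).
#' @export
poiseuille_resistance <- function(mu, L, R0) {
  if (any(c(mu, L) <= 0)) stop("mu and L must be positive")
  if (R0 <= 0) stop("R0 must be positive")
  8 * mu * L / (pi * R0^4)
}

#' Equivalent cylindrical radius of a capillary
#'
#' Radius of the cylinder with the capillary's volume and total length:
#' `R0 = sqrt(V / (pi L))`.
#'
#' @param V_cap Capillary volume (um^3).
#' @param L Total capillary length (um).
#' @return Equivalent radius (um).
#' @export
equivalent_radius <- function(V_cap, L) {
  if (any(c(V_cap, L) <= 0)) stop("V_cap and L must be positive")
  sqrt(V_cap / (pi * L))
}

#' Leveque (boundary-layer) flow-limited transfer scaling
#'
#' High-Peclet transfer through a thin wall boundary layer:
#' `N_flow,1 = alpha * c_mat * (D^2 B dP L^2 / R)^(1/3)` with
#' `alpha = (12 pi^2)^(1/3)/Gamma(4/3)`. Valid for short capillaries where
#' oxygen has not diffused to the centreline by the outlet.
#'
#' @param params A [transport_params()] object.
#' @param L Capillary length (um).
#' @param resistance Vascular resistance (Pa s/um^3).
#' @param dP Pressure drop (Pa), `>= 0`.
#' @return Oxygen transfer rate (ug/s).
#' @export
leveque_transfer <- function(params, L, resistance, dP) {
  stopifnot(inherits(params, "transport_params"))
  if (any(c(L, resistance) <= 0)) stop("L and resistance must be positive")
  if (any(dP < 0)) stop("dP must be nonnegative")
  alpha_leveque() * params$c_mat *
    (params$D^2 * params$B * dP * L^2 / resistance)^(1 / 3) *
    .G_PER_S_TO_UG_PER_S
}

#' Equilibrated flow-limited transfer scaling
#'
#' Low-Peclet/long-tube limit in which the outflow is fully oxygenated and
#' transfer is set by how much blood flows through:
#' `N_flow,2 = c_mat B dP / R = c_mat B Q`.
#'
#' @inheritParams leveque_transfer
#' @return Oxygen transfer rate (ug/s).
#' @export
equilibrated_transfer <- function(params, resistance, dP) {
  stopifnot(inherits(params, "transport_params"))
  if (resistance <= 0) stop("resistance must be positive")
  if (any(dP < 0)) stop("dP must be nonnegative")
  params$c_mat * params$B * dP / resistance * .G_PER_S_TO_UG_PER_S
}

#' Diffusion-limited upper bound from the concentric-annulus model
#'
#' Transfer when the capillary surface is a perfect oxygen sink and
#' diffusion through the villous tissue annulus limits supply. Modelling
#' the villous branch as a concentric cylinder of radius `R0 + d` around a
#' capillary of radius `R0` and surface area `A` gives
#' `N_max = D A c_mat / (R0 * ln(1 + d/R0))`.
#'
#' @param params A [transport_params()] object.
#' @param A Capillary surface area (um^2).
#' @param R0 Capillary radius (um).
#' @param d Mean villous distance from the capillary surface (um).
#' @return Upper bound on the oxygen transfer rate (ug/s).
#' @export
annular_diffusion_bound <- function(params, A, R0, d) {
  stopifnot(inherits(params, "transport_params"))
  if (any(c(A, R0) <= 0)) stop("A and R0 must be positive")
  if (d <= 0) {
    stop("d = 0: the capillary touches the villous surface and the annular bound diverges")
  }
  params$D * A * params$c_mat / (R0 * log(1 + d / R0)) * .G_PER_S_TO_UG_PER_S
}

#' Regression equation bridging the two flow-limited regimes
#'
#' `N_flow = K1 K2 dP / (K2 + K1 dP^(2/3))` with `K1 = c_mat B / R`
#' (equilibrated slope) and `K2 = alpha c_mat (D^2 B L^2 / R)^(1/3)`
#' (Leveque coefficient). The equation reduces to the equilibrated scaling
#' as `dP -> 0` and to the Leveque scaling as `dP -> Inf`.
#'
#' @inheritParams leveque_transfer
#' @return A list with `N_flow` (ug/s), `K1` (ug/s per Pa) and `K2`
#'   (ug/s per Pa^(1/3)).
#' @export
regression_flow <- function(params, L, resistance, dP) {
  stopifnot(inherits(params, "transport_params"))
  if (any(c(L, resistance) <= 0)) stop("L and resistance must be positive")
  if (any(dP < 0)) stop("dP must be nonnegative")
  K1 <- params$c_mat * params$B / resistance * .G_PER_S_TO_UG_PER_S
  K2 <- alpha_leveque() * params$c_mat *
    (params$D^2 * params$B * L^2 / resistance)^(1 / 3) * .G_PER_S_TO_UG_PER_S
  N <- ifelse(dP == 0, 0, K1 * K2 * dP / (K2 + K1 * dP^(2 / 3)))
  list(N_flow = N, K1 = K1, K2 = K2)
}

#' Villous-volume correction to the flow-limited transfer
#'
#' Accounts for the drop in oxygen concentration across the villous tissue:
#' with the annular bound `N_max`, the corrected transfer is
#' `N = N_flow / (1 + N_flow/N_max)` and the concentration at the capillary
#' surface is `c_inner = c_mat (1 - N/N_max)`.
#'
#' @param N_flow Flow-limited transfer with oxygen supplied at the capillary
#'   surface (ug/s), `>= 0`.
#' @param N_max Diffusion-limited bound (ug/s), `> 0`; either the closed-form
#'   annular value or an externally computed numerical bound.
#' @return A list with `N` (ug/s) and `c_inner_fraction = c_inner/c_mat`.
#' @export
villous_corrected_transfer <- function(N_flow, N_max) {
  if (any(N_flow < 0)) stop("N_flow must be nonnegative")
  if (any(N_max <= 0)) stop("N_max must be positive")
  N <- N_flow / (1 + N_flow / N_max)
  list(N = N, c_inner_fraction = 1 - N / N_max)
}

#' Classify the oxygen-transfer regime of a capillary
#'
#' Operationalizes the regime map: the equilibrated scaling applies when
#' `Pe_eff` is much smaller than `L_path R0/(d+R0)^2`, the Leveque scaling
#' when it is much larger (and the flow-limited transfer stays well below
#' the diffusion bound), and the diffusion-limited regime when
#' `N_flow >> N_max`. "Much" is a configurable factor (default 10);
#' borderline cases report `"crossover"`.
#'
#' @param params A [transport_params()] object.
#' @param u0 Characteristic flow speed (um/s).
#' @param R0 Capillary radius (um).
#' @param d Villous distance (um).
#' @param L_path Longest inflow-to-outflow path length (um).
#' @param N_flow Flow-limited transfer (ug/s).
#' @param N_max Diffusion-limited bound (ug/s).
#' @param threshold Separation factor `>= 1` interpreting the strong
#'   inequalities of the regime map.
#' @return One of `"flow_limited_equilibrated"`, `"flow_limited_leveque"`,
#'   `"diffusion_limited"`, `"crossover"`.
#' @export
classify_regime <- function(params, u0, R0, d, L_path, N_flow, N_max,
                            threshold = 10) {
  if (threshold < 1) stop("threshold must be >= 1")
  pe <- effective_peclet(params, u0, R0)
  ratio <- L_path * R0 / (d + R0)^2
  if (N_flow >= threshold * N_max) return("diffusion_limited")
  if (pe * threshold <= ratio) return("flow_limited_equilibrated")
  if (pe >= threshold * ratio && N_flow * threshold <= N_max) {
    return("flow_limited_leveque")
  }
  "crossover"
}

#' Sensitivity of oxygen transfer to geometric rescaling
#'
#' Multiplier applied to the transfer rate `N` when all length scales are
#' expanded by a factor `k` (`mode = "uniform"`) or the radius alone is
#' expanded (`mode = "radius_only"`), in the equilibrated (`"low_Pe"`) or
#' Leveque (`"high_Pe"`) regime. The exponents follow from the two scalings
#' combined with the Poiseuille resistance `R ~ L/R0^4`: uniform expansion
#' gives `k^3` (low Pe) or `k^(5/3)` (high Pe); radius-only gives `k^4` or
#' `k^(4/3)`.
#'
#' @param k Expansion factor, `> 0`.
#' @param mode `"uniform"` or `"radius_only"`.
#' @param regime `"low_Pe"` or `"high_Pe"`.
#' @return The multiplier on `N`.
#' @examples
#' sensitivity_factor(1.1, "uniform", "low_Pe")   # 1.331 (a 33% increase)
#' sensitivity_factor(1.1, "uniform", "high_Pe")  # about 1.17
#' @export
sensitivity_factor <- function(k, mode = c("uniform", "radius_only"),
                               regime = c("low_Pe", "high_Pe")) {
  if (any(k <= 0)) stop("k must be positive")
  mode <- match.arg(mode)
  regime <- match.arg(regime)
  expo <- switch(mode,
    uniform = if (regime == "low_Pe") 3 else 5 / 3,
    radius_only = if (regime == "low_Pe") 4 else 4 / 3
  )
  k^expo
}
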
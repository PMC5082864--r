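# Deterministic generators for test inputs: synthetic radius profiles,
# canonical geometries, the annulus oracle case, and the packaged
# morphometry of the three imaged terminal-villus capillaries.

#' Synthetic radius-vs-arclength profile of a dilated capillary
#'
#' Samples the one-degree-of-freedom cosine bump at spacing `ds` and
#' optionally adds seeded Gaussian radius noise (emulating the
#' voxel-quantization scatter of skeleton radius estimates). Radii are
#' floored at 0.1 um. Bit-reproducible given the same arguments and seed.
#'
#' @param R0 Undilated radius (um).
#' @param R_max Maximum radius (um).
#' @param lam Dilation length (um), centred in the branch.
#' @param L Branch length (um), `>= lam`.
#' @param ds Sample spacing (um).
#' @param noise_sigma Gaussian radius noise standard deviation (um).
#' @param seed RNG seed; mandatory when `noise_sigma > 0`.
#' @return A profile `data.frame` (columns `s`, `r`).
#' @export
make_bump_profile <- function(R0, R_max, lam, L, ds = 0.5,
                              noise_sigma = 0, seed = NULL) {
  if (ds <= 0) stop("ds must be positive")
  if (lam > L) stop("lam must not exceed L")
  if (noise_sigma > 0 && is.null(seed)) {
    stop("seed is mandatory when noise_sigma > 0")
  }
  shape <- bump_shape(R0, R_max, lam, L)
  s <- seq(0, L, by = ds)
  r <- radius_profile(shape, s)
  if (noise_sigma > 0) {
    r <- .with_seed(seed, r + stats::rnorm(length(r), sd = noise_sigma))
  }
  data.frame(s = s, r = pmax(r, 0.1))
}

#' Morphometry of the three imaged terminal-villus capillaries
#'
#' Geometric and computed properties of three confocal-microscopy-derived
#' villous branches, as a `capillary_summary` table: total capillary
#' length, longest inflow-to-outflow path, capillary volume and surface
#' area (from the villous totals and the capillary fractions), mean
#' villous distance, measured vascular resistance and the numerically
#' computed diffusion-limited bound `N_max`. Use [table3_raw()] for the
#' underlying printed quantities.
#'
#' @return A `capillary_summary` data frame with three rows.
#' @examples
#' fx <- table3_fixture()
#' fx$L                       # 185 164 92
#' fx$L^2 / fx$R_resistance   # about 5.9e7, 6.7e7, 2.8e7
#' @export
table3_fixture <- function() {
  raw <- table3_raw()
  out <- do.call(rbind, lapply(seq_len(nrow(raw)), function(i) {
    x <- raw[i, ]
    capillary_summary(
      L = x$L, d = x$d, A = x$villous_area * x$cap_area_fraction,
      L_path = x$L_path, V_cap = x$villous_volume * x$cap_volume_fraction,
      R_resistance = x$R_resistance, N_max_numeric = x$N_max_numeric,
      label = x$label
    )
  }))
  class(out) <- c("capillary_summary", "data.frame")
  out
}

#' Printed morphometric and computed quantities of the three images
#'
#' @return A `data.frame` with, per branch: villous volume (um^3) and
#'   surface area (um^2), capillary volume/area fractions, total capillary
#'   length `L` and longest path `L_path` (um), mean villous distance `d`
#'   (um), measured vascular resistance (Pa s/um^3), the `L^2/R` scaling
#'   ratio (um^5/Pa s), maximum velocity at 0.5 Pa (um/s), the numerically
#'   computed diffusion-limited bound and its annular closed-form
#'   prediction (ug/s), and the transfer ratios `N/N_flow` at 0.5 and 20
#'   Pa (fractions).
#' @export
table3_raw <- function() {
  data.frame(
    label = c("Image 1", "Image 2", "Image 3"),
    villous_volume = c(6.88e4, 5.62e4, 2.54e4),
    villous_area = c(8.01e3, 7.55e3, 3.96e3),
    cap_volume_fraction = c(0.185, 0.340, 0.255),
    cap_area_fraction = c(0.680, 0.862, 0.674),
    L = c(185, 164, 92),
    L_path = c(147, 164, 80),
    d = c(51, 15, 22),
    u_max_0.5Pa = c(45, 38, 53),
    R_resistance = c(5.8e-4, 4.0e-4, 3.0e-4),
    L2_over_R = c(5.9e7, 6.7e7, 2.8e7),
    N_max_numeric = c(3.2e-6, 6.6e-6, 2.7e-6),
    N_max_annular = c(1.8e-6, 3.3e-6, 1.2e-6),
    N_ratio_0.5Pa = c(0.83, 0.90, 0.84),
    N_ratio_20Pa = c(0.28, 0.39, 0.26),
    stringsAsFactors = FALSE
  )
}

#' Concentric-annulus oracle case
#'
#' Returns the geometry of a capillary of radius `R0` inside an oxygenated
#' villous cylinder of radius `R0 + d`, together with a function giving
#' the closed-form diffusion-limited transfer for any transport
#' parameters: `N_max = 2 pi L D c_mat / ln(1 + d/R0)`.
#'
#' @param R0 Inner (capillary) radius (um).
#' @param d Annulus thickness (um).
#' @param L Axial length (um).
#' @return A list with `R0`, `d`, `L`, `A_inner` and `N_analytic(params)`.
#' @export
make_annulus_case <- function(R0, d, L) {
  if (any(c(R0, d, L) <= 0)) stop("R0, d, L must be positive")
  list(
    R0 = R0, d = d, L = L, A_inner = 2 * pi * R0 * L,
    N_analytic = function(params) {
      annular_diffusion_bound(params, A = 2 * pi * R0 * L, R0 = R0, d = d)
    }
  )
}
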
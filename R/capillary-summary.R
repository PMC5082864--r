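# Capillary geometry summaries and the per-capillary transfer prediction
# pipeline built on the reduced-order model.

#' Geometric summary of a capillary branch
#'
#' One row of capillary morphometry: total length, longest
#' inflow-to-outflow path, volume or radius, villous distance, surface
#' area and (optionally) measured vascular resistance. At least one of
#' `V_cap` and `R0` must be given; when both are present `R0` wins for the
#' transfer formulas. A missing `R_resistance` is filled by the Poiseuille
#' value when predictions are computed.
#'
#' @param L Total capillary length (um).
#' @param d Mean villous distance from the capillary surface (um).
#' @param A Capillary surface area (um^2).
#' @param L_path Longest inflow-to-outflow path (um); defaults to `L`.
#' @param V_cap Capillary volume (um^3), optional.
#' @param R0 Capillary radius (um), optional.
#' @param R_resistance Vascular resistance (Pa s/um^3), optional.
#' @param N_max_numeric Externally computed diffusion-limited bound (ug/s),
#'   optional; used instead of the closed-form annular bound when present.
#' @param label Free-text identifier.
#' @return A one-row `data.frame` of class `capillary_summary`.
#' @export
capillary_summary <- function(L, d, A, L_path = L, V_cap = NA_real_,
                              R0 = NA_real_, R_resistance = NA_real_,
                              N_max_numeric = NA_real_, label = "") {
  if (any(c(L, d, A, L_path) <= 0)) stop("L, d, A and L_path must be positive")
  if (is.na(V_cap) && is.na(R0)) stop("at least one of V_cap and R0 is required")
  if (!is.na(V_cap) && V_cap <= 0) stop("V_cap must be positive")
  if (!is.na(R0) && R0 <= 0) stop("R0 must be positive")
  if (!is.na(R_resistance) && R_resistance <= 0) stop("R_resistance must be positive")
  out <- data.frame(
    label = label, L = L, L_path = L_path, V_cap = V_cap, R0 = R0,
    d = d, A = A, R_resistance = R_resistance, N_max_numeric = N_max_numeric,
    stringsAsFactors = FALSE
  )
  class(out) <- c("capillary_summary", "data.frame")
  out
}

#' Read capillary summaries from a CSV file
#'
#' Expects a header row with the `capillary_summary` field names
#' (`label, L, L_path, V_cap, R0, d, A, R_resistance, N_max_numeric`);
#' missing optional columns are filled with `NA`.
#'
#' @param path CSV path.
#' @return A `capillary_summary` data frame (one row per capillary).
#' @export
read_capillary_summaries <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  required <- c("L", "d", "A")
  missing <- setdiff(required, names(df))
  if (length(missing)) {
    stop("missing required columns: ", paste(missing, collapse = ", "))
  }
  optional <- c(label = NA_character_, L_path = NA_real_, V_cap = NA_real_,
                R0 = NA_real_, R_resistance = NA_real_, N_max_numeric = NA_real_)
  for (nm in names(optional)) if (is.null(df[[nm]])) df[[nm]] <- optional[[nm]]
  num_cols <- c("L", "L_path", "V_cap", "R0", "d", "A", "R_resistance",
                "N_max_numeric")
  for (nm in num_cols) df[[nm]] <- as.numeric(df[[nm]])
  df$L_path <- ifelse(is.na(df$L_path), df$L, df$L_path)
  df <- df[c("label", "L", "L_path", "V_cap", "R0", "d", "A",
             "R_resistance", "N_max_numeric")]
  class(df) <- c("capillary_summary", "data.frame")
  df
}

#' Write capillary summaries to CSV
#'
#' @param summaries A `capillary_summary` data frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_capillary_summaries <- function(summaries, path) {
  utils::write.csv(as.data.frame(summaries), path, row.names = FALSE)
  invisible(path)
}

#' Predict oxygen transfer for capillary summaries over a pressure ladder
#'
#' Runs the full reduced-order pipeline for each capillary and each
#' pressure drop: fills the radius from the equivalent-cylinder relation
#' and the resistance from Poiseuille's law where not measured, evaluates
#' the Leveque and equilibrated scalings, the regression equation, the
#' diffusion-limited bound (closed-form annulus, or the supplied numerical
#' `N_max_numeric` when present), applies the villous correction, and
#' classifies the transfer regime. The characteristic speed used for the
#' Peclet number is the mean speed `Q/(pi R0^2)` through the equivalent
#' cylinder.
#'
#' @param summaries A `capillary_summary` data frame.
#' @param params A [transport_params()] object.
#' @param dP Vector of pressure drops (Pa).
#' @param threshold Regime-separation factor passed to [classify_regime()].
#' @return A `data.frame` of class `transfer_prediction` with one row per
#'   capillary x pressure drop: `N_flow_1`, `N_flow_2`, `N_flow_regression`,
#'   `N_max`, `N_corrected`, `c_inner_fraction`, `N_ratio`, `K1`, `K2`,
#'   `Pe_eff`, `regime`.
#' @examples
#' preds <- predict_transfer(table3_fixture(), transport_params(), dP = 0.5)
#' preds[, c("label", "N_max", "N_corrected", "regime")]
#' @export
predict_transfer <- function(summaries, params, dP, threshold = 10) {
  stopifnot(inherits(params, "transport_params"))
  df <- as.data.frame(summaries)
  rows <- vector("list", nrow(df) * length(dP))
  k <- 0L
  for (i in seq_len(nrow(df))) {
    row <- df[i, ]
    R0 <- if (!is.na(row$R0)) row$R0 else equivalent_radius(row$V_cap, row$L)
    resistance <- if (!is.na(row$R_resistance)) row$R_resistance else
      poiseuille_resistance(params$mu, row$L, R0)
    N_max <- if (!is.na(row$N_max_numeric)) row$N_max_numeric else
      annular_diffusion_bound(params, row$A, R0, row$d)
    L_path <- if (!is.na(row$L_path)) row$L_path else row$L
    for (p in dP) {
      k <- k + 1L
      n1 <- leveque_transfer(params, row$L, resistance, p)
      n2 <- equilibrated_transfer(params, resistance, p)
      reg <- regression_flow(params, row$L, resistance, p)
      corr <- villous_corrected_transfer(reg$N_flow, N_max)
      u0 <- p / resistance / (pi * R0^2)  # mean speed Q/(pi R0^2)
      regime <- classify_regime(params, u0, R0, row$d, L_path,
                                reg$N_flow, N_max, threshold)
      rows[[k]] <- data.frame(
        label = row$label, dP = p, R0 = R0, resistance = resistance,
        N_flow_1 = n1, N_flow_2 = n2, N_flow_regression = reg$N_flow,
        N_max = N_max, N_corrected = corr$N,
        c_inner_fraction = corr$c_inner_fraction,
        N_ratio = if (reg$N_flow > 0) corr$N / reg$N_flow else 1,
        K1 = reg$K1, K2 = reg$K2,
        Pe_eff = effective_peclet(params, u0, R0),
        regime = regime, stringsAsFactors = FALSE
      )
    }
  }
  out <- do.call(rbind, rows)
  class(out) <- c("transfer_prediction", "data.frame")
  out
}

#' Write transfer predictions as JSON records
#'
#' @param predictions A `transfer_prediction` data frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_predictions_json <- function(predictions, path) {
  jsonlite::write_json(as.data.frame(predictions), path,
                       dataframe = "rows", auto_unbox = TRUE, digits = NA)
  invisible(path)
}
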
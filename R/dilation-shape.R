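# Fourier-series parameterization of an axisymmetric capillary wall with a
# localized dilation. Inside the dilation window of length lam the radius is
#
#   R(zeta)/R0 = a0/2 + sum_k a_k cos(k pi zeta/lam)
#                     + sum_k b_k sin(k pi zeta/lam),   zeta in [0, lam],
#
# subject to the continuity/smoothness constraints
# R(0) = R(lam) = R0 and R'(0) = R'(lam) = 0; outside the window R = R0.

#' Constraint matrix of the wall series, in R0 units
#'
#' Rows: R(0)=1, R(lam)=1, R'(0)=0, R'(lam)=0 (derivative rows scaled by
#' lam/pi so entries are the integer mode numbers). Columns: a0, a1..an,
#' b1..bn.
#' @noRd
.shape_constraint_matrix <- function(n) {
  k <- seq_len(n)
  C <- matrix(0, 4, 2 * n + 1)
  C[1, ] <- c(0.5, rep(1, n), rep(0, n))
  C[2, ] <- c(0.5, (-1)^k, rep(0, n))
  C[3, ] <- c(0, rep(0, n), k)
  C[4, ] <- c(0, rep(0, n), (-1)^k * k)
  rownames(C) <- c("R(0)", "R(lam)", "R'(0)", "R'(lam)")
  colnames(C) <- c("a0", paste0("a", k), paste0("b", k))
  C
}

#' Indices zeroed by the symmetry rule
#' @noRd
.symmetry_zeros <- function(n, symmetric, symmetry_mode) {
  if (!symmetric) return(integer(0))
  k <- seq_len(n)
  if (symmetry_mode == "strict_parity") {
    # even-k cosines only: zero odd a_k and every b_k
    c(1L + k[k %% 2 == 1L], 1L + n + k)
  } else {
    # paper rule: zero a_k and b_k for odd k < n
    odd_lt_n <- k[k %% 2 == 1L & k < n]
    c(1L + odd_lt_n, 1L + n + odd_lt_n)
  }
}

#' Construct a dilated-capillary wall shape
#'
#' Builds a `dilation_shape` from explicit Fourier coefficients and
#' validates the continuity/smoothness constraints (residuals must be below
#' `1e-10` in units of `R0`) and the occlusion floor
#' `min R >= r_min_fraction * R0`. Most users will construct shapes through
#' [bump_shape()], [symmetric_bump_shape()] or [apply_constraints()], which
#' enforce the constraints by elimination.
#'
#' @param R0 Undilated radius (um).
#' @param lam Dilation length (um), `lam <= L`.
#' @param L Total capillary length (um).
#' @param a Cosine coefficients `a0..an` (dimensionless, in units of `R0`).
#' @param b Sine coefficients `b1..bn`.
#' @param z_start Axial position where the dilation starts (um); default
#'   centres the dilation.
#' @param symmetric Whether the shape is declared symmetric about the
#'   dilation midpoint.
#' @param symmetry_mode `"strict_parity"` (even-k cosines only; default) or
#'   `"paper_odd_zero"` (zero odd-k coefficients below the truncation
#'   order, which still admits midpoint-antisymmetric sine terms).
#' @param r_min_fraction Occlusion floor as a fraction of `R0`.
#' @return An object of class `dilation_shape`.
#' @export
dilation_shape <- function(R0, lam, L, a, b = numeric(length(a) - 1L),
                           z_start = (L - lam) / 2, symmetric = FALSE,
                           symmetry_mode = c("strict_parity", "paper_odd_zero"),
                           r_min_fraction = 0.2) {
  symmetry_mode <- match.arg(symmetry_mode)
  n <- length(a) - 1L
  if (n < 1L) stop("need truncation order n >= 1 (a must hold a0..an)")
  if (length(b) != n) stop("b must hold b1..bn")
  if (any(c(R0, lam, L) <= 0)) stop("R0, lam, L must be positive")
  if (lam > L + 1e-12) stop("lam must not exceed L")
  if (z_start < -1e-12 || z_start + lam > L + 1e-9) {
    stop("dilation window [z_start, z_start + lam] must lie inside [0, L]")
  }

  theta <- c(a, b)
  C <- .shape_constraint_matrix(n)
  res <- C %*% theta - c(1, 1, 0, 0)
  if (max(abs(res)) > 1e-10) {
    stop(sprintf("wall continuity/smoothness constraints violated (max residual %.3g R0 units)",
                 max(abs(res))))
  }
  if (symmetric) {
    zz <- .symmetry_zeros(n, TRUE, symmetry_mode)
    if (length(zz) && any(theta[zz] != 0)) {
      stop("coefficients zeroed by the symmetry rule must be exactly zero")
    }
  }

  shape <- structure(
    list(R0 = R0, lam = lam, L = L, z_start = z_start, n = n,
         a = as.numeric(a), b = as.numeric(b), symmetric = symmetric,
         symmetry_mode = symmetry_mode, r_min_fraction = r_min_fraction),
    class = "dilation_shape"
  )
  ex <- shape_extrema(shape)
  if (ex$R_min < r_min_fraction * R0 - 1e-9 * R0) {
    stop(sprintf("shape occludes the channel: min R = %.4g < %.4g um floor",
                 ex$R_min, r_min_fraction * R0))
  }
  shape
}

#' Evaluate the wall radius profile
#'
#' Returns `R(z)` in um: the truncated Fourier series inside the dilation
#' window (in the local coordinate `zeta = z - z_start`), and the undilated
#' radius `R0` outside it.
#'
#' @param shape A `dilation_shape`.
#' @param z Axial positions (um) in `[0, L]`; vectorized.
#' @return Radii (um) at `z`.
#' @export
radius_profile <- function(shape, z) {
  stopifnot(inherits(shape, "dilation_shape"))
  if (any(z < -1e-9) || any(z > shape$L + 1e-9)) stop("z must lie in [0, L]")
  r <- rep(shape$R0, length(z))
  zeta <- z - shape$z_start
  inside <- zeta >= 0 & zeta <= shape$lam
  if (any(inside)) {
    zi <- zeta[inside]
    val <- rep(shape$a[1] / 2, length(zi))
    for (k in seq_len(shape$n)) {
      arg <- k * pi * zi / shape$lam
      val <- val + shape$a[k + 1L] * cos(arg) + shape$b[k] * sin(arg)
    }
    r[inside] <- shape$R0 * val
  }
  r
}

#' Number of free parameters of a constrained wall series
#'
#' Total coefficients minus symmetry zeros minus the rank of the
#' continuity/smoothness constraint system on the remaining coefficients.
#'
#' @param n Truncation order.
#' @inheritParams dilation_shape
#' @return Integer count of free parameters.
#' @export
n_free_params <- function(n, symmetric = FALSE,
                          symmetry_mode = c("strict_parity", "paper_odd_zero")) {
  symmetry_mode <- match.arg(symmetry_mode)
  C <- .shape_constraint_matrix(n)
  zz <- .symmetry_zeros(n, symmetric, symmetry_mode)
  keep <- setdiff(seq_len(2L * n + 1L), zz)
  r <- qr(C[, keep, drop = FALSE])$rank
  length(keep) - r
}

#' Build a feasible shape from free parameters by constraint elimination
#'
#' Distributes `free_params` over the non-eliminated Fourier coefficients
#' (cosines in ascending order, then sines) and solves the four linear
#' continuity/smoothness constraints for the eliminated coefficients
#' (by default `a0, a1, b1, b2`, extended or reduced as the symmetry rule
#' and the constraint rank require). Elimination is exact, so every
#' returned shape satisfies the constraints to round-off.
#'
#' @param free_params Numeric vector of length [n_free_params()].
#' @param n Truncation order, `n >= 2`.
#' @inheritParams dilation_shape
#' @return A `dilation_shape`.
#' @export
apply_constraints <- function(free_params, n, R0, lam, L,
                              z_start = (L - lam) / 2, symmetric = FALSE,
                              symmetry_mode = c("strict_parity", "paper_odd_zero"),
                              r_min_fraction = 0.2) {
  symmetry_mode <- match.arg(symmetry_mode)
  if (n < 2L) stop("need n >= 2 so the elimination set exists")
  ntot <- 2L * n + 1L
  C <- .shape_constraint_matrix(n)
  zz <- .symmetry_zeros(n, symmetric, symmetry_mode)
  keep <- setdiff(seq_len(ntot), zz)

  rank_C <- qr(C[, keep, drop = FALSE])$rank
  # candidate elimination order: a0, a1, b1, b2, then remaining low-order
  cand <- c(1L, 2L, n + 2L, n + 3L, setdiff(keep, c(1L, 2L, n + 2L, n + 3L)))
  cand <- cand[cand %in% keep]
  elim <- integer(0)
  for (j in cand) {
    if (length(elim) == rank_C) break
    trial <- c(elim, j)
    if (qr(C[, trial, drop = FALSE])$rank == length(trial)) elim <- trial
  }
  if (length(elim) < rank_C) {
    stop(sprintf("constraint matrix singular for elimination set {%s}",
                 paste(colnames(C)[cand[seq_len(min(4, length(cand)))]], collapse = ", ")))
  }
  free_idx <- setdiff(keep, elim)
  if (length(free_params) != length(free_idx)) {
    stop(sprintf("expected %d free parameters (n = %d%s), got %d",
                 length(free_idx), n,
                 if (symmetric) paste0(", symmetric/", symmetry_mode) else "",
                 length(free_params)))
  }

  theta <- numeric(ntot)
  theta[free_idx] <- free_params
  rhs <- c(1, 1, 0, 0) - C[, free_idx, drop = FALSE] %*% theta[free_idx]
  sol <- qr.solve(qr(C[, elim, drop = FALSE]), rhs)
  theta[elim] <- sol

  dilation_shape(R0 = R0, lam = lam, L = L,
                 a = theta[seq_len(n + 1L)], b = theta[(n + 2L):ntot],
                 z_start = z_start, symmetric = symmetric,
                 symmetry_mode = symmetry_mode,
                 r_min_fraction = r_min_fraction)
}

#' One-degree-of-freedom cosine bump
#'
#' The lowest-order symmetric series member satisfying the wall
#' constraints: `R(zeta)/R0 = 1 + (R_max/R0 - 1) * (1 - cos(2 pi zeta/lam))/2`,
#' i.e. a single even-k cosine bump whose maximum radius at the window
#' midpoint is `R_max`.
#'
#' @param R0 Undilated radius (um).
#' @param R_max Maximum radius at the dilation midpoint (um).
#' @param lam Dilation length (um).
#' @param L Capillary length (um).
#' @inheritParams dilation_shape
#' @return A `dilation_shape` with `n = 2`.
#' @examples
#' sh <- bump_shape(R0 = 4.7, R_max = 6.8, lam = 31, L = 76)
#' shape_extrema(sh)$R_max  # 6.8
#' @export
bump_shape <- function(R0, R_max, lam, L, z_start = (L - lam) / 2,
                       r_min_fraction = 0.2) {
  symmetric_bump_shape(R0 = R0, lam = lam, L = L,
                       amplitudes = (R_max / R0 - 1),
                       z_start = z_start, r_min_fraction = r_min_fraction)
}

#' Symmetric multi-mode bump from even-cosine amplitudes
#'
#' Builds the symmetric family used by the shape optimizer:
#' `R(zeta)/R0 = 1 + sum_m c_m * (1 - cos(2 pi m zeta/lam))/2`. Each basis
#' bump satisfies the wall constraints individually, so any combination
#' does; `m = 1` is the one-degree-of-freedom family and `m = 2` adds the
#' `k = 4` cosine harmonic.
#'
#' @param amplitudes Numeric vector `c_1, c_2, ...` (dimensionless; `c_m`
#'   is the peak contribution of mode `m` in units of `R0`).
#' @inheritParams dilation_shape
#' @return A `dilation_shape` with `n = 2 * length(amplitudes)`.
#' @export
symmetric_bump_shape <- function(R0, lam, L, amplitudes,
                                 z_start = (L - lam) / 2,
                                 r_min_fraction = 0.2) {
  m <- length(amplitudes)
  if (m < 1L) stop("need at least one amplitude")
  n <- max(2L, 2L * m)
  a <- numeric(n + 1L)
  a[1] <- 2 * (1 + sum(amplitudes) / 2)       # a0
  for (j in seq_len(m)) a[2L * j + 1L] <- -amplitudes[j] / 2
  dilation_shape(R0 = R0, lam = lam, L = L, a = a, b = numeric(n),
                 z_start = z_start, symmetric = TRUE,
                 symmetry_mode = "strict_parity",
                 r_min_fraction = r_min_fraction)
}

#' Global extrema of the wall radius over the dilation window
#'
#' Locates the minimum and maximum of `R(z)` on the dilation window by
#' dense sampling followed by local refinement (accuracy about
#' `1e-6 * R0`).
#'
#' @param shape A `dilation_shape`.
#' @return A list with `R_min`, `R_max` (um) and `z_at_max` (um, absolute
#'   axial position of the maximum).
#' @export
shape_extrema <- function(shape) {
  stopifnot(inherits(shape, "dilation_shape"))
  zs <- seq(shape$z_start, shape$z_start + shape$lam, length.out = 2001L)
  r <- radius_profile(shape, zs)
  f <- function(z) radius_profile(shape, z)
  refine <- function(idx, maximum) {
    lo <- zs[max(1L, idx - 1L)]; hi <- zs[min(length(zs), idx + 1L)]
    if (hi - lo < .Machine$double.eps) return(c(zs[idx], r[idx]))
    opt <- stats::optimize(f, c(lo, hi), maximum = maximum,
                           tol = 1e-8 * shape$lam)
    if (maximum) c(opt$maximum, opt$objective) else c(opt$minimum, opt$objective)
  }
  imax <- which.max(r); imin <- which.min(r)
  mx <- refine(imax, TRUE); mn <- refine(imin, FALSE)
  # endpoints are pinned to R0; dense samples include them
  list(R_min = min(mn[2], shape$R0), R_max = max(mx[2], shape$R0),
       z_at_max = mx[1])
}

#' @export
print.dilation_shape <- function(x, ...) {
  ex <- shape_extrema(x)
  cat(sprintf("Dilated capillary wall: L = %g um, window [%g, %g] um (lam = %g)\n",
              x$L, x$z_start, x$z_start + x$lam, x$lam))
  cat(sprintf("  R0 = %g um, R_min = %.4g, R_max = %.4g um (max at z = %.4g)\n",
              x$R0, ex$R_min, ex$R_max, ex$z_at_max))
  cat(sprintf("  Fourier order n = %d%s\n", x$n,
              if (x$symmetric) paste0(", symmetric (", x$symmetry_mode, ")") else ""))
  invisible(x)
}

#' @export
plot.dilation_shape <- function(x, n_points = 400, ...) {
  z <- seq(0, x$L, length.out = n_points)
  r <- radius_profile(x, z)
  graphics::plot(z, r, type = "l", xlab = "z (um)", ylab = "R(z) (um)",
                 ylim = c(0, max(r) * 1.1), ...)
  graphics::abline(h = x$R0, lty = 3, col = "grey40")
  invisible(x)
}

#' Serialize a shape to JSON
#'
#' Record fields: `R0_um, lambda_um, L_um, z_start_um, n, a, b, symmetric,
#' symmetry_mode`.
#'
#' @param shape A `dilation_shape`.
#' @param path Optional output path; when `NULL` the JSON string is returned.
#' @return `path` invisibly, or the JSON string.
#' @export
shape_to_json <- function(shape, path = NULL) {
  rec <- list(R0_um = shape$R0, lambda_um = shape$lam, L_um = shape$L,
              z_start_um = shape$z_start, n = shape$n,
              a = shape$a, b = shape$b, symmetric = shape$symmetric,
              symmetry_mode = shape$symmetry_mode,
              r_min_fraction = shape$r_min_fraction)
  if (is.null(path)) {
    as.character(jsonlite::toJSON(rec, auto_unbox = TRUE, digits = NA))
  } else {
    jsonlite::write_json(rec, path, auto_unbox = TRUE, digits = NA)
    invisible(path)
  }
}

#' Deserialize a shape from JSON
#'
#' @param path Path to a JSON file written by [shape_to_json()] (or a JSON
#'   string).
#' @return A `dilation_shape`.
#' @export
shape_from_json <- function(path) {
  rec <- jsonlite::fromJSON(path)
  dilation_shape(R0 = rec$R0_um, lam = rec$lambda_um, L = rec$L_um,
                 a = rec$a, b = rec$b, z_start = rec$z_start_um,
                 symmetric = isTRUE(rec$symmetric),
                 symmetry_mode = if (is.null(rec$symmetry_mode)) "strict_parity"
                                 else rec$symmetry_mode,
                 r_min_fraction = if (is.null(rec$r_min_fraction)) 0.2
                                  else rec$r_min_fraction)
}

#' Export a sampled wall profile as two-column CSV (`z_um, R_um`)
#'
#' @param shape A `dilation_shape`.
#' @param path Output path.
#' @param n_points Number of samples along `[0, L]`.
#' @return `path`, invisibly.
#' @export
export_shape_profile <- function(shape, path, n_points = 501L) {
  z <- seq(0, shape$L, length.out = n_points)
  utils::write.csv(data.frame(z_um = z, R_um = radius_profile(shape, z)),
                   path, row.names = FALSE)
  invisible(path)
}
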
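# Steady axisymmetric Stokes flow through the meshed capillary, driven by
# a normal-stress (pressure) difference between the inflow and outflow
# planes. Taylor-Hood P2/P1 discretization of the stress-divergence weak
# form with the r-weighted axisymmetric measure:
#
#   int 2 mu [e(u):e(v) + (u_r v_r)/r^2] r dA - int p div_axi(v) r dA
#     = int_Gamma (sigma.n).v r ds,
#   int q div_axi(u) r dA = 0,   div_axi(u) = du_r/dr + u_r/r + du_z/dz.
#
# On the inflow plane the normal stress is set to -dP and the tangential
# velocity to zero; on the outflow plane the normal stress is zero. No slip
# holds on the wall, and u_r = 0 on the axis. Because the inlet condition
# fixes the stress rather than a velocity profile, the computed resistance
# includes entrance effects.

#' Pressure drop giving a target centreline speed in an undilated capillary
#'
#' Inverts the Poiseuille centreline relation `u_c = dP R0^2 / (4 mu L)`:
#' returns `dP = 4 mu L u_c / R0^2`.
#'
#' @param R0 Capillary radius (um).
#' @param L Capillary length (um).
#' @param mu Dynamic viscosity (Pa s).
#' @param u_centreline Target centreline speed (um/s).
#' @return Pressure drop (Pa).
#' @examples
#' calibrate_pressure(4.7, 76, 1e-3, 300)  # about 4.13 Pa
#' @export
calibrate_pressure <- function(R0, L, mu, u_centreline = 300) {
  if (any(c(R0, L, mu) <= 0)) stop("R0, L, mu must be positive")
  if (u_centreline < 0) stop("u_centreline must be nonnegative")
  4 * mu * L * u_centreline / R0^2
}

#' Solve steady Stokes flow through the capillary
#'
#' @param mesh An `axisym_mesh` built by [build_mesh()].
#' @param mu Dynamic viscosity (Pa s).
#' @param dP Pressure drop between inflow and outflow planes (Pa).
#' @param reverse Drive the flow from the outflow plane instead (used for
#'   the Stokes-reversibility check).
#' @return An object of class `field_solution` with nodal velocities
#'   `ur`, `uz` (um/s), vertex pressures `p` (Pa), flow rate `Q` (um^3/s),
#'   `resistance = dP/Q` (Pa s/um^3), inflow/outflow rates, and the wall
#'   shear stress profile.
#' @export
solve_stokes <- function(mesh, mu, dP, reverse = FALSE) {
  stopifnot(inherits(mesh, "axisym_mesh"))
  if (mu <= 0 || dP <= 0) stop("mu and dP must be positive")

  nn <- mesh$nn; nv <- mesh$nv
  blocks <- .assemble_p2_blocks(mesh)
  pb <- .assemble_pressure_blocks(mesh)
  K1 <- blocks$K1; K2 <- blocks$K2; Krz <- blocks$Krz; M1r <- blocks$M1r

  A_rr <- mu * (2 * K1 + K2 + 2 * M1r)
  A_rz <- mu * Krz
  A_zz <- mu * (K1 + 2 * K2)

  A <- rbind(
    cbind(A_rr, A_rz, -Matrix::t(pb$Gr)),
    cbind(Matrix::t(A_rz), A_zz, -Matrix::t(pb$Gz)),
    cbind(-pb$Gr, -pb$Gz,
          Matrix::sparseMatrix(i = integer(0), j = integer(0), x = numeric(0),
                               dims = c(nv, nv)))
  )

  f <- numeric(2L * nn + nv)
  drive_edges <- if (reverse) mesh$edges_out else mesh$edges_in
  w_drive <- .edge_load_p2(mesh, drive_edges)
  # inlet (n = -e_z): (sigma.n).v = dP * v_z; outlet (n = +e_z): -dP * v_z
  sgn <- if (reverse) -1 else 1
  f[nn + seq_len(nn)] <- sgn * dP * w_drive

  # Dirichlet sets: no slip on the wall (both components); u_r = 0 on the
  # axis (or inner wall no slip for an annulus) and on the in/outflow planes
  fixed_r <- unique(c(mesh$nodes_wall, mesh$nodes_base,
                      mesh$nodes_in, mesh$nodes_out))
  fixed_z <- mesh$nodes_wall
  if (mesh$kind == "annulus") fixed_z <- unique(c(fixed_z, mesh$nodes_base))
  fixed <- c(fixed_r, nn + fixed_z)
  free <- setdiff(seq_len(2L * nn + nv), fixed)

  sol <- numeric(2L * nn + nv)
  Af <- A[free, free, drop = FALSE]
  sol[free] <- as.numeric(Matrix::solve(Af, f[free]))

  ur <- sol[seq_len(nn)]
  uz <- sol[nn + seq_len(nn)]
  p <- sol[2L * nn + seq_len(nv)]

  w_out <- .edge_load_p2(mesh, mesh$edges_out)
  w_in <- .edge_load_p2(mesh, mesh$edges_in)
  Q_out <- 2 * pi * sum(w_out * uz)
  Q_in <- 2 * pi * sum(w_in * uz)
  if (reverse) { tmp <- Q_out; Q_out <- -Q_in; Q_in <- -tmp }
  Q <- Q_out
  if (Q <= 0) warning("non-positive flow rate; check mesh and boundary tags")

  structure(
    list(mesh = mesh, mu = mu, dP = dP, reverse = reverse,
         ur = ur, uz = uz, p = p,
         Q = Q, Q_in = Q_in, resistance = dP / Q,
         mass_balance_error = abs(Q_in - Q_out) / abs(Q_out),
         wall_shear = wall_shear_stress(mesh, ur, uz, mu),
         c = NULL),
    class = "field_solution"
  )
}

#' Wall shear stress profile from a velocity field
#'
#' Evaluates `tau_w = mu * d(u_t)/dn` (tangential velocity gradient along
#' the inward wall normal) at the midpoint of every wall edge, from the P2
#' velocity gradient of the adjacent element.
#'
#' @param mesh An `axisym_mesh`.
#' @param ur,uz Nodal velocity components (um/s).
#' @param mu Dynamic viscosity (Pa s).
#' @return A `data.frame` with `z` (um, wall-edge midpoint) and `tau` (Pa).
#' @export
wall_shear_stress <- function(mesh, ur, uz, mu) {
  edges <- mesh$edges_wall
  elems <- mesh$wall_elem
  if (is.null(edges) || nrow(edges) == 0L) {
    return(data.frame(z = numeric(0), tau = numeric(0)))
  }
  geo <- .el_geometry(mesh$verts, mesh$tri)
  out_z <- numeric(nrow(edges)); out_tau <- numeric(nrow(edges))
  for (k in seq_len(nrow(edges))) {
    e <- elems[k]
    p1 <- mesh$nodes[edges[k, 1], ]; p2 <- mesh$nodes[edges[k, 2], ]
    pm <- mesh$nodes[edges[k, 3], ]
    tvec <- (p2 - p1) / sqrt(sum((p2 - p1)^2))
    nvec <- c(tvec[2], -tvec[1])           # rotate; orient outward (away from fluid)
    cen <- c(mean(geo$r1[e] + geo$r2[e] + geo$r3[e]) / 3,
             (geo$z1[e] + geo$z2[e] + geo$z3[e]) / 3)
    if (sum((pm - cen) * nvec) < 0) nvec <- -nvec
    # reference coordinates of the midpoint within element e
    J <- matrix(c(geo$r2[e] - geo$r1[e], geo$r3[e] - geo$r1[e],
                  geo$z2[e] - geo$z1[e], geo$z3[e] - geo$z1[e]),
                2, 2, byrow = TRUE)
    xy <- solve(J, pm - c(geo$r1[e], geo$z1[e]))
    lam <- matrix(c(1 - xy[1] - xy[2], xy[1], xy[2]), 1, 3)
    pbq <- .p2_basis(lam)
    gx <- pbq$dx[1, ]; gy <- pbq$dy[1, ]
    gr <- geo$a11[e] * gx + geo$a12[e] * gy
    gz <- geo$a21[e] * gx + geo$a22[e] * gy
    nodes_e <- mesh$tri6[e, ]
    dur <- c(sum(gr * ur[nodes_e]), sum(gz * ur[nodes_e]))
    duz <- c(sum(gr * uz[nodes_e]), sum(gz * uz[nodes_e]))
    # grad(u)[i, j] = d u_i / d x_j with x = (r, z)
    gradu <- rbind(dur, duz)
    ut_grad <- c(tvec[1] * gradu[1, 1] + tvec[2] * gradu[2, 1],
                 tvec[1] * gradu[1, 2] + tvec[2] * gradu[2, 2])
    # shear = mu * d(u_t)/dn along the inward normal (into the fluid)
    out_tau[k] <- mu * abs(sum(ut_grad * nvec))
    out_z[k] <- pm[2]
  }
  ord <- order(out_z)
  data.frame(z = out_z[ord], tau = out_tau[ord])
}

#' @export
print.field_solution <- function(x, ...) {
  cat("Axisymmetric field solution\n")
  cat(sprintf("  dP = %g Pa, Q = %.6g um^3/s, resistance = %.6g Pa s/um^3\n",
              x$dP, x$Q, x$resistance))
  cat(sprintf("  mass balance error %.3g\n", x$mass_balance_error))
  if (!is.null(x$c)) {
    cat(sprintf("  N = %.6g ug/s (flux balance error %.3g)\n",
                x$N, x$flux_balance_error))
  }
  invisible(x)
}

#' @export
summary.field_solution <- function(object, ...) {
  out <- list(
    dP = object$dP, Q = object$Q, resistance = object$resistance,
    mass_balance_error = object$mass_balance_error,
    u_max = max(sqrt(object$ur^2 + object$uz^2)),
    tau_range = range(object$wall_shear$tau)
  )
  if (!is.null(object$c)) {
    out$N <- object$N
    out$flux_balance_error <- object$flux_balance_error
    out$chat_range <- range(object$chat)
  }
  class(out) <- "summary.field_solution"
  out
}

#' @export
print.summary.field_solution <- function(x, ...) {
  for (nm in names(x)) {
    v <- x[[nm]]
    cat(sprintf("  %-20s %s\n", nm, paste(signif(v, 6), collapse = " .. ")))
  }
  invisible(x)
}

#' @export
plot.field_solution <- function(x, what = c("uz", "c", "p"), ...) {
  what <- match.arg(what)
  val <- switch(what, uz = x$uz, p = c(x$p, rep(NA, x$mesh$nn - x$mesh$nv)),
                c = if (is.null(x$c)) stop("no concentration field") else x$c)
  nodes <- x$mesh$nodes
  keep <- !is.na(val)
  cols <- grDevices::hcl.colors(64, "viridis")
  ci <- cols[cut(val[keep], 64, labels = FALSE)]
  graphics::plot(nodes[keep, 2], nodes[keep, 1], col = ci, pch = 16, cex = 0.4,
                 xlab = "z (um)", ylab = "r (um)", main = what, ...)
  invisible(x)
}

#' Export a field solution as a CSV point cloud
#'
#' Columns: `r_um, z_um, u_r, u_z, p, c` (pressure only at vertex nodes;
#' `NA` elsewhere).
#'
#' @param solution A `field_solution`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
export_fields_csv <- function(solution, path) {
  mesh <- solution$mesh
  p_full <- rep(NA_real_, mesh$nn)
  p_full[seq_len(mesh$nv)] <- solution$p
  df <- data.frame(r_um = mesh$nodes[, 1], z_um = mesh$nodes[, 2],
                   u_r = solution$ur, u_z = solution$uz, p = p_full,
                   c = if (is.null(solution$c)) NA_real_ else solution$c)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
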
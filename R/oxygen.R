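# Hemoglobin-enhanced oxygen transport in the solved flow field:
#
#   B u . grad(c) = D laplacian(c)
#
# with c = 0 at the inflow, c = c_mat on the oxygenated (dilated) wall
# section, and zero diffusive flux on the undilated wall, outflow plane and
# axis. In linear mode B is the constant enhancement factor and the solve
# is performed once on the nondimensional concentration
# chat = (c - c_in)/(c_mat - c_in). In nonlinear mode the local enhancement
# 1 + (c_max k_hn / rho_bl) S'(P_O2) is evaluated from a pluggable
# saturation law via Henry's law and iterated to a fixed point with
# damping. Transport uses P1 elements on the refined mesh with
# streamline-upwind (SUPG) stabilization active where the element Peclet
# number exceeds one.

#' Solve oxygen transport in a computed flow field
#'
#' @param mesh An `axisym_mesh` (the one the flow was solved on).
#' @param flow A `field_solution` from [solve_stokes()], or `NULL` for a
#'   pure-diffusion solve (e.g. on an annulus mesh).
#' @param params A [transport_params()] object.
#' @param mode `"linear_B"` (constant enhancement, single solve) or
#'   `"nonlinear"` (pluggable saturation law, damped fixed-point
#'   iteration).
#' @param c_in Inflow dissolved-oxygen concentration (g/um^3).
#' @param c_mat Wall/source concentration (g/um^3); defaults to the
#'   maternal value in `params`.
#' @param stabilize Use SUPG stabilization (on by default).
#' @param extra_oxygenated_nodes Optional additional node ids held at
#'   `c_mat`, e.g. sections of the undilated wall for the variant that
#'   approximates oxygen transfer upstream/downstream of the dilation (see
#'   [upstream_downstream_nodes()]).
#' @param damping Damping factor of the nonlinear fixed-point update.
#' @param max_iter Iteration cap for the nonlinear mode.
#' @param tol Relative-update termination threshold (nonlinear mode).
#' @return The `flow` solution augmented with `c` (g/um^3), `chat`,
#'   `N` (ug/s, advective outflow of total oxygen), boundary flux
#'   decomposition and `flux_balance_error`; class `field_solution`.
#' @export
solve_oxygen <- function(mesh, flow, params, mode = c("linear_B", "nonlinear"),
                         c_in = 0, c_mat = params$c_mat, stabilize = TRUE,
                         extra_oxygenated_nodes = integer(0),
                         damping = 0.5, max_iter = 100L, tol = 1e-8) {
  stopifnot(inherits(mesh, "axisym_mesh"), inherits(params, "transport_params"))
  mode <- match.arg(mode)
  nn <- mesh$nn
  if (is.null(flow)) {
    ur <- numeric(nn); uz <- numeric(nn)
    flow <- structure(list(mesh = mesh, mu = params$mu, dP = 0,
                           ur = ur, uz = uz, p = numeric(mesh$nv),
                           Q = 0, Q_in = 0, resistance = NA_real_,
                           mass_balance_error = 0,
                           wall_shear = data.frame(z = numeric(0), tau = numeric(0))),
                      class = "field_solution")
  } else {
    stopifnot(inherits(flow, "field_solution"))
    ur <- flow$ur; uz <- flow$uz
  }
  dc <- c_mat - c_in
  if (dc == 0) stop("c_mat must differ from c_in")

  dir1 <- unique(c(mesh$bc_c1, extra_oxygenated_nodes))
  dir0 <- setdiff(mesh$bc_c0, dir1)
  dir_all <- c(dir0, dir1)
  free <- setdiff(seq_len(nn), dir_all)

  solve_linear <- function(Bfield) {
    K <- .assemble_transport(mesh, params$D, ur, uz, Bfield, stabilize)
    chat <- numeric(nn)
    chat[dir1] <- 1
    rhs <- -as.numeric(K[, dir1, drop = FALSE] %*% chat[dir1])
    chat[free] <- as.numeric(Matrix::solve(K[free, free, drop = FALSE],
                                           rhs[free]))
    list(chat = chat, K = K)
  }

  iterations <- 0L
  avg_enhancement <- NA_real_
  if (mode == "linear_B") {
    Bfield <- rep(params$B, nn)
    res <- solve_linear(Bfield)
    chat <- res$chat
  } else {
    if (is.null(params$saturation_law)) {
      stop("nonlinear mode requires params$saturation_law")
    }
    if (is.null(params$c_max) || is.null(params$k_hn) || is.null(params$rho_bl)) {
      stop("nonlinear mode requires c_max, k_hn, rho_bl in params")
    }
    sprime <- function(p) {
      h <- 1e-3
      pp <- p + h
      pm <- pmax(p - h, 0)   # saturation laws are defined for P >= 0
      (vapply(pp, params$saturation_law, numeric(1)) -
       vapply(pm, params$saturation_law, numeric(1))) / (pp - pm)
    }
    enhancement_of <- function(c_dim) {
      p_o2 <- params$k_hn * pmax(c_dim, 0) / params$rho_bl
      1 + (params$c_max * params$k_hn / params$rho_bl) * sprime(p_o2)
    }
    Bfield <- rep(params$B, nn)
    history <- numeric(0)
    damp <- damping
    repeat {
      iterations <- iterations + 1L
      res <- solve_linear(Bfield)
      chat <- res$chat
      c_dim <- c_in + chat * dc
      B_new <- enhancement_of(c_dim)
      upd <- max(abs(B_new - Bfield)) / max(abs(Bfield))
      # cut the damping when the update stops shrinking (period-two cycles
      # of the plain damped map), recover it while converging steadily
      if (length(history)) {
        prev <- history[length(history)]
        if (upd > prev) damp <- max(damp / 2, 0.1)
        else if (upd < 0.7 * prev) damp <- min(damp * 1.5, damping)
      }
      history <- c(history, upd)
      Bfield <- Bfield + damp * (B_new - Bfield)
      if (upd < tol) break
      if (iterations >= max_iter) {
        stop(paste0("nonlinear enhancement iteration did not converge; ",
                    "relative updates: ",
                    paste(signif(utils::tail(history, 5), 3), collapse = ", ")))
      }
    }
    avg_enhancement <- .domain_average(mesh, Bfield)
  }

  c_dim <- c_in + chat * dc
  # advective flux of total (dissolved + hemoglobin-bound) oxygen: the
  # carried concentration is c + c_max S(P(c)), which the linearized model
  # reduces to B c
  if (mode == "linear_B") {
    c_tot <- params$B * c_dim
    c_tot_in <- params$B * c_in
  } else {
    sat <- function(cd) {
      p <- params$k_hn * pmax(cd, 0) / params$rho_bl
      params$c_max * vapply(p, params$saturation_law, numeric(1))
    }
    c_tot <- c_dim + sat(c_dim)
    c_tot_in <- c_in + sat(c_in)[1]
  }
  N_adv_out <- 2 * pi * .edge_integral_p1(mesh, mesh$edges2_out, uz * c_tot)
  N_adv_in <- 2 * pi * .edge_integral_p1(mesh, mesh$edges2_in,
                                         uz * rep(c_tot_in, nn))
  Bout <- if (mode == "linear_B") rep(params$B, nn) else Bfield

  # consistent (residual-based) diffusive boundary fluxes, dimensional;
  # resid_i ~ int D dchat/dn phi_i r ds with n the outward normal
  resid <- as.numeric(res$K %*% chat) * dc * 2 * pi
  N_diff_wall <- sum(resid[dir1])           # influx through the oxygenated wall
  N_diff_in_loss <- -sum(resid[dir0])       # diffusive loss through the inflow plane

  N_transfer <- N_adv_out - N_adv_in
  fbe <- if (N_transfer != 0) {
    abs(N_transfer - (N_diff_wall - N_diff_in_loss)) / abs(N_transfer)
  } else if (N_diff_wall != 0) {
    abs(N_diff_wall - N_diff_in_loss) / abs(N_diff_wall)
  } else 0

  sol <- flow
  sol$params <- params
  sol$mode <- mode
  sol$c_in <- c_in
  sol$c_mat <- c_mat
  sol$chat <- chat
  sol$c <- c_dim
  sol$Bfield_range <- range(Bout)
  sol$avg_enhancement <- avg_enhancement
  sol$nonlinear_iterations <- iterations
  sol$N <- N_transfer * 1e6              # ug/s
  sol$N_adv_out <- N_adv_out * 1e6
  sol$N_diff_wall <- N_diff_wall * 1e6
  sol$N_diff_in_loss <- N_diff_in_loss * 1e6
  sol$flux_balance_error <- fbe
  sol$chat_range <- range(chat)
  sol
}

# domain average with the axisymmetric 2*pi*r measure (P1 field on tri4)
.domain_average <- function(mesh, f) {
  tri <- mesh$tri4
  geo <- .el_geometry(mesh$nodes, tri)
  area <- geo$det / 2
  rbar <- (geo$r1 + geo$r2 + geo$r3) / 3
  fbar <- (f[tri[, 1]] + f[tri[, 2]] + f[tri[, 3]]) / 3
  sum(fbar * rbar * area) / sum(rbar * area)
}

#' Rescale a linear-mode concentration solution to new boundary values
#'
#' Because the transport equation is linear in the concentration, a single
#' nondimensional solve `chat = (c - c_in)/(c_mat - c_in)` determines the
#' field for any boundary values: `c = c_in_new + chat * (c_mat_new -
#' c_in_new)`, with all transfer quantities scaled by the concentration
#' difference. No re-solve is performed.
#'
#' @param solution A linear-mode `field_solution` from [solve_oxygen()].
#' @param c_in_new New inflow concentration (g/um^3).
#' @param c_mat_new New wall concentration (g/um^3).
#' @return The rescaled `field_solution`.
#' @export
rescale_concentration <- function(solution, c_in_new, c_mat_new) {
  stopifnot(inherits(solution, "field_solution"))
  if (is.null(solution$chat)) stop("no concentration field to rescale")
  if (!identical(solution$mode, "linear_B")) {
    stop("rescaling requires a linear_B mode solution")
  }
  scale <- (c_mat_new - c_in_new) / (solution$c_mat - solution$c_in)
  out <- solution
  out$c_in <- c_in_new
  out$c_mat <- c_mat_new
  out$c <- c_in_new + solution$chat * (c_mat_new - c_in_new)
  out$N <- solution$N * scale
  out$N_diff_wall <- solution$N_diff_wall * scale
  out$N_diff_in_loss <- solution$N_diff_in_loss * scale
  out$N_adv_out <- out$N + solution$params$B * c_in_new * solution$Q * 1e6
  out
}

#' Boundary flux decomposition of a transport solution
#'
#' Returns the advective outflow, the consistent (residual-based)
#' diffusive influx through the oxygenated wall, the diffusive loss
#' through the inflow plane, the relative flux balance error, and the wall
#' shear stress profile.
#'
#' @param solution A `field_solution` with a solved concentration field.
#' @return A list with `N_advective_out`, `N_diffusive_wall`,
#'   `N_diffusive_in_loss` (ug/s), `flux_balance_error` and
#'   `wall_shear_stress` (data frame).
#' @export
compute_fluxes <- function(solution) {
  stopifnot(inherits(solution, "field_solution"))
  if (is.null(solution$c)) stop("solve_oxygen must be run first")
  list(
    N_advective_out = solution$N_adv_out,
    N_diffusive_wall = solution$N_diff_wall,
    N_diffusive_in_loss = solution$N_diff_in_loss,
    flux_balance_error = solution$flux_balance_error,
    wall_shear_stress = solution$wall_shear
  )
}

#' Undilated-wall node sets for the upstream/downstream oxygenation variant
#'
#' Selects nodes of the undilated wall within given distances upstream and
#' downstream of the dilation window, to be held at the maternal
#' concentration. This approximates additional oxygen transfer through the
#' villous tissue on either side of a vasculo-syncytial membrane; it is an
#' approximation by construction, not a model of the full exterior
#' diffusion problem.
#'
#' @param mesh A capillary `axisym_mesh`.
#' @param upstream_um Length of oxygenated wall upstream of the window (um).
#' @param downstream_um Length downstream (um).
#' @return Integer node ids, suitable for
#'   `solve_oxygen(extra_oxygenated_nodes = ...)`.
#' @export
upstream_downstream_nodes <- function(mesh, upstream_um = 0, downstream_um = 0) {
  if (is.null(mesh$window)) stop("mesh has no dilation window")
  z <- mesh$nodes[, 2]
  zs <- mesh$window[1]; ze <- mesh$window[2]
  wall <- setdiff(mesh$nodes_wall, mesh$nodes_wall_d)
  sel_up <- wall[z[wall] >= zs - upstream_um - 1e-9 & z[wall] < zs]
  sel_dn <- wall[z[wall] > ze & z[wall] <= ze + downstream_um + 1e-9]
  c(sel_up, sel_dn)
}

#' Diffusion-only solve on a concentric annulus and comparison value
#'
#' Solves the steady diffusion equation between an oxygenated outer
#' (villous) surface and a perfectly absorbing inner (capillary) surface
#' and returns the absorbed oxygen flux, together with the closed-form
#' annular bound it should approach.
#'
#' @param R0 Inner radius (um).
#' @param d Annulus thickness (um).
#' @param L Axial length (um).
#' @param params A [transport_params()] object.
#' @param resolution Radial cells for the mesh.
#' @return A list with `N_fem` (ug/s), `N_analytic` (ug/s) and the
#'   `field_solution`.
#' @export
solve_annulus_diffusion <- function(R0, d, L, params, resolution = 12L) {
  mesh <- build_annulus_mesh(R0, d, L, resolution = resolution)
  sol <- solve_oxygen(mesh, flow = NULL, params = params, mode = "linear_B",
                      stabilize = FALSE)
  # absorbed flux = diffusive flux through the inner (sink) surface
  N_fem <- sol$N_diff_in_loss
  N_analytic <- annular_diffusion_bound(params, A = 2 * pi * R0 * L,
                                        R0 = R0, d = d)
  list(N_fem = N_fem, N_analytic = N_analytic, solution = sol)
}
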
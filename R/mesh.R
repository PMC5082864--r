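# Structured axisymmetric meshes: a capillary of radius profile R(z)
# (meshed from the axis to the wall) or a concentric annulus (villous
# tissue between capillary and villous surfaces). The triangulation is a
# structured quad grid split into triangles; radial grading clusters nodes
# at the wall to resolve high-Peclet concentration boundary layers. The
# dilation window endpoints are inserted into the axial grid, so the
# oxygenated wall section gamma_d is an exact union of mesh edges.

.axial_grid <- function(L, z_start, z_end, nz_target) {
  brks <- sort(unique(pmin(pmax(c(0, z_start, z_end, L), 0), L)))
  segs <- diff(brks)
  segs_keep <- segs > 1e-9
  h <- L / nz_target
  zs <- 0
  for (i in which(segs_keep)) {
    ncell <- max(2L, ceiling(segs[i] / h))
    zs <- c(zs, seq(brks[i], brks[i + 1], length.out = ncell + 1L)[-1])
  }
  zs
}

.radial_fractions <- function(nr, q) {
  s <- seq(0, 1, length.out = nr + 1L)
  1 - (1 - s)^q
}

.build_structured_mesh <- function(zgrid, r_inner_fun, r_outer_fun, nr, q,
                                   kind, window = NULL, shape = NULL) {
  nzp <- length(zgrid); nz <- nzp - 1L
  zeta <- .radial_fractions(nr, q)
  vid <- function(i, j) i * (nr + 1L) + j + 1L  # i in 0..nz, j in 0..nr

  nv <- nzp * (nr + 1L)
  verts <- matrix(0, nv, 2L)
  iz <- integer(nv); jr <- integer(nv)
  for (i in 0:nz) {
    ri <- r_inner_fun(zgrid[i + 1L]); ro <- r_outer_fun(zgrid[i + 1L])
    idx <- vid(i, 0:nr)
    verts[idx, 1L] <- ri + zeta * (ro - ri)
    verts[idx, 2L] <- zgrid[i + 1L]
    iz[idx] <- i; jr[idx] <- 0:nr
  }

  m <- 2L * nz * nr
  tri <- matrix(0L, m, 3L)
  e <- 0L
  for (i in 0:(nz - 1L)) {
    for (j in 0:(nr - 1L)) {
      A <- vid(i, j); B <- vid(i + 1L, j); C <- vid(i + 1L, j + 1L); D <- vid(i, j + 1L)
      tri[e + 1L, ] <- c(A, B, C)
      tri[e + 2L, ] <- c(A, C, D)
      e <- e + 2L
    }
  }
  # enforce positive orientation
  det <- (verts[tri[, 2], 1] - verts[tri[, 1], 1]) *
         (verts[tri[, 3], 2] - verts[tri[, 1], 2]) -
         (verts[tri[, 3], 1] - verts[tri[, 1], 1]) *
         (verts[tri[, 2], 2] - verts[tri[, 1], 2])
  flip <- det < 0
  if (any(flip)) tri[flip, 2:3] <- tri[flip, 3:2]

  # unique edges -> P2 midpoint nodes
  ekey <- function(v1, v2) pmin(v1, v2) * (nv + 1) + pmax(v1, v2)
  all_e <- rbind(cbind(tri[, 1], tri[, 2]), cbind(tri[, 2], tri[, 3]),
                 cbind(tri[, 3], tri[, 1]))
  keys <- ekey(all_e[, 1], all_e[, 2])
  ukeys <- unique(keys)
  eidx <- match(keys, ukeys)
  first_occ <- match(ukeys, keys)
  edge_v <- all_e[first_occ, , drop = FALSE]
  ne <- length(ukeys)
  mid_id <- nv + seq_len(ne)
  nodes <- rbind(verts, (verts[edge_v[, 1], ] + verts[edge_v[, 2], ]) / 2)
  tri6 <- cbind(tri,
                nv + eidx[seq_len(m)],
                nv + eidx[m + seq_len(m)],
                nv + eidx[2L * m + seq_len(m)])
  # adjacent element of each unique edge (first occurrence)
  edge_elem <- ((first_occ - 1L) %% m) + 1L

  # refined P1 triangulation on all nodes
  tri4 <- rbind(
    cbind(tri6[, 1], tri6[, 4], tri6[, 6]),
    cbind(tri6[, 4], tri6[, 2], tri6[, 5]),
    cbind(tri6[, 6], tri6[, 5], tri6[, 3]),
    cbind(tri6[, 4], tri6[, 5], tri6[, 6])
  )

  edge_lookup <- function(v1, v2) nv + match(ekey(v1, v2), ukeys)

  # boundary edge tables (end, end, midpoint)
  mk_edges <- function(v1s, v2s) {
    cbind(v1s, v2s, edge_lookup(v1s, v2s))
  }
  j_in <- 0:(nr - 1L)
  edges_in <- mk_edges(vid(0L, j_in), vid(0L, j_in + 1L))
  edges_out <- mk_edges(vid(nz, j_in), vid(nz, j_in + 1L))
  i_w <- 0:(nz - 1L)
  edges_wall <- mk_edges(vid(i_w, nr), vid(i_w + 1L, nr))
  wall_elem <- edge_elem[edges_wall[, 3] - nv]
  edges_base <- mk_edges(vid(i_w, 0L), vid(i_w + 1L, 0L))
  base_elem <- edge_elem[edges_base[, 3] - nv]

  refine2 <- function(ed) rbind(cbind(ed[, 1], ed[, 3]), cbind(ed[, 3], ed[, 2]))

  # node sets, classified by coordinates (boundaries are grid lines)
  zmax <- max(zgrid)
  on_in <- abs(nodes[, 2] - zgrid[1]) < 1e-9
  on_out <- abs(nodes[, 2] - zmax) < 1e-9
  wall_nodes <- sort(unique(as.vector(edges_wall)))
  base_nodes <- sort(unique(as.vector(edges_base)))

  mesh <- list(
    kind = kind, shape = shape, window = window,
    verts = verts, tri = tri, tri6 = tri6, tri4 = tri4, nodes = nodes,
    nv = nv, nn = nrow(nodes), n_elem = m,
    nr = nr, nz = nz, zgrid = zgrid, grading = q,
    nodes_in = which(on_in), nodes_out = which(on_out),
    nodes_wall = wall_nodes, nodes_base = base_nodes,
    edges_in = edges_in, edges_out = edges_out,
    edges_wall = edges_wall, wall_elem = wall_elem,
    edges_base = edges_base, base_elem = base_elem,
    edges2_in = refine2(edges_in), edges2_out = refine2(edges_out)
  )
  class(mesh) <- "axisym_mesh"
  mesh
}

#' Build an axisymmetric mesh of a dilated capillary
#'
#' Triangulates the domain `{0 <= r <= R(z), 0 <= z <= L}` with a
#' structured grid: `resolution` quadratic-element cells across the radius
#' (graded towards the wall when `bl_refine`) and an axial grid that
#' contains the dilation window endpoints exactly, so the oxygenated wall
#' section `gamma_d` is a union of mesh edges. Velocity is discretized with
#' P2 elements on this grid and transport with P1 on its once-refined
#' companion, so the reported node set contains both.
#'
#' @param shape A [dilation_shape()].
#' @param resolution Number of radial element cells, `>= 8`.
#' @param bl_refine Grade the radial grid towards the wall so that the
#'   first cell resolves a concentration boundary layer of thickness
#'   `R0 * target_pe^(-1/3)`.
#' @param nz Number of axial cells; default targets an axial spacing of
#'   about twice the ungraded radial spacing.
#' @param target_pe Effective Peclet number used to size the wall cell when
#'   `bl_refine` is on.
#' @param occlusion_floor Minimum admissible wall radius as a fraction of
#'   `R0`; shapes narrower than this are refused.
#' @return An object of class `axisym_mesh`.
#' @export
build_mesh <- function(shape, resolution = 10L, bl_refine = TRUE, nz = NULL,
                       target_pe = 500, occlusion_floor = 0.2) {
  stopifnot(inherits(shape, "dilation_shape"))
  if (resolution < 8L) stop("resolution must be >= 8")
  ex <- shape_extrema(shape)
  if (ex$R_min < occlusion_floor * shape$R0 - 1e-9) {
    stop("mesh refused: shape violates the occlusion floor")
  }
  if (is.null(nz)) {
    nz <- max(24L, ceiling(shape$L * resolution / (2 * shape$R0)))
  }
  q <- 1
  if (bl_refine) {
    q_need <- (log(4) + log(target_pe) / 3) / log(resolution)
    q <- min(3, max(1.3, q_need))
  }
  zg <- .axial_grid(shape$L, shape$z_start, shape$z_start + shape$lam, nz)
  mesh <- .build_structured_mesh(
    zg, r_inner_fun = function(z) 0,
    r_outer_fun = function(z) radius_profile(shape, z),
    nr = as.integer(resolution), q = q, kind = "tube",
    window = c(shape$z_start, shape$z_start + shape$lam), shape = shape
  )
  # split the wall into undilated (gamma_u) and oxygenated (gamma_d) parts
  zmid <- (mesh$nodes[mesh$edges_wall[, 1], 2] +
           mesh$nodes[mesh$edges_wall[, 2], 2]) / 2
  in_d <- zmid >= shape$z_start - 1e-9 & zmid <= shape$z_start + shape$lam + 1e-9
  mesh$edges_wall_d <- mesh$edges_wall[in_d, , drop = FALSE]
  mesh$edges_wall_u <- mesh$edges_wall[!in_d, , drop = FALSE]
  mesh$wall_elem_d <- mesh$wall_elem[in_d]
  mesh$nodes_wall_d <- sort(unique(as.vector(mesh$edges_wall_d)))
  mesh$nodes_axis <- mesh$nodes_base
  # transport Dirichlet sets: deoxygenated inflow, oxygenated dilated wall
  mesh$bc_c0 <- setdiff(mesh$nodes_in, mesh$nodes_wall_d)
  mesh$bc_c1 <- mesh$nodes_wall_d
  mesh
}

#' Build a concentric-annulus mesh of the villous tissue
#'
#' Meshes the annulus `{R0 <= r <= R0 + d, 0 <= z <= L}` between a
#' capillary surface (inner, acting as a perfect oxygen sink) and the
#' villous surface (outer, held at the maternal concentration), for
#' validating the diffusion-limited transfer bound.
#'
#' @param R0 Capillary radius (um).
#' @param d Villous distance / annulus thickness (um).
#' @param L Axial length (um).
#' @param resolution Radial element cells, `>= 8`.
#' @param nz Axial cells; defaults to a roughly isotropic grid.
#' @return An `axisym_mesh` with `bc_c0` on the inner and `bc_c1` on the
#'   outer surface.
#' @export
build_annulus_mesh <- function(R0, d, L, resolution = 10L, nz = NULL) {
  if (any(c(R0, d, L) <= 0)) stop("R0, d, L must be positive")
  if (resolution < 8L) stop("resolution must be >= 8")
  if (is.null(nz)) nz <- max(8L, ceiling(L * resolution / (2 * d)))
  zg <- seq(0, L, length.out = nz + 1L)
  mesh <- .build_structured_mesh(
    zg, r_inner_fun = function(z) R0, r_outer_fun = function(z) R0 + d,
    nr = as.integer(resolution), q = 1, kind = "annulus",
    window = NULL, shape = NULL
  )
  mesh$R0 <- R0; mesh$d <- d; mesh$L <- L
  mesh$nodes_inner <- mesh$nodes_base
  mesh$bc_c0 <- mesh$nodes_inner   # deoxygenated capillary surface
  mesh$bc_c1 <- mesh$nodes_wall    # oxygenated villous surface
  mesh
}

#' Volume of the meshed solid of revolution
#'
#' Sum of `2 pi r_centroid * area` over the triangulation; for a capillary
#' mesh this approximates `pi * integral of R(z)^2 dz`.
#'
#' @param mesh An `axisym_mesh`.
#' @return Volume (um^3).
#' @export
mesh_volume <- function(mesh) {
  geo <- .el_geometry(mesh$verts, mesh$tri)
  sum(2 * pi * (geo$r1 + geo$r2 + geo$r3) / 3 * geo$det / 2)
}

#' @export
print.axisym_mesh <- function(x, ...) {
  cat(sprintf("Axisymmetric %s mesh: %d P2 elements (%d refined P1), %d nodes\n",
              x$kind, x$n_elem, nrow(x$tri4), x$nn))
  cat(sprintf("  radial cells %d (grading %.2f), axial cells %d\n",
              x$nr, x$grading, x$nz))
  cat(sprintf("  volume %.6g um^3\n", mesh_volume(x)))
  invisible(x)
}

#' @export
plot.axisym_mesh <- function(x, ...) {
  graphics::plot(x$verts[, 2], x$verts[, 1], pch = ".", xlab = "z (um)",
                 ylab = "r (um)", asp = 1, ...)
  invisible(x)
}
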
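# Internal finite-element machinery for the axisymmetric solver: reference
# bases, quadrature, element geometry and vectorized assembly of the
# r-weighted (axisymmetric) bilinear forms. All elements are straight-sided
# triangles; velocity uses continuous piecewise quadratics (P2), pressure
# continuous piecewise linears (P1) on the same triangulation (Taylor-Hood),
# and transport uses P1 on the once-refined mesh whose vertices are exactly
# the P2 nodes.

# 7-point degree-5 triangle quadrature (barycentric points, weights
# normalized to sum to 1; multiply by det/2 for physical integrals)
.tri_quad <- local({
  a1 <- 0.101286507323456; a2 <- 0.470142064105115
  w1 <- 0.125939180544827; w2 <- 0.132394152788506
  pts <- rbind(
    c(1 / 3, 1 / 3, 1 / 3),
    c(1 - 2 * a1, a1, a1), c(a1, 1 - 2 * a1, a1), c(a1, a1, 1 - 2 * a1),
    c(1 - 2 * a2, a2, a2), c(a2, 1 - 2 * a2, a2), c(a2, a2, 1 - 2 * a2)
  )
  list(lambda = pts, w = c(0.225, w1, w1, w1, w2, w2, w2))
})

# P2 basis values and reference gradients at barycentric points.
# Node order: 3 vertices, then midpoints of edges (1,2), (2,3), (3,1).
.p2_basis <- function(lambda) {
  L1 <- lambda[, 1]; L2 <- lambda[, 2]; L3 <- lambda[, 3]
  N <- cbind(L1 * (2 * L1 - 1), L2 * (2 * L2 - 1), L3 * (2 * L3 - 1),
             4 * L1 * L2, 4 * L2 * L3, 4 * L3 * L1)
  # reference gradients wrt (x, y) with L1 = 1-x-y, L2 = x, L3 = y
  dx <- cbind(-(4 * L1 - 1), 4 * L2 - 1, 0 * L3,
              4 * (L1 - L2), 4 * L3, -4 * L3)
  dy <- cbind(-(4 * L1 - 1), 0 * L2, 4 * L3 - 1,
              -4 * L2, 4 * L2, 4 * (L1 - L3))
  list(N = N, dx = dx, dy = dy)  # each Q x 6
}

# Affine element geometry for a triangulation (vertex coordinate matrix
# vcoord [n x 2, (r, z)], element index matrix tri [m x 3]).
.el_geometry <- function(vcoord, tri) {
  r1 <- vcoord[tri[, 1], 1]; z1 <- vcoord[tri[, 1], 2]
  r2 <- vcoord[tri[, 2], 1]; z2 <- vcoord[tri[, 2], 2]
  r3 <- vcoord[tri[, 3], 1]; z3 <- vcoord[tri[, 3], 2]
  J11 <- r2 - r1; J12 <- r3 - r1
  J21 <- z2 - z1; J22 <- z3 - z1
  det <- J11 * J22 - J12 * J21
  list(r1 = r1, r2 = r2, r3 = r3, z1 = z1, z2 = z2, z3 = z3,
       det = det,
       # gradient transform: grad_rz = ((J22, -J21), (-J12, J11))/det %*% grad_xy
       a11 = J22 / det, a12 = -J21 / det,
       a21 = -J12 / det, a22 = J11 / det)
}

# Assemble the scalar P2 blocks of the axisymmetric forms over a mesh:
#   K1  = int dphi_i/dr dphi_j/dr r dA      K2  = int dphi_i/dz dphi_j/dz r dA
#   Krz = int dphi_i/dz dphi_j/dr r dA      M1r = int phi_i phi_j / r dA
# Returns sparse matrices over all P2 nodes.
.assemble_p2_blocks <- function(mesh) {
  tri6 <- mesh$tri6
  m <- nrow(tri6)
  geo <- .el_geometry(mesh$verts, mesh$tri)
  qp <- .tri_quad
  pb <- .p2_basis(qp$lambda)
  nq <- length(qp$w)

  npair <- 36L
  iidx <- rep(seq_len(6), times = 6)
  jidx <- rep(seq_len(6), each = 6)
  K1v <- matrix(0, m, npair); K2v <- matrix(0, m, npair)
  Krzv <- matrix(0, m, npair); M1rv <- matrix(0, m, npair)

  for (q in seq_len(nq)) {
    lam <- qp$lambda[q, ]
    rq <- geo$r1 * lam[1] + geo$r2 * lam[2] + geo$r3 * lam[3]
    wq <- qp$w[q] * geo$det / 2
    # physical gradients of the 6 basis functions at this point: m x 6
    gr <- outer(geo$a11, pb$dx[q, ]) + outer(geo$a12, pb$dy[q, ])
    gz <- outer(geo$a21, pb$dx[q, ]) + outer(geo$a22, pb$dy[q, ])
    Nq <- pb$N[q, ]
    wr <- wq * rq
    winv <- wq / rq
    for (p in seq_len(npair)) {
      i <- iidx[p]; j <- jidx[p]
      K1v[, p] <- K1v[, p] + wr * gr[, i] * gr[, j]
      K2v[, p] <- K2v[, p] + wr * gz[, i] * gz[, j]
      Krzv[, p] <- Krzv[, p] + wr * gz[, i] * gr[, j]
      M1rv[, p] <- M1rv[, p] + winv * Nq[i] * Nq[j]
    }
  }

  nn <- nrow(mesh$nodes)
  rows <- as.vector(tri6[, iidx]); cols <- as.vector(tri6[, jidx])
  sp <- function(vals) Matrix::sparseMatrix(i = rows, j = cols,
                                            x = as.vector(vals),
                                            dims = c(nn, nn))
  list(K1 = sp(K1v), K2 = sp(K2v), Krz = sp(Krzv), M1r = sp(M1rv))
}

# Assemble the pressure-velocity coupling blocks (P1 pressure, P2 velocity):
#   Gr[i, j] = int psi_i (dphi_j/dr + phi_j / r) r dA
#   Gz[i, j] = int psi_i dphi_j/dz r dA
.assemble_pressure_blocks <- function(mesh) {
  tri <- mesh$tri; tri6 <- mesh$tri6
  m <- nrow(tri6)
  geo <- .el_geometry(mesh$verts, mesh$tri)
  qp <- .tri_quad
  pb <- .p2_basis(qp$lambda)

  Grv <- matrix(0, m, 18L); Gzv <- matrix(0, m, 18L)
  iidx <- rep(seq_len(3), times = 6)   # pressure test index
  jidx <- rep(seq_len(6), each = 3)    # velocity trial index

  for (q in seq_len(length(qp$w))) {
    lam <- qp$lambda[q, ]
    rq <- geo$r1 * lam[1] + geo$r2 * lam[2] + geo$r3 * lam[3]
    wq <- qp$w[q] * geo$det / 2
    gr <- outer(geo$a11, pb$dx[q, ]) + outer(geo$a12, pb$dy[q, ])
    gz <- outer(geo$a21, pb$dx[q, ]) + outer(geo$a22, pb$dy[q, ])
    Nq <- pb$N[q, ]
    psi <- lam  # P1 basis values are the barycentric coordinates
    for (p in seq_len(18L)) {
      i <- iidx[p]; j <- jidx[p]
      Grv[, p] <- Grv[, p] + wq * psi[i] * (gr[, j] * rq + Nq[j])
      Gzv[, p] <- Gzv[, p] + wq * psi[i] * gz[, j] * rq
    }
  }

  nv <- nrow(mesh$verts); nn <- nrow(mesh$nodes)
  rows <- as.vector(tri[, iidx]); cols <- as.vector(tri6[, jidx])
  list(
    Gr = Matrix::sparseMatrix(i = rows, j = cols, x = as.vector(Grv),
                              dims = c(nv, nn)),
    Gz = Matrix::sparseMatrix(i = rows, j = cols, x = as.vector(Gzv),
                              dims = c(nv, nn))
  )
}

# P1 transport operator on the refined mesh: diffusion + advection + SUPG.
# u_r, u_z, Bfield are nodal values on the P2/refined node set; D constant.
# Returns the assembled (unconstrained) sparse operator.
.assemble_transport <- function(mesh, D, ur, uz, Bfield, stabilize = TRUE) {
  tri <- mesh$tri4
  m <- nrow(tri)
  nn <- nrow(mesh$nodes)
  geo <- .el_geometry(mesh$nodes, tri)
  area <- geo$det / 2
  rbar <- (geo$r1 + geo$r2 + geo$r3) / 3

  # constant P1 gradients: grad N1 = (-1,-1) etc. transformed
  gr <- cbind(-geo$a11 - geo$a12, geo$a11, geo$a12)
  gz <- cbind(-geo$a21 - geo$a22, geo$a21, geo$a22)

  # element means of velocity and B
  u1 <- ur[tri[, 1]]; u2 <- ur[tri[, 2]]; u3 <- ur[tri[, 3]]
  w1 <- uz[tri[, 1]]; w2 <- uz[tri[, 2]]; w3 <- uz[tri[, 3]]
  B1 <- Bfield[tri[, 1]]; B2 <- Bfield[tri[, 2]]; B3 <- Bfield[tri[, 3]]
  Bbar <- (B1 + B2 + B3) / 3
  urm <- (u1 + u2 + u3) / 3
  uzm <- (w1 + w2 + w3) / 3
  speed <- sqrt(urm^2 + uzm^2)

  # SUPG parameter (element length in the streamline direction)
  tau <- numeric(m)
  if (stabilize) {
    ug <- abs(urm * gr[, 1] + uzm * gz[, 1]) +
          abs(urm * gr[, 2] + uzm * gz[, 2]) +
          abs(urm * gr[, 3] + uzm * gz[, 3])
    h <- ifelse(ug > 0, 2 * speed / ug, 0)
    pe <- Bbar * speed * h / (2 * D)
    xi <- ifelse(pe > 1e-8, 1 / tanh(pe) - 1 / pe, pe / 3)
    tau <- ifelse(speed > 0 & pe > 1, h * xi / (2 * Bbar * speed), 0)
  }

  # 3-point midpoint rule (degree 2) for the advection term with linearly
  # varying u, B and r; diffusion and SUPG use element means (exact for
  # constant-gradient P1 diffusion up to the linear r weight).
  midl <- rbind(c(0.5, 0.5, 0), c(0, 0.5, 0.5), c(0.5, 0, 0.5))
  vals <- matrix(0, m, 9L)
  iidx <- rep(seq_len(3), times = 3)
  jidx <- rep(seq_len(3), each = 3)

  for (p in seq_len(9L)) {
    i <- iidx[p]; j <- jidx[p]
    # diffusion
    vals[, p] <- D * area * rbar * (gr[, i] * gr[, j] + gz[, i] * gz[, j])
    # SUPG
    if (stabilize) {
      vals[, p] <- vals[, p] + tau * Bbar^2 * area * rbar *
        (urm * gr[, i] + uzm * gz[, i]) * (urm * gr[, j] + uzm * gz[, j])
    }
  }
  # advection: loop quad points
  uq <- list(c1 = cbind(u1, u2, u3), c2 = cbind(w1, w2, w3),
             B = cbind(B1, B2, B3),
             r = cbind(geo$r1, geo$r2, geo$r3))
  for (q in seq_len(3L)) {
    lam <- midl[q, ]
    urq <- uq$c1 %*% lam; uzq <- uq$c2 %*% lam
    Bq <- uq$B %*% lam; rq <- uq$r %*% lam
    wq <- area / 3
    for (p in seq_len(9L)) {
      i <- iidx[p]; j <- jidx[p]
      conv <- Bq * (urq * gr[, j] + uzq * gz[, j])
      vals[, p] <- vals[, p] + wq * rq * lam[i] * conv
    }
  }

  rows <- as.vector(tri[, iidx]); cols <- as.vector(tri[, jidx])
  Matrix::sparseMatrix(i = rows, j = cols, x = as.vector(vals),
                       dims = c(nn, nn))
}

# 1D boundary integral int f phi_i r ds over a set of straight P2 edges
# given as a matrix [k x 3] of node ids (end, end, midpoint). Returns the
# load vector over all nodes (f = 1).
.edge_load_p2 <- function(mesh, edges) {
  nn <- nrow(mesh$nodes)
  out <- numeric(nn)
  if (is.null(edges) || nrow(edges) == 0L) return(out)
  # 3-point Gauss on [0, 1]
  t <- c(0.5 - sqrt(15) / 10, 0.5, 0.5 + sqrt(15) / 10)
  w <- c(5 / 18, 8 / 18, 5 / 18)
  N <- rbind((1 - t) * (1 - 2 * t), t * (2 * t - 1), 4 * t * (1 - t))  # 3 x nq
  p1 <- mesh$nodes[edges[, 1], , drop = FALSE]
  p2 <- mesh$nodes[edges[, 2], , drop = FALSE]
  len <- sqrt((p2[, 1] - p1[, 1])^2 + (p2[, 2] - p1[, 2])^2)
  idx_all <- integer(0); val_all <- numeric(0)
  for (q in seq_len(3L)) {
    rq <- p1[, 1] + t[q] * (p2[, 1] - p1[, 1])
    for (i in seq_len(3L)) {
      idx_all <- c(idx_all, edges[, i])
      val_all <- c(val_all, w[q] * len * rq * N[i, q])
    }
  }
  agg <- rowsum(val_all, idx_all)
  out[as.integer(rownames(agg))] <- agg[, 1]
  out
}

# int g phi_i r ds for nodal field g (linear on refined edges): returns the
# scalar integral int g r ds over a set of refined (2-node) edges.
.edge_integral_p1 <- function(mesh, edges2, g) {
  if (is.null(edges2) || nrow(edges2) == 0L) return(0)
  p1 <- mesh$nodes[edges2[, 1], , drop = FALSE]
  p2 <- mesh$nodes[edges2[, 2], , drop = FALSE]
  len <- sqrt((p2[, 1] - p1[, 1])^2 + (p2[, 2] - p1[, 2])^2)
  # 2-point Gauss (exact to cubic): g linear, r linear -> quadratic
  t1 <- 0.5 - sqrt(3) / 6; t2 <- 0.5 + sqrt(3) / 6
  val <- 0
  for (t in c(t1, t2)) {
    rq <- p1[, 1] + t * (p2[, 1] - p1[, 1])
    gq <- g[edges2[, 1]] * (1 - t) + g[edges2[, 2]] * t
    val <- val + sum(0.5 * len * rq * gq)
  }
  val
}
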
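# Shared fixtures: default transport parameters, the two measured dilation
# configurations, and lazily cached solver runs reused across tests (the
# solves are deterministic, so sharing them only saves time).

default_params <- function() transport_params()

# dilation geometries measured from the imaged branch (undilated radius
# from the branch minimum or the branch average, with matching window)
config_rav <- function() list(R0 = 4.7, lam = 31, L = 76)
config_rmin <- function() list(R0 = 2.8, lam = 23, L = 76)

straight_tube_shape <- function(R0 = 4.7, lam = 31, L = 76) {
  bump_shape(R0 = R0, R_max = R0, lam = lam, L = L)
}

.cache_env <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (is.null(.cache_env[[key]])) .cache_env[[key]] <- force(expr)
  .cache_env[[key]]
}

# straight-tube Stokes solve at the calibrated 300 um/s pressure drop
cached_straight_flow <- function(resolution = 8) {
  key <- paste0("straight", resolution)
  cached(key, {
    sh <- straight_tube_shape()
    mesh <- build_mesh(sh, resolution = resolution)
    dP <- calibrate_pressure(4.7, 76, 1e-3, 300)
    list(mesh = mesh, dP = dP, flow = solve_stokes(mesh, 1e-3, dP))
  })
}

expect_rel_equal <- function(actual, expected, tol) {
  testthat::expect_lt(abs(actual / expected - 1), tol)
}
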
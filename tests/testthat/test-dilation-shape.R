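test_that("radius profile evaluates the truncated series inside the window only", {
  # all coefficients zero except a0 = 2 -> straight tube everywhere
  sh <- dilation_shape(R0 = 4.7, lam = 31, L = 76, a = c(2, 0, 0))
  z <- seq(0, 76, length.out = 101)
  expect_equal(radius_profile(sh, z), rep(4.7, 101))

  # n = 2 with only a0, a2 nonzero and a0/2 + a2 = 1:
  # R(0) = R(lam) = R0 and R(lam/2) = R0 (a0/2 - a2)
  a2 <- -0.2; a0 <- 2 * (1 - a2)
  sh2 <- dilation_shape(R0 = 4.7, lam = 31, L = 76, a = c(a0, 0, a2))
  zs <- sh2$z_start
  expect_equal(radius_profile(sh2, zs), 4.7, tolerance = 1e-10)
  expect_equal(radius_profile(sh2, zs + 31), 4.7, tolerance = 1e-10)
  expect_equal(radius_profile(sh2, zs + 15.5), 4.7 * (a0 / 2 - a2),
               tolerance = 1e-10)
  # undilated outside the window
  expect_equal(radius_profile(sh2, zs - 1), 4.7)
  expect_equal(radius_profile(sh2, 76), 4.7)
  expect_error(radius_profile(sh2, -1), "\\[0, L\\]")
})

test_that("constructor enforces wall continuity and the occlusion floor", {
  # broken endpoint constraint
  expect_error(dilation_shape(R0 = 4.7, lam = 31, L = 76, a = c(2, 0.1, 0)),
               "constraints violated")
  # occluding shape: amplitude pushes min R below the floor
  expect_error(symmetric_bump_shape(4.7, 31, 76, amplitudes = -0.9),
               "occlude")
  expect_error(dilation_shape(R0 = 4.7, lam = 80, L = 76, a = c(2, 0, 0)),
               "lam")
})

test_that("constraint elimination is exact for random free parameters", {
  set.seed(11)
  for (i in 1:100) {
    free <- runif(n_free_params(6), -0.02, 0.02)
    sh <- apply_constraints(free, n = 6, R0 = 4.7, lam = 31, L = 76,
                            r_min_fraction = 0.01)
    th <- c(sh$a, sh$b)
    C <- capflux:::.shape_constraint_matrix(6)
    expect_lt(max(abs(C %*% th - c(1, 1, 0, 0))), 1e-10)
  }
  # free-parameter counting: 2n+1 coefficients, 4 constraints
  expect_equal(n_free_params(6), 2 * 6 + 1 - 4)
  expect_equal(n_free_params(2), 1)
  # symmetric strict-parity family: even cosines, one constraint
  expect_equal(n_free_params(4, symmetric = TRUE), 2)
  expect_error(apply_constraints(c(1, 2), n = 6, R0 = 1, lam = 1, L = 2),
               "expected 9 free parameters")
})

test_that("one- and two-DOF families hit prescribed extrema at the midpoint", {
  # 1 DOF, R_max = R0 -> straight tube
  sh0 <- bump_shape(4.7, 4.7, 31, 76)
  ex0 <- shape_extrema(sh0)
  expect_equal(ex0$R_min, 4.7)
  expect_equal(ex0$R_max, 4.7)

  # measured geometry: max 6.8 um at the window midpoint, endpoints at 4.7
  sh <- bump_shape(R0 = 4.7, R_max = 6.8, lam = 31, L = 76)
  ex <- shape_extrema(sh)
  expect_equal(ex$R_max, 6.8, tolerance = 1e-9)
  expect_equal(ex$z_at_max, sh$z_start + 31 / 2, tolerance = 1e-5)
  expect_equal(radius_profile(sh, sh$z_start), 4.7, tolerance = 1e-10)

  # extrema of a random order-6 shape agree with a dense grid oracle
  set.seed(5)
  free <- runif(n_free_params(6), -0.03, 0.03)
  shr <- apply_constraints(free, n = 6, R0 = 4.7, lam = 31, L = 76,
                           r_min_fraction = 0.01)
  zg <- seq(shr$z_start, shr$z_start + 31, length.out = 1e6)
  rg <- radius_profile(shr, zg)
  exr <- shape_extrema(shr)
  expect_equal(exr$R_max, max(rg), tolerance = 1e-6 * 4.7)
  expect_equal(exr$R_min, min(rg), tolerance = 1e-6 * 4.7)
})

test_that("strict-parity symmetric shapes are mirror-symmetric about the window midpoint", {
  sh <- symmetric_bump_shape(4.7, 31, 76, amplitudes = c(0.4, -0.1))
  zeta <- seq(0, 31, length.out = 301)
  r1 <- radius_profile(sh, sh$z_start + zeta)
  r2 <- radius_profile(sh, sh$z_start + 31 - zeta)
  expect_lt(max(abs(r1 - r2)), 1e-9 * 4.7)

  # the published odd-zeroing rule keeps even sine terms, which are
  # antisymmetric about the midpoint — both modes are exposed
  shp <- apply_constraints(c(0.1, 0.05, 0.02), n = 4, R0 = 4.7, lam = 31,
                           L = 76, symmetric = TRUE,
                           symmetry_mode = "paper_odd_zero")
  expect_true(all(shp$a[c(2, 4)] == 0))  # odd-k cosines zeroed (k = 1, 3)
  expect_true(all(shp$b[c(1, 3)] == 0))  # odd-k sines zeroed
})

test_that("shape JSON and profile CSV round-trip", {
  sh <- symmetric_bump_shape(4.7, 31, 76, amplitudes = c(0.35, 0.05))
  tmp <- withr::local_tempfile(fileext = ".json")
  shape_to_json(sh, tmp)
  back <- shape_from_json(tmp)
  expect_equal(back$a, sh$a)
  expect_equal(back$b, sh$b)
  expect_equal(back$lam, sh$lam)

  csv <- withr::local_tempfile(fileext = ".csv")
  export_shape_profile(sh, csv, n_points = 101)
  df <- utils::read.csv(csv)
  expect_equal(df$R_um, radius_profile(sh, df$z_um))
})
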
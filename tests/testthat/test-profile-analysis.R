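test_that("flat and degenerate profiles report no dilation", {
  flat <- data.frame(s = seq(0, 76, by = 0.5), r = rep(4.7, 153))
  for (def in c("average_crossing", "local_minima")) {
    m <- measure_dilation(flat, def)
    expect_equal(m$status, "no dilation detected")
    expect_true(is.na(m$lam))
  }
  expect_error(measure_dilation(data.frame(s = c(1, 2), r = c(1, 1))),
               "3 samples")
  expect_error(measure_dilation(data.frame(s = c(1, 1, 2), r = c(1, 1, 1))),
               "increasing")
})

test_that("average-crossing measurement matches the analytic crossings of a noiseless bump", {
  prof <- make_bump_profile(R0 = 4.7, R_max = 6.8, lam = 31, L = 76, ds = 0.25)
  m <- measure_dilation(prof, "average_crossing", smoothing_window = 0)
  expect_equal(m$status, "ok")
  expect_equal(m$R_max, 6.8)

  # analytic construction: the arclength mean of the sampled bump, and the
  # cosine-bump crossings through it
  R0 <- 4.7; A <- 6.8 - 4.7; lam <- 31; L <- 76
  rbar <- m$R0
  frac <- (rbar - R0) / A                      # (1 - cos)/2 value at crossing
  zeta <- lam / (2 * pi) * acos(1 - 2 * frac)
  lam_analytic <- lam - 2 * zeta
  expect_lt(abs(m$lam - lam_analytic), 0.25)   # within one sample spacing
  # trapezoidal mean itself is close to the continuous mean
  expect_rel_equal(rbar, R0 + A * (lam / 2) / L, 5e-3)
})

test_that("local-minima measurement recovers the full window of a noiseless bump", {
  prof <- make_bump_profile(R0 = 4.7, R_max = 6.8, lam = 31, L = 76, ds = 0.25)
  m <- measure_dilation(prof, "local_minima", smoothing_window = 0)
  expect_equal(m$status, "ok")
  expect_equal(m$R0, 4.7)          # branch minimum radius
  expect_equal(m$R_max, 6.8)
  # flanking minima of the noiseless bump sit at the window edges
  expect_lt(abs(m$lam - 31), 2 * 0.25 + 1e-9)
})

test_that("measurements are scale-equivariant", {
  prof <- make_bump_profile(R0 = 4.7, R_max = 6.8, lam = 31, L = 76, ds = 0.25)
  k <- 3.7
  scaled <- data.frame(s = prof$s * k, r = prof$r * k)
  for (def in c("average_crossing", "local_minima")) {
    m1 <- measure_dilation(prof, def, smoothing_window = 1.9)
    m2 <- measure_dilation(scaled, def, smoothing_window = 1.9 * k)
    expect_equal(m2$lam, k * m1$lam, tolerance = 1e-9)
    expect_equal(m2$R0, k * m1$R0, tolerance = 1e-9)
    expect_equal(m2$R_max, k * m1$R_max, tolerance = 1e-9)
  }
})

test_that("average-crossing is robust to seeded radius noise", {
  # 100 noisy bumps (sigma = 0.1 um, smoothing window 3 um): the dilation
  # length must land within 15% of the noiseless value in at least 90
  truth <- measure_dilation(
    make_bump_profile(4.7, 6.8, 31, 76, ds = 0.5),
    "average_crossing", smoothing_window = 3)$lam
  hits <- 0L
  for (seed in 1:100) {
    prof <- make_bump_profile(4.7, 6.8, 31, 76, ds = 0.5,
                              noise_sigma = 0.1, seed = seed)
    m <- measure_dilation(prof, "average_crossing", smoothing_window = 3)
    if (m$status == "ok" && abs(m$lam - truth) / truth <= 0.15) {
      hits <- hits + 1L
    }
  }
  expect_gte(hits, 90L)
})

test_that("measurement round-trips through the axisymmetric model shape", {
  # straight measurement -> straight tube
  m0 <- list(status = "ok", definition = "average_crossing", lam = 31,
             R0 = 4.7, R_max = 4.7, s_start = 20, s_end = 51,
             smoothing_window = 0)
  class(m0) <- "dilation_measurement"
  sh0 <- profile_to_shape(m0, L = 76)
  expect_equal(shape_extrema(sh0)$R_max, 4.7)

  # measured geometry -> shape with the measured extrema
  prof <- make_bump_profile(4.7, 6.8, 31, 76, ds = 0.25)
  m <- measure_dilation(prof, "local_minima", smoothing_window = 0)
  sh <- profile_to_shape(m, L = 76)
  ex <- shape_extrema(sh)
  expect_equal(ex$R_min, 4.7, tolerance = 1e-6)
  expect_equal(ex$R_max, 6.8, tolerance = 1e-6)

  # measuring a resampled model profile recovers the dilation length to
  # within one sample spacing
  prof2 <- data.frame(s = seq(0, 76, by = 0.25),
                      r = radius_profile(sh, seq(0, 76, by = 0.25)))
  m2 <- measure_dilation(prof2, "local_minima", smoothing_window = 0)
  expect_lt(abs(m2$lam - m$lam), 2 * 0.25 + 1e-9)
})

test_that("profile CSV IO validates and round-trips", {
  prof <- make_bump_profile(4.7, 6.8, 31, 76, ds = 0.5)
  tmp <- withr::local_tempfile(fileext = ".csv")
  write_radius_profile(prof, tmp)
  back <- read_radius_profile(tmp)
  expect_equal(back, prof)
  bad <- withr::local_tempfile(fileext = ".csv")
  utils::write.csv(data.frame(x = 1:3, y = 1:3), bad, row.names = FALSE)
  expect_error(read_radius_profile(bad), "s_um")
})
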
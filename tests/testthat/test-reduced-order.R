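test_that("Poiseuille resistance and equivalent radius follow their closed forms", {
  expect_rel_equal(poiseuille_resistance(1e-3, 164, 6.09), 3.03e-4, 5e-3)
  expect_equal(poiseuille_resistance(1e-3, 2 * 164, 6.09),
               2 * poiseuille_resistance(1e-3, 164, 6.09))
  expect_equal(poiseuille_resistance(1e-3, 164, 2 * 6.09),
               poiseuille_resistance(1e-3, 164, 6.09) / 16)
  expect_error(poiseuille_resistance(1e-3, 164, 0), "positive")

  expect_rel_equal(equivalent_radius(0.185 * 6.88e4, 185), 4.68, 5e-3)
  expect_equal(equivalent_radius(pi * 12, 12), 1)
  r <- 3.21
  expect_equal(equivalent_radius(pi * r^2 * 50, 50), r, tolerance = 1e-12)
})

test_that("flow-limited scalings carry their exact prefactors and exponents", {
  tp <- default_params()
  expect_lt(abs(alpha_leveque() - 5.5), 0.05)   # (12 pi^2)^(1/3)/Gamma(4/3)

  expect_equal(leveque_transfer(tp, 100, 1e-4, 0), 0)
  # cube-root pressure scaling: 8x dP doubles N
  expect_equal(leveque_transfer(tp, 100, 1e-4, 8),
               2 * leveque_transfer(tp, 100, 1e-4, 1), tolerance = 1e-12)

  expect_equal(equilibrated_transfer(tp, 4e-4, 0), 0)
  expect_equal(equilibrated_transfer(tp, 4e-4, 2),
               4 * equilibrated_transfer(tp, 4e-4, 0.5), tolerance = 1e-12)
  # direct arithmetic: c_mat*B*dP/R = 141 * 2.24e-18 * 1250 um^3/s
  expect_rel_equal(equilibrated_transfer(tp, 4e-4, 0.5), 3.95e-7, 2e-3)
})

test_that("regression equation interpolates between its two asymptotes", {
  tp <- default_params()
  L <- 164; R <- 4e-4
  reg <- regression_flow(tp, L, R, 1)
  K1 <- reg$K1; K2 <- reg$K2

  expect_equal(regression_flow(tp, L, R, 0)$N_flow, 0)

  # equilibrated limit: K1*dP^(2/3) <= 1e-6 K2
  dP_lo <- (1e-6 * K2 / K1)^1.5
  expect_rel_equal(regression_flow(tp, L, R, dP_lo)$N_flow,
                   equilibrated_transfer(tp, R, dP_lo), 1e-5)

  # crossover point dP* = (K2/K1)^(3/2): N = K2 dP*^(1/3) / 2
  dP_x <- (K2 / K1)^1.5
  expect_rel_equal(regression_flow(tp, L, R, dP_x)$N_flow,
                   K2 * dP_x^(1 / 3) / 2, 1e-12)

  # asymptote agreement at extreme pressure ratios (1e-6 and 1e6 of
  # crossover), and monotone concave behaviour in between
  expect_rel_equal(regression_flow(tp, L, R, dP_x * 1e-6)$N_flow,
                   equilibrated_transfer(tp, R, dP_x * 1e-6), 1e-3)
  expect_rel_equal(regression_flow(tp, L, R, dP_x * 1e6)$N_flow,
                   leveque_transfer(tp, L, R, dP_x * 1e6), 1e-3)
  dPs <- dP_x * 10^seq(-3, 3, by = 0.5)
  Ns <- vapply(dPs, function(p) regression_flow(tp, L, R, p)$N_flow, numeric(1))
  expect_true(all(diff(Ns) > 0))
  expect_true(all(diff(diff(Ns) / diff(dPs)) < 0))  # concave in dP
})

test_that("annular bound and villous correction respect their limits", {
  tp <- default_params()
  # unit-log case: R0 = 1, d = e-1, A = 2 pi L  ->  N = 2 pi L D c_mat
  L <- 30
  expect_rel_equal(annular_diffusion_bound(tp, 2 * pi * L, 1, exp(1) - 1),
                   2 * pi * L * tp$D * tp$c_mat * 1e6, 1e-12)
  expect_error(annular_diffusion_bound(tp, 10, 1, 0), "touches")

  v <- villous_corrected_transfer(2, 2)
  expect_equal(v$N, 1)
  expect_equal(v$c_inner_fraction, 0.5)
  expect_rel_equal(villous_corrected_transfer(1e9 * 3, 3)$N, 3, 1e-8)
  expect_rel_equal(villous_corrected_transfer(3, 1e12)$N, 3, 1e-9)
  # bounded above by both arguments, monotone in both
  set.seed(7)
  for (i in 1:25) {
    nf <- runif(1, 0, 5); nm <- runif(1, 0.1, 5)
    N <- villous_corrected_transfer(nf, nm)$N
    expect_lt(N, min(nf + (nf == 0), nm))
    expect_gte(villous_corrected_transfer(nf * 1.1, nm)$N, N)
    expect_gte(villous_corrected_transfer(nf, nm * 1.1)$N, N)
  }
})

test_that("regime classification follows the separation-factor inequalities", {
  tp <- default_params()
  R0 <- 4.7; d <- 20; L_path <- 150
  ratio <- L_path * R0 / (d + R0)^2
  u_of_pe <- function(pe) pe * tp$D / (tp$B * R0)

  expect_equal(classify_regime(tp, u_of_pe(0.01 * ratio), R0, d, L_path,
                               1e-8, 1e-6), "flow_limited_equilibrated")
  expect_equal(classify_regime(tp, u_of_pe(100 * ratio), R0, d, L_path,
                               1e-8, 1e-6), "flow_limited_leveque")
  expect_equal(classify_regime(tp, u_of_pe(100 * ratio), R0, d, L_path,
                               1e-4, 1e-6), "diffusion_limited")
  # tie at the boundary ratio falls to crossover
  expect_equal(classify_regime(tp, u_of_pe(ratio), R0, d, L_path,
                               1e-8, 1e-6), "crossover")
  expect_error(classify_regime(tp, 1, R0, d, L_path, 1, 1, threshold = 0.5),
               ">= 1")
})

test_that("geometric sensitivity factors reproduce the scaling exponents", {
  expect_equal(sensitivity_factor(1.1, "uniform", "low_Pe"), 1.1^3)
  expect_equal(sensitivity_factor(1.1, "uniform", "high_Pe"), 1.1^(5 / 3))
  expect_equal(sensitivity_factor(1.1, "radius_only", "low_Pe"), 1.1^4)
  expect_equal(sensitivity_factor(1.1, "radius_only", "high_Pe"), 1.1^(4 / 3))
  for (m in c("uniform", "radius_only")) {
    for (r in c("low_Pe", "high_Pe")) expect_equal(sensitivity_factor(1, m, r), 1)
  }

  # consistency with the transfer formulas under L -> kL, R0 -> kR0:
  # the equilibrated (low-Pe) ratio via Poiseuille resistance is exactly k^3,
  # the Leveque (high-Pe) ratio exactly k^(5/3)
  tp <- default_params()
  k <- 1.37; L <- 100; R0 <- 4
  res1 <- poiseuille_resistance(tp$mu, L, R0)
  res2 <- poiseuille_resistance(tp$mu, k * L, k * R0)
  expect_equal(equilibrated_transfer(tp, res2, 1) / equilibrated_transfer(tp, res1, 1),
               sensitivity_factor(k, "uniform", "low_Pe"), tolerance = 1e-12)
  expect_equal(leveque_transfer(tp, k * L, res2, 1) / leveque_transfer(tp, L, res1, 1),
               sensitivity_factor(k, "uniform", "high_Pe"), tolerance = 1e-12)
})

test_that("prediction pipeline fills derived columns and stays internally consistent", {
  tp <- default_params()
  preds <- predict_transfer(table3_fixture(), tp, dP = c(0.5, 2, 20))
  expect_equal(nrow(preds), 9L)
  expect_true(all(preds$N_corrected <= preds$N_max))
  expect_true(all(preds$N_corrected <= preds$N_flow_regression))
  expect_true(all(preds$N_ratio > 0 & preds$N_ratio <= 1))
  # monotone N(dP) per capillary
  for (lab in unique(preds$label)) {
    sub <- preds[preds$label == lab, ]
    expect_true(all(diff(sub$N_corrected[order(sub$dP)]) > 0))
  }
  # the numerically computed bound from the fixture is used, not the
  # closed-form annulus value
  expect_equal(unique(preds$N_max), table3_raw()$N_max_numeric)
})

test_that("capillary summary CSV IO round-trips the bundled fixture losslessly", {
  fx <- table3_fixture()
  tmp <- withr::local_tempfile(fileext = ".csv")
  write_capillary_summaries(fx, tmp)
  back <- read_capillary_summaries(tmp)
  expect_equal(as.data.frame(back), as.data.frame(fx))

  shipped <- system.file("extdata", "capillary_morphometry.csv",
                         package = "capflux")
  expect_true(nzchar(shipped))
  shipped_df <- read_capillary_summaries(shipped)
  expect_equal(shipped_df$L, fx$L)
  expect_equal(shipped_df$V_cap, fx$V_cap)
  expect_equal(shipped_df$N_max_numeric, fx$N_max_numeric)
})
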
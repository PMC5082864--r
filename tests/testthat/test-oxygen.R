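test_that("pure-diffusion annulus solve reproduces the closed-form bound", {
  tp <- default_params()
  res <- solve_annulus_diffusion(R0 = 4.7, d = 15, L = 76, params = tp,
                                 resolution = 12)
  expect_rel_equal(res$N_fem, res$N_analytic, 0.02)
  # and the analytic value is what make_annulus_case() advertises
  cs <- make_annulus_case(4.7, 15, 76)
  expect_equal(res$N_analytic, cs$N_analytic(tp))
})

test_that("consistent residual-based flux beats naive gradient evaluation on the annulus", {
  tp <- default_params()
  res <- solve_annulus_diffusion(R0 = 2, d = 2 * (exp(1) - 1), L = 40,
                                 params = tp, resolution = 8)
  expect_rel_equal(res$N_fem, res$N_analytic, 0.01)

  # naive one-sided gradient at the inner wall from the first radial cell
  sol <- res$solution; mesh <- sol$mesh
  inner <- mesh$nodes_inner
  r_in <- mesh$nodes[inner, 1][1]
  others <- setdiff(seq_len(mesh$nn), inner)
  r1 <- min(mesh$nodes[others, 1])     # first node ring off the wall
  ring <- others[abs(mesh$nodes[others, 1] - r1) < 1e-9]
  dcdr <- mean(sol$c[ring]) / (r1 - r_in)  # c = 0 at the inner wall
  N_naive <- tp$D * 2 * pi * r_in * 40 * dcdr * 1e6
  err_naive <- abs(N_naive / res$N_analytic - 1)
  err_resid <- abs(res$N_fem / res$N_analytic - 1)
  expect_lt(err_resid, err_naive)
})

test_that("low-Peclet transport saturates to the equilibrated limit c_mat B Q", {
  tp <- transport_params(B = 1, D = 1e5)
  # oxygen along (almost) the whole wall; Pe_eff R0 / L ~ 1e-5
  sh <- bump_shape(2, 2, lam = 99.99, L = 100, z_start = 0.005)
  mesh <- build_mesh(sh, resolution = 8)
  dP <- calibrate_pressure(2, 100, 1e-3, 50)
  fl <- solve_stokes(mesh, 1e-3, dP)
  ox <- solve_oxygen(mesh, fl, tp)
  expect_rel_equal(ox$N, equilibrated_transfer(tp, fl$resistance, dP), 0.02)
})

test_that("high-Peclet transfer follows the one-third Leveque pressure exponent", {
  tp <- default_params()
  sh <- straight_tube_shape()
  mesh <- build_mesh(sh, resolution = 12, target_pe = 1e4)
  dPs <- calibrate_pressure(4.7, 76, 1e-3, 300) * 10 * 10^seq(0, 1, by = 1 / 3)
  Ns <- vapply(dPs, function(p) {
    fl <- solve_stokes(mesh, 1e-3, p)
    solve_oxygen(mesh, fl, tp)$N
  }, numeric(1))
  slope <- stats::coef(stats::lm(log(Ns) ~ log(dPs)))[[2]]
  expect_lt(abs(slope - 1 / 3), 0.03)
})

test_that("oxygen transfer is monotone in the pressure drop at fixed geometry", {
  tp <- default_params()
  sh <- bump_shape(4.7, 6.8, 31, 76)
  mesh <- build_mesh(sh, resolution = 8)
  dPs <- calibrate_pressure(4.7, 76, 1e-3, 300) * c(0.25, 0.5, 1, 2, 4)
  Ns <- vapply(dPs, function(p) {
    solve_oxygen(mesh, solve_stokes(mesh, 1e-3, p), tp)$N
  }, numeric(1))
  expect_true(all(diff(Ns) > 0))
})

test_that("flux balance closes and the discrete field respects the maximum principle", {
  tp <- default_params()
  sh <- bump_shape(4.7, 6.8, 31, 76)
  sol <- simulate_dilation(sh, tp, resolution = 10)
  expect_lt(sol$flux_balance_error, 0.01)
  expect_gte(sol$chat_range[1], -1e-3)
  expect_lte(sol$chat_range[2], 1 + 1e-3)
  fx <- compute_fluxes(sol)
  expect_equal(fx$N_advective_out, sol$N_adv_out)
  expect_gt(fx$N_diffusive_wall, 0)
})

test_that("concentration does not scale linearly with dP although the flow does", {
  tp <- default_params()
  sh <- bump_shape(4.7, 6.8, 31, 76)
  mesh <- build_mesh(sh, resolution = 8)
  o1 <- solve_oxygen(mesh, solve_stokes(mesh, 1e-3, 2), tp)
  o2 <- solve_oxygen(mesh, solve_stokes(mesh, 1e-3, 6), tp)
  # nondimensional concentration fields differ materially
  expect_gt(max(abs(o2$chat - o1$chat)), 0.01)
  # transfer grows sublinearly (between the 1/3-power and linear regimes)
  expect_lt(o2$N / o1$N, 3)
  expect_gt(o2$N / o1$N, 3^(1 / 3) * 0.99)
})

test_that("rescaling boundary concentrations matches a fresh solve exactly", {
  tp <- default_params()
  sh <- bump_shape(4.7, 6.8, 31, 76)
  mesh <- build_mesh(sh, resolution = 8)
  fl <- solve_stokes(mesh, 1e-3, 4.13)
  base <- solve_oxygen(mesh, fl, tp)

  # identity rescale
  same <- rescale_concentration(base, 0, base$c_mat)
  expect_equal(same$c, base$c)
  expect_equal(same$N, base$N)

  # doubling c_mat doubles N
  twice <- rescale_concentration(base, 0, 2 * base$c_mat)
  expect_rel_equal(twice$N, 2 * base$N, 1e-12)

  # against a fresh solve at shifted boundary values
  c_in_new <- 0.3 * tp$c_mat; c_mat_new <- 1.7 * tp$c_mat
  rs <- rescale_concentration(base, c_in_new, c_mat_new)
  fresh <- solve_oxygen(mesh, fl, tp, c_in = c_in_new, c_mat = c_mat_new)
  expect_lt(max(abs(rs$c - fresh$c)) / max(fresh$c), 1e-10)
  expect_rel_equal(rs$N, fresh$N, 1e-10)
  expect_error(rescale_concentration(fl, 0, 1), "no concentration")
})

test_that("nonlinear saturation mode converges and brackets the linear run", {
  # Henry's-law constituents consistent with the internal units: blood
  # density 1e-12 g/um^3, k_hn giving 52.5 mmHg at the maternal
  # concentration, and c_max chosen so 1 + c_max K k_hn / rho_bl = 141
  K <- 0.019
  c_mat <- 2.24e-18
  rho_bl <- 1e-12
  k_hn <- 52.5 * rho_bl / c_mat
  c_max <- 140 * rho_bl / (K * k_hn)

  # S = K p on the whole pressure range makes S' = K everywhere, so the
  # nonlinear fixed point must land on the linear solution
  tp <- transport_params(B = 141, K = K, c_max = c_max, k_hn = k_hn,
                         rho_bl = rho_bl,
                         saturation_law = function(p) pmin(1, K * p))
  sh <- bump_shape(4.7, 6.8, 31, 76)
  mesh <- build_mesh(sh, resolution = 8)
  fl <- solve_stokes(mesh, 1e-3, 4.13)
  lin <- solve_oxygen(mesh, fl, tp, mode = "linear_B")
  nl <- solve_oxygen(mesh, fl, tp, mode = "nonlinear")
  expect_gt(nl$nonlinear_iterations, 0)
  expect_rel_equal(nl$N, lin$N, 1e-3)
  expect_rel_equal(nl$avg_enhancement, 141, 1e-3)

  # a genuinely sigmoidal (Hill) law converges; near 52.5 mmHg it is
  # flatter than the origin-linearization, so the average enhancement and
  # the transfer drop below the linear-B values
  tph <- transport_params(B = 141, K = K, c_max = c_max, k_hn = k_hn,
                          rho_bl = rho_bl,
                          saturation_law = hill_saturation(p50 = 20, n = 2.5))
  nlh <- solve_oxygen(mesh, fl, tph, mode = "nonlinear")
  expect_true(is.finite(nlh$N) && nlh$N > 0)
  expect_gt(nlh$avg_enhancement, 1)
  expect_lt(nlh$avg_enhancement, 141)
  # flux closure is looser here than in linear mode (the advected total
  # c + c_max S is strongly nonlinear near the wall); it tightens under
  # mesh refinement
  expect_lt(nlh$flux_balance_error, 0.05)
  expect_error(solve_oxygen(mesh, fl, default_params(), mode = "nonlinear"),
               "saturation_law")
})

test_that("upstream/downstream oxygenation variant adds transfer", {
  tp <- default_params()
  sh <- bump_shape(4.7, 6.8, 31, 76)
  mesh <- build_mesh(sh, resolution = 8)
  fl <- solve_stokes(mesh, 1e-3, 4.13)
  base <- solve_oxygen(mesh, fl, tp)
  extra <- upstream_downstream_nodes(mesh, upstream_um = 10, downstream_um = 10)
  expect_gt(length(extra), 0)
  more <- solve_oxygen(mesh, fl, tp, extra_oxygenated_nodes = extra)
  expect_gt(more$N, base$N)
})
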
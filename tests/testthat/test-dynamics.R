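test_that("solids rate vanishes at steady state and tracks net fluxes", {
  w0 <- worm_params(tau_s = 0.1, E_c = 1, E_i = 1)
  r0 <- root_params(R_g = 0.001, R_d = 0.001)
  expect_equal(solids_rate(r0, w0, V_t = 30, gamma_s = 2.7), 0)
  r1 <- root_params(R_g = 0.0022, R_d = 0.001, gamma_r = 1.2)
  expect_equal(solids_rate(r1, w0, V_t = 1, gamma_s = 2.7), 0.001)
  w1 <- worm_params(tau_s = 0.1, E_c = 0.5, E_i = 1.5)
  expect_equal(solids_rate(r0, w1, V_t = 1, gamma_s = 2.0), -0.5)
})

test_that("pore-change factor columns each sum to -1", {
  set.seed(31)
  for (i in 1:20) {
    s_mic <- runif(1)
    sh <- c(mic = s_mic, mes = 1 - s_mic)
    w <- worm_params(tau_s = 0.1, eps_casts = runif(1, 0.2, 1),
                     f_casts_mic = runif(1))
    r <- root_params(f_r_c = runif(1))
    m <- table3_factors(sh, eps = runif(1, 0.3, 1), w, r)
    expect_equal(unname(colSums(m)), rep(-1, 4), tolerance = 1e-14)
  }
})

test_that("root-decay factors follow the coarse-root fraction", {
  sh <- structural_shares(0.08, 0.02, 0.8)
  w <- worm_params(tau_s = 0.1, eps_casts = 0.6, f_casts_mic = 0.8)
  m <- table3_factors(sh, eps = 0.6, w, root_params(f_r_c = 0.2))
  expect_equal(unname(m[, "root_decay"]), c(0, -0.8, -0.2))
})

test_that("casting and ingestion factors coincide at exchange equilibrium", {
  # casts indistinguishable from the matrix they replace: the two columns
  # are identical, so their difference in the class-rate equation vanishes
  s_mic <- 0.845
  sh <- c(mic = s_mic, mes = 1 - s_mic)
  w <- worm_params(tau_s = 0.1, eps_casts = 0.714, f_casts_mic = s_mic)
  m <- table3_factors(sh, eps = w$eps_casts, w, root_params())
  expect_equal(unname(m[, "worm_casting"]), unname(m[, "worm_ingestion"]),
               tolerance = 1e-14)
})

test_that("degenerate structural pools fall back to the textural split", {
  expect_equal(structural_shares(0, 0, 0.8), c(mic = 0.8, mes = 0.2))
  expect_equal(structural_shares(3, 1, 0.5), c(mic = 0.75, mes = 0.25))
})

test_that("pore-change bookkeeping conserves or grows volume as factors say", {
  # factors summing to -1 conserve V_t for any agent mix
  set.seed(32)
  for (i in 1:20) {
    f1 <- runif(3, -1, 1); f1 <- f1 - (sum(f1) + 1) / 3
    f2 <- runif(3, -1, 1); f2 <- f2 - (sum(f2) + 1) / 3
    dv <- stats::setNames(runif(2, -2, 2), c("a", "b"))
    step <- pore_change_step(dv, list(a = f1, b = f2))
    expect_equal(step$dV_t, 0, tolerance = 1e-12)
  }
  # microbial aggregation: factors >> 0 grow pore and total volume
  som <- pore_change_step(c(som = 1), list(som = c(mic = 0, mes = 1, mac = 2)))
  expect_equal(som$dV_t, 4)
  expect_equal(som$dV_ps_mes + som$dV_ps_mic + som$dV_mac, 3)
  # root decay moves solid volume into meso- and macropores
  dec <- pore_change_step(c(root_decay = -1),
                          list(root_decay = c(mic = 0, mes = -0.8,
                                              mac = -0.2)))
  expect_equal(dec$dV_ps_mic, 0)
  expect_equal(dec$dV_ps_mes, 0.8)
  expect_equal(dec$dV_mac, 0.2)
  expect_equal(dec$dV_t, 0)
  expect_error(pore_change_step(c(x = 1), list(y = c(0, 0, 0))), "factors")
})

test_that("swell-shrink follows the shrinkage characteristic slope", {
  expect_equal(swell_shrink_step(-5, 0), 0)
  expect_equal(swell_shrink_step(-2, 1), -2)
  expect_equal(swell_shrink_step(4, 0.5), 2)
  expect_error(swell_shrink_step(1, 1.2), "f_slope")
})

test_that("steady-flux class rates sum to zero and vanish in the bare case", {
  sc <- scenario_params()
  init <- scenario_initial()
  p <- porosities(init, sc$gamma_s)
  rates <- steady_flux_rates(p, sc$roots, sc$worms, sc$gamma_s)
  expect_equal(sum(rates), 0, tolerance = 1e-15)
  expect_gt(rates[["dphi_mac"]], 0)  # recovery starts from zero macroporosity
  # no roots, casts matching the matrix: macropore rate is zero
  ss <- steady_state(root_params(), sc$worms, sc$phi, sc$phi_min,
                     sc$f_t_mic, sc$gamma_s)
  r2 <- steady_flux_rates(ss, root_params(), sc$worms, sc$gamma_s)
  expect_equal(r2[["dphi_mac"]], 0, tolerance = 1e-14)
})

test_that("closed-form steady state is a fixed point of the flux rates", {
  sc <- scenario_params()
  ss <- steady_state(sc$roots, sc$worms, sc$phi, sc$phi_min, sc$f_t_mic,
                     sc$gamma_s)
  expect_equal(ss$phi_mac, 0.0416666667, tolerance = 1e-8)
  rates <- steady_flux_rates(ss, sc$roots, sc$worms, sc$gamma_s)
  expect_equal(unname(rates), c(0, 0, 0), tolerance = 1e-10)
})

test_that("bare-soil steady-state matrix void ratio equals the cast void ratio", {
  w <- worm_params(tau_s = 0.08, eps_casts = 0.6, f_casts_mic = 0.7)
  ss <- steady_state(root_params(), w, phi = 0.4, phi_min = 0.3,
                     f_t_mic = 0.8, gamma_s = 2.7)
  expect_identical(ss$eps, w$eps_casts)
  expect_equal(ss$phi_mat, (1 - 0.4) * 0.6)
  expect_equal(ss$phi_mac, 0.04)
})

test_that("infeasible steady states raise explicit errors", {
  # crushing root compression at negligible bioturbation
  r <- root_params(B_r = 0.5, tau_r = 1, gamma_r = 1.2, f_r_c = 1)
  w <- worm_params(tau_s = 1e-4, eps_casts = 0.6, f_casts_mic = 0.8)
  expect_error(steady_state(r, w, 0.4, 0.3, 0.8, 2.7), "infeasible")
})

test_that("turnover rate scales with ingestion and biomass", {
  expect_equal(turnover_rate(1000, 2e-4, 1.5), 0.13333333, tolerance = 1e-7)
  expect_equal(turnover_rate(1000, 0, 1.5), 0)
  expect_equal(turnover_rate(2000, 2e-4, 1.5),
               2 * turnover_rate(1000, 2e-4, 1.5))
  expect_error(turnover_rate(1000, 2e-4, 0), "gamma_b")
})

test_that("surface-cast fraction is a clipped linear threshold", {
  expect_equal(surface_cast_fraction(0, 0.057), 1)
  expect_equal(surface_cast_fraction(0.057, 0.057), 0)
  expect_equal(surface_cast_fraction(0.057 / 2, 0.057), 0.5)
  expect_equal(surface_cast_fraction(0.2, 0.057), 0)
  expect_error(surface_cast_fraction(0.01, 0), "phi_mac_c")
})

test_that("bioturbation volume rates conserve solids and match the parcel oracle", {
  fx <- recovery_fixture()
  w <- worm_params(I_r = fx$truth$I_r, E_bio = fx$fixed$E_bio,
                   eps_casts = fx$truth$eps_casts,
                   f_casts_mic = fx$truth$f_casts_mic,
                   phi_mac_c = fx$truth$phi_mac_c)
  rates <- bioturbation_volume_rates(fx$initial, w, fx$fixed$gamma_s)
  oracle <- oracle_parcel_rates(fx$initial, w, fx$fixed$gamma_s, dt = 1e-4)
  for (f in c("dV_mac", "dV_ps_mes", "dV_ps_mic", "dV_t"))
    expect_equal(rates[[f]], oracle[[f]], tolerance = 1e-3, label = f)
  # internal-only casting (macroporosity above threshold) conserves V_t
  st2 <- state_from_porosities(0.36, 0.03, 0.08, 0.35, 0.966, 30)
  r2 <- bioturbation_volume_rates(st2, w, fx$fixed$gamma_s)
  expect_equal(r2$f_surf, 0)
  expect_equal(r2$dV_t, 0)
  expect_equal(r2$dV_mac + r2$dV_ps_mes + r2$dV_ps_mic, 0, tolerance = 1e-12)
})

test_that("fully surface-casting worms grow the soil volume by the cast bulk", {
  fx <- recovery_fixture()
  st <- state_from_porosities(0.36, 0.012, 0, 0.35, 0.966, 30)
  w <- worm_params(I_r = 2, E_bio = fx$fixed$E_bio, eps_casts = 0.714,
                   f_casts_mic = 0.845, phi_mac_c = 0.057)
  r <- bioturbation_volume_rates(st, w, fx$fixed$gamma_s)
  expect_equal(r$f_surf, 1)
  # all pore creation equals the total volume growth when every cast is
  # deposited at the surface, net of the ingestion-egestion pore exchange
  Q <- total_volume(st) * 2 * 365 * fx$fixed$E_bio / fx$fixed$gamma_s
  expect_equal(r$dV_t, Q * (1 + w$eps_casts), tolerance = 1e-12)
  expect_equal(r$dV_mac + r$dV_ps_mes + r$dV_ps_mic,
               Q * (1 + w$eps_casts), tolerance = 1e-12)
})

test_that("exchange equilibrium has zero rates everywhere", {
  # cast void ratio equal to matrix void ratio, cast pore split equal to
  # the structural split, macroporosity above the casting threshold
  st <- state_from_porosities(0.34, 0.10, 0.10, 0.3, 0.8, 30)
  p <- porosities(st, 2.7)
  eps <- p$phi_mat / (1 - p$phi)
  sh <- structural_shares(st$V_ps_mic, st$V_ps_mes, st$f_t_mic)
  w <- worm_params(I_r = 1, E_bio = 2e-4, eps_casts = eps,
                   f_casts_mic = sh[["mic"]], phi_mac_c = 0.05)
  r <- bioturbation_volume_rates(st, w, 2.7)
  expect_equal(r$dV_mac, 0, tolerance = 1e-12)
  expect_equal(r$dV_ps_mes, 0, tolerance = 1e-12)
  expect_equal(r$dV_ps_mic, 0, tolerance = 1e-12)
})
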
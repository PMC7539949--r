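test_that("retention curve hits its limits and is monotone", {
  p <- retention_params(0.588, 0.77, 1.08)
  expect_equal(vg_theta(0, p), 0.588)
  expect_error(vg_theta(5, p), "psi")
  set.seed(21)
  for (i in 1:20) {
    p <- retention_params(runif(1, 0.3, 0.6), runif(1, 0.01, 2),
                          runif(1, 1.05, 2.5))
    psi <- -sort(10^runif(50, -1, 5))
    th <- vg_theta(psi, p)
    expect_true(all(th <= p$phi_mat + 1e-15))
    expect_true(all(diff(th[order(abs(psi))]) <= 1e-15))
  }
})

test_that("alpha from pore pools inverts the curve at the class boundary", {
  # frozen values computed by bisection on the raw retention expression
  expect_equal(alpha_from_pools(0.415, 0.588, 1.08, -100), 0.7726025386,
               tolerance = 1e-9)
  expect_equal(alpha_from_pools(0.413, 0.565, 1.08, -100), 0.4958367048,
               tolerance = 1e-9)
  expect_equal(vg_theta(-100, retention_params(0.588, 0.7726025386, 1.08)),
               0.415, tolerance = 1e-9)
  expect_equal(alpha_from_pools(0.5, 0.5, 1.2), 0)
  expect_error(alpha_from_pools(0.6, 0.5, 1.2), "exceed")
  # round trip on random pools
  set.seed(22)
  for (i in 1:25) {
    phi_mat <- runif(1, 0.3, 0.6)
    phi_mic <- runif(1, 0.5, 0.999) * phi_mat
    n <- runif(1, 1.05, 2.5)
    psi_b <- -runif(1, 30, 300)
    a <- alpha_from_pools(phi_mic, phi_mat, n, psi_b)
    expect_equal(vg_theta(psi_b, retention_params(phi_mat, a, n)), phi_mic,
                 tolerance = 1e-10)
  }
})

test_that("alpha matches the bisection oracle on the treatment pools", {
  pools <- treatment_pools()
  for (k in seq_len(nrow(pools))) {
    a_pkg <- alpha_from_pools(pools$phi_mic[k], pools$phi_mat[k], 1.08)
    a_orc <- oracle_alpha(pools$phi_mic[k], pools$phi_mat[k], 1.08)
    expect_equal(a_pkg, a_orc, tolerance = 1e-9)
  }
})

test_that("pressure head converts to equivalent pore diameter reciprocally", {
  expect_equal(psi_to_diameter(-100), 30)
  expect_equal(psi_to_diameter(-30), 100)
  expect_equal(psi_to_diameter(-3000), 1)
  psi <- -10^seq(0, 4, by = 0.5)
  expect_equal(psi_to_diameter(psi) * abs(psi), rep(3000, length(psi)))
  expect_error(psi_to_diameter(0), "psi")
})

test_that("conductivity ratio is the squared alpha ratio", {
  expect_equal(ksat_ratio(0.4, 0.4), 1)
  expect_equal(ksat_ratio(2, 1), 4)
  expect_error(ksat_ratio(1, 0), "alpha_2")
})

test_that("shared-n fit recovers noiseless generating parameters", {
  truth <- data.frame(label = c("g1", "g2"),
                      phi_mat = c(0.52, 0.44),
                      alpha = c(0.3, 0.05), n = 1.15)
  d <- gen_retention(truth, replicates = 1, noise_sd = 0, seed = 5)
  fit <- fit_shared_n(d, n_fixed = 1.15, exclude_psi = -2.5)
  expect_equal(fit$params$phi_mat, truth$phi_mat, tolerance = 1e-6)
  expect_equal(fit$params$alpha, truth$alpha, tolerance = 1e-6)
  # shared n as a free parameter is also recovered
  fit_free <- fit_shared_n(d, n_fixed = NULL, exclude_psi = -2.5)
  expect_equal(fit_free$n, 1.15, tolerance = 1e-4)
})

test_that("noisy-replicate recovery respects the information limit", {
  truth <- data.frame(label = c("g1", "g2"),
                      phi_mat = c(0.588, 0.565),
                      alpha = c(0.77, 0.50), n = 1.08)
  # centred replicate scatter keeps the per-head mean on the curve, so the
  # pooled fit recovers the generating parameters essentially exactly
  dc <- gen_retention(truth, replicates = 12, noise_sd = 0.01,
                      center_noise = TRUE, seed = 7)
  fitc <- fit_shared_n(dc, n_fixed = 1.08, exclude_psi = -2.5)
  expect_equal(fitc$params$phi_mat, truth$phi_mat, tolerance = 1e-5)
  # uncentred noise: at n = 1.08 the linearized SE of phi_mat is about
  # 2.6x the point noise (phi_mat-alpha correlation 0.998), so recovery is
  # asserted at 3x that SE, the precision the data actually support
  d <- gen_retention(truth, replicates = 12, noise_sd = 0.002, seed = 7)
  fit <- fit_shared_n(d, n_fixed = 1.08, exclude_psi = -2.5)
  expect_equal(fit$params$phi_mat, truth$phi_mat,
               tolerance = 3 * 2.6 * 0.002 / 0.565)
  expect_lt(max(fit$params$rmse), 0.005)
})

test_that("excluded heads are dropped and sparse curves rejected", {
  truth <- data.frame(label = "g", phi_mat = 0.5, alpha = 0.2, n = 1.2)
  d <- gen_retention(truth, replicates = 1, noise_sd = 0,
                     sat_excess = 0.1, seed = 1)
  # the saturation-excess point at -2.5 cm would bias the fit if retained
  fit_ex <- fit_shared_n(d, n_fixed = 1.2, exclude_psi = -2.5)
  expect_equal(fit_ex$params$phi_mat, 0.5, tolerance = 1e-6)
  fit_in <- fit_shared_n(d, n_fixed = 1.2, exclude_psi = numeric(0))
  expect_gt(abs(fit_in$params$phi_mat - 0.5), 1e-3)
  expect_equal(fit_ex$params$n_points, 7L)
  d3 <- d[d$psi_cm %in% c(-2.5, -10, -100), ]
  expect_error(fit_shared_n(d3, n_fixed = 1.2, exclude_psi = -2.5),
               "at least 3")
})

test_that("pore classification reproduces the treatment class partition", {
  pools <- treatment_pools()
  for (k in seq_len(nrow(pools))) {
    row <- pools[k, ]
    a <- alpha_from_pools(row$phi_mic, row$phi_mat, 1.08)
    tab <- classify_pores(retention_params(row$phi_mat, a, 1.08),
                          psi_mic_mes = -100, phi_min = 0.3,
                          f_t_mic = 0.295 / 0.3)
    for (col in c("phi_t_mic", "phi_t_mes", "phi_t", "phi_s_mic",
                  "phi_s_mes", "phi_s", "phi_mic", "phi_mes", "phi_mat"))
      expect_equal(tab[[col]], row[[col]], tolerance = 1e-6,
                   label = paste(row$label, col))
  }
})

test_that("classification degenerates cleanly and flags impossible splits", {
  # matrix porosity equal to the minimum: all structural entries zero
  p <- retention_params(0.3, 0.2, 1.2)
  phi_mic <- vg_theta(-100, p)
  tab <- classify_pores(p, phi_min = 0.3, f_t_mic = phi_mic / 0.3)
  expect_equal(tab$phi_s_mic, 0, tolerance = 1e-12)
  expect_equal(tab$phi_s_mes, 0, tolerance = 1e-12)
  # textural micropores exceeding total micropores is an error
  expect_error(classify_pores(retention_params(0.5, 2, 1.6),
                              phi_min = 0.3, f_t_mic = 1),
               "micropore")
})

test_that("retention data round-trip through CSV with metadata", {
  truth <- data.frame(label = "g", phi_mat = 0.5, alpha = 0.2, n = 1.2)
  d <- gen_retention(truth, replicates = 2, noise_sd = 0.005, seed = 9)
  path <- withr::local_tempfile(fileext = ".csv")
  write_retention(d, path, meta = c("synthetic", "seed=9"))
  d2 <- read_retention(path)
  expect_equal(d2$theta, d$theta, tolerance = 1e-12)
  expect_identical(readLines(path, n = 1), "# synthetic")
})
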
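#' Generate synthetic replicate retention curves with known ground truth
#'
#' Evaluates the matrix retention curve for each group at a ladder of
#' measurement pressure heads and adds independent Gaussian measurement
#' noise, truncated to the physical range `[0, 1]`.  This emulates a
#' replicated laboratory retention data set (sand box + pressure plate):
#' near saturation (heads above the macropore drainage limit) an optional
#' saturation excess can be added to mimic water held in structural
#' macropores, which the matrix curve deliberately does not describe — the
#' reason such points are excluded from fitting.
#'
#' @param truth Data frame with columns `label`, `phi_mat`, `alpha`, `n`
#'   (one row per group).
#' @param psi_heads Measurement heads, cm (<= 0).
#' @param replicates Number of replicate samples per group.
#' @param noise_sd Gaussian noise standard deviation on water content,
#'   cm^3/cm^3.
#' @param sat_excess Extra water content added at heads shallower than
#'   `-5` cm (macropore water), cm^3/cm^3.
#' @param center_noise If `TRUE`, the replicate noise at each head is
#'   centred (its per-head mean subtracted), so the replicate scatter is
#'   preserved but the per-head treatment mean lies exactly on the
#'   generating curve.  Use this to emulate a *fixed* measured data set
#'   whose mean curve is known: the pooled least-squares optimum of such
#'   data coincides exactly with the generating parameters.  With ordinary
#'   uncentred noise (`FALSE`, the default) the near-flat curve at small n
#'   makes `phi_mat` weakly identified (its sampling SE is roughly 2.6x the
#'   point noise at n = 1.08), which is the realistic setting for
#'   robustness experiments.
#' @param seed Integer seed; recorded in the `spec` attribute.
#' @return Data frame `label`, `replicate`, `psi_cm`, `theta` with
#'   attributes `truth` (the generating parameters) and `spec` (generator
#'   settings incl. seed).
#' @export
gen_retention <- function(truth,
                          psi_heads = c(-2.5, -10, -30, -60, -100, -300,
                                        -1000, -15000),
                          replicates = 12, noise_sd = 0.01,
                          sat_excess = 0, center_noise = FALSE, seed = 1) {
  stopifnot(all(c("label", "phi_mat", "alpha", "n") %in% names(truth)),
            replicates >= 1, noise_sd >= 0)
  set.seed(seed)
  rows <- list()
  for (g in seq_len(nrow(truth))) {
    p <- retention_params(truth$phi_mat[g], truth$alpha[g], truth$n[g])
    theta0 <- vg_theta(psi_heads, p)
    theta0 <- theta0 + ifelse(psi_heads > -5, sat_excess, 0)
    e <- matrix(stats::rnorm(replicates * length(psi_heads), 0, noise_sd),
                nrow = replicates)
    if (center_noise && replicates > 1)
      e <- sweep(e, 2, colMeans(e))
    for (r in seq_len(replicates)) {
      rows[[length(rows) + 1L]] <- data.frame(
        label = truth$label[g], replicate = r,
        psi_cm = psi_heads, theta = pmin(pmax(theta0 + e[r, ], 0), 1))
    }
  }
  out <- do.call(rbind, rows)
  attr(out, "truth") <- truth
  attr(out, "spec") <- list(kind = "retention", psi_heads = psi_heads,
                            replicates = replicates, noise_sd = noise_sd,
                            sat_excess = sat_excess,
                            center_noise = center_noise, seed = seed)
  out
}

#' Generate a synthetic compaction-recovery observation series
#'
#' Forward-simulates the bare-soil surface-casting model from a compacted
#' initial state with known parameters, samples the four observables at the
#' given times, and adds truncated Gaussian noise.  Optionally generates a
#' drifting control-plot series (a smooth multiplicative drift applied to
#' the initial observables) so that [normalize_to_control()] can be
#' exercised: normalizing data generated with drift recovers the no-drift
#' series.  Before noise is added the generated rows satisfy
#' `theta_100 <= theta_30 <= porosity` by construction.
#'
#' @param pars Named list or vector with `I_r` (g/g/day), `eps_casts`,
#'   `f_casts_mic`, `phi_mac_c`.
#' @param fixed List with `gamma_s`, `E_bio`, `phi_min`, `f_t_mic`,
#'   optionally `layer_thickness`.
#' @param initial Initial [pore_space_state()] (compacted).
#' @param times Observation times, yr since compaction.
#' @param noise_sd Named vector of noise standard deviations per observable
#'   (any subset of `bulk_density`, `porosity`, `theta_30`, `theta_100`);
#'   a single number is recycled.  Use 0 for noiseless series.
#' @param control_drift Peak relative drift of the control plot over the
#'   observation period (0 = constant control).
#' @param seed Integer seed.
#' @param dt Forward-integration step, yr.
#' @return Data frame with columns `time_yr`, `plot`, `bulk_density`,
#'   `porosity`, `theta_30`, `theta_100` and `sd_*` columns; attributes
#'   `truth` (generating parameters) and `spec`.
#' @export
gen_recovery <- function(pars, fixed, initial,
                         times = seq(0, 4, by = 0.5),
                         noise_sd = c(bulk_density = 0.03, porosity = 0.01,
                                      theta_30 = 0.01, theta_100 = 0.01),
                         control_drift = 0, seed = 1, dt = 0.02) {
  pars <- as.list(pars)
  vars <- c("bulk_density", "porosity", "theta_30", "theta_100")
  if (length(noise_sd) == 1) noise_sd <- stats::setNames(rep(noise_sd, 4), vars)
  noise_sd <- noise_sd[vars]
  if (any(noise_sd < 0)) stop("`noise_sd` must be >= 0", call. = FALSE)
  sim <- .forward_recovery(pars$I_r, pars$eps_casts, pars$f_casts_mic,
                           pars$phi_mac_c, E_bio = fixed$E_bio,
                           initial = initial, gamma_s = fixed$gamma_s,
                           times = times, dt = dt)
  if (is.null(sim))
    stop("infeasible forward parameters for recovery generator",
         call. = FALSE)
  V_pt <- initial$V_p_textural
  f_t_mic <- initial$f_t_mic
  phi_mic <- (sim[, "V_ps_mic"] + f_t_mic * V_pt) / sim[, "V_t"]
  phi_mat <- phi_mic + (sim[, "V_ps_mes"] + (1 - f_t_mic) * V_pt) / sim[, "V_t"]
  phi <- phi_mat + sim[, "V_mac"] / sim[, "V_t"]
  clean <- data.frame(time_yr = times, plot = "compacted",
                      bulk_density = fixed$gamma_s * (1 - phi),
                      porosity = phi, theta_30 = phi_mat,
                      theta_100 = phi_mic)
  stopifnot(all(clean$theta_100 <= clean$theta_30 + 1e-12),
            all(clean$theta_30 <= clean$porosity + 1e-12))

  set.seed(seed)
  noisy <- clean
  for (v in vars) {
    noisy[[v]] <- pmax(clean[[v]] +
                         stats::rnorm(nrow(clean), 0, noise_sd[[v]]), 0)
    noisy[[paste0("sd_", v)]] <- noise_sd[[v]]
  }
  # control plot: initial observables under a smooth multiplicative drift
  drift <- 1 + control_drift * sin(pi * times / max(max(times), 1e-9))
  ctrl <- data.frame(time_yr = times, plot = "control",
                     bulk_density = clean$bulk_density[1] * drift,
                     porosity = clean$porosity[1] * drift,
                     theta_30 = clean$theta_30[1] * drift,
                     theta_100 = clean$theta_100[1] * drift)
  for (v in vars) ctrl[[paste0("sd_", v)]] <- noise_sd[[v]]
  out <- rbind(noisy, ctrl)
  attr(out, "truth") <- pars
  attr(out, "spec") <- list(kind = "recovery", times = times,
                            noise_sd = noise_sd,
                            control_drift = control_drift, seed = seed,
                            fixed = fixed)
  attr(out, "clean") <- clean
  out
}
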
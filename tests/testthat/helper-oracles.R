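# Independent oracles used to freeze expected values.  These deliberately
# avoid the package's own code paths.

# Solve the retention curve numerically for alpha such that
# theta(psi) = phi_mic, by bisection on the raw van Genuchten expression.
oracle_alpha <- function(phi_mic, phi_mat, n, psi = -100) {
  f <- function(a) phi_mat * (1 + (a * abs(psi))^n)^(1 / n - 1) - phi_mic
  stats::uniroot(f, c(1e-8, 50), tol = 1e-14)$root
}

# Discrete parcel-moving bookkeeping for one bioturbation step of length dt:
# ingest a parcel of solids, delete the enclosing matrix volume (creating a
# macropore), egest casts into macropores and at the surface, and tally the
# volume changes.  Returns per-year rates.
oracle_parcel_rates <- function(state, worms, gamma_s, dt) {
  V_t <- total_volume(state)
  V_mat_pore <- state$V_ps_mic + state$V_ps_mes + state$V_p_textural
  phi <- (V_mat_pore + state$V_mac) / V_t
  eps <- (V_mat_pore / V_t) / (1 - phi)
  ss <- state$V_ps_mic + state$V_ps_mes
  s_mic <- if (ss > 1e-12) state$V_ps_mic / ss else state$f_t_mic
  f_surf <- if (is.finite(worms$phi_mac_c))
    max(0, 1 - (state$V_mac / V_t) / worms$phi_mac_c) else 0
  q <- V_t * (worms$I_r * 365) * worms$E_bio / gamma_s * dt  # solids parcel

  d_mic <- d_mes <- d_mac <- d_Vt <- 0
  # ingestion: remove (1+eps) q of matrix, leave a macropore of that size
  d_mic <- d_mic - s_mic * eps * q
  d_mes <- d_mes - (1 - s_mic) * eps * q
  d_mac <- d_mac + (1 + eps) * q
  # egestion: cast bulk (1+eps_casts) q; internal casts fill macropores,
  # surface casts add new soil volume; cast pores join the matrix classes
  ec <- worms$eps_casts
  d_mac <- d_mac - (1 - f_surf) * (1 + ec) * q
  d_mic <- d_mic + worms$f_casts_mic * ec * q
  d_mes <- d_mes + (1 - worms$f_casts_mic) * ec * q
  d_Vt <- d_Vt + f_surf * (1 + ec) * q
  list(dV_ps_mic = d_mic / dt, dV_ps_mes = d_mes / dt,
       dV_mac = d_mac / dt, dV_t = d_Vt / dt)
}
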
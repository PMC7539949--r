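#' Simulate soil structure dynamics
#'
#' Integrates the pore-volume ODE system forward in time in one of two
#' regimes:
#'
#' * `mode = "steady-flux"`: root biomass and within-soil casting are at
#'   steady state (`R_g = R_d`, `E_c = E_i`), so solids, total volume and
#'   total porosity are constant while pore volume is redistributed between
#'   the micro-, meso- and macropore classes (the long-term recovery
#'   scenarios).
#' * `mode = "surface-casting"`: bare soil (`B_r = 0`), earthworms ingest
#'   matrix soil and cast partly at the surface ([surface_cast_fraction()]),
#'   so the total soil volume and layer thickness grow while the solid
#'   volume is conserved.  The total worm biomass is conserved: the biomass
#'   concentration is recomputed as `E_bio(t) = E_bio(0) * V_t(0) / V_t(t)`,
#'   so the gut flux stays proportional to the (fixed) biomass rather than
#'   to the growing soil volume.
#'
#' The matrix void ratio `eps = phi_mat / (1 - phi)` and the bulk density
#' `gamma_b = gamma_s (1 - phi)` are re-evaluated from the current state at
#' every step.
#'
#' The default integrator is an adaptive Runge-Kutta (Cash-Karp 4/5 via
#' \pkg{deSolve}) with maximum step 0.05 yr and absolute tolerance 1e-9 on
#' volumes; `method = "rk4"` and `method = "euler"` run fixed-step schemes
#' with step `dt` (the Euler scheme is the natural comparator for discrete
#' parcel-moving bookkeeping).
#'
#' @param initial A [pore_space_state()] at time 0.
#' @param roots A [root_params()]; ignored (treated as absent) in
#'   surface-casting mode.
#' @param worms A [worm_params()].
#' @param gamma_s Particle density, g/cm^3.
#' @param t_end Simulation horizon, yr.
#' @param dt_out Output interval, yr.
#' @param mode `"steady-flux"` or `"surface-casting"`.
#' @param method `"adaptive"`, `"rk4"` or `"euler"`.
#' @param dt Fixed step for `"rk4"`/`"euler"`, yr.
#' @return A `pore_trajectory`: a data frame with columns `time`,
#'   `phi_mic`, `phi_mes`, `phi_mac`, `phi_mat`, `phi`, `phi_s_mic`,
#'   `phi_s_mes`, `bulk_density`, `layer_thickness`, `f_surf` and the state
#'   volumes `V_ps_mic`, `V_ps_mes`, `V_mac`, `V_t`.  The attributes
#'   `initial`, `gamma_s` and `mode` carry the run setup.
#' @export
simulate_structure <- function(initial, roots = root_params(), worms,
                               gamma_s, t_end, dt_out = 0.5,
                               mode = c("steady-flux", "surface-casting"),
                               method = c("adaptive", "rk4", "euler"),
                               dt = 0.01) {
  mode <- match.arg(mode)
  method <- match.arg(method)
  if (t_end <= 0) stop("`t_end` must be positive", call. = FALSE)
  times <- unique(c(seq(0, t_end, by = dt_out), t_end))

  V_t0 <- total_volume(initial)
  V_pt <- initial$V_p_textural
  V_s <- initial$V_s_mineral + initial$V_s_organic
  f_t_mic <- initial$f_t_mic
  # conserved worm biomass (surface-casting mode)
  M_bio <- if (!is.null(worms$E_bio)) worms$E_bio * V_t0 else NA_real_

  deriv <- function(t, y, parms) {
    V_ps_mic <- y[1]; V_ps_mes <- y[2]; V_mac <- y[3]; V_t <- y[4]
    V_mat_p <- V_ps_mic + V_ps_mes + V_pt
    phi <- (V_mat_p + V_mac) / V_t
    phi_mat <- V_mat_p / V_t
    eps <- phi_mat / (1 - phi)
    gamma_b <- gamma_s * (1 - phi)
    sh <- structural_shares(V_ps_mic, V_ps_mes, f_t_mic)
    if (mode == "steady-flux") {
      tau_s <- worm_tau_s(worms, gamma_b)
      root_term <- roots$B_r * roots$tau_r / roots$gamma_r
      worm_term <- gamma_b * tau_s / gamma_s
      ec <- worms$eps_casts; fcm <- worms$f_casts_mic
      d_mac <- (roots$f_r_c * root_term + (eps - ec) * worm_term) * V_t
      d_mes <- ((1 - roots$f_r_c - sh[["mes"]]) * root_term +
                  ((1 - fcm) * ec - sh[["mes"]] * eps) * worm_term) * V_t
      d_mic <- (-sh[["mic"]] * root_term +
                  (fcm * ec - sh[["mic"]] * eps) * worm_term) * V_t
      list(c(d_mic, d_mes, d_mac, 0))
    } else {
      ec <- worms$eps_casts; fcm <- worms$f_casts_mic
      Q <- if (!is.null(worms$I_r) && is.finite(M_bio))
        per_day_to_per_year(worms$I_r) * M_bio / gamma_s
      else worm_tau_s(worms, gamma_b) * gamma_b * V_t / gamma_s
      f_surf <- if (is.finite(worms$phi_mac_c))
        surface_cast_fraction(V_mac / V_t, worms$phi_mac_c) else 0
      d_mic <- Q * (fcm * ec - sh[["mic"]] * eps)
      d_mes <- Q * ((1 - fcm) * ec - sh[["mes"]] * eps)
      d_mac <- Q * (eps - ec + f_surf * (1 + ec))
      list(c(d_mic, d_mes, d_mac, Q * f_surf * (1 + ec)))
    }
  }

  y0 <- c(initial$V_ps_mic, initial$V_ps_mes, initial$V_mac, V_t0)
  sol <- switch(method,
    adaptive = deSolve::ode(y0, times, deriv, parms = NULL, method = "ode45",
                            hmax = 0.05, atol = 1e-9, rtol = 1e-10),
    rk4 = deSolve::rk4(y0, unique(sort(c(times, seq(0, t_end, by = dt)))),
                       deriv, parms = NULL),
    euler = deSolve::euler(y0, unique(sort(c(times, seq(0, t_end, by = dt)))),
                           deriv, parms = NULL))
  sol <- sol[sol[, 1] %in% times, , drop = FALSE]

  traj <- as.data.frame(sol)
  names(traj) <- c("time", "V_ps_mic", "V_ps_mes", "V_mac", "V_t")
  # clamp ODE round-off per the negative-volume guard
  for (v in c("V_ps_mic", "V_ps_mes", "V_mac")) {
    bad <- traj[[v]] < 0
    if (any(traj[[v]] < -1e-9 * traj$V_t))
      stop("integration produced a negative ", v, call. = FALSE)
    traj[[v]][bad] <- 0
  }
  V_mat_p <- traj$V_ps_mic + traj$V_ps_mes + V_pt
  traj$phi_mic <- (traj$V_ps_mic + f_t_mic * V_pt) / traj$V_t
  traj$phi_mes <- (traj$V_ps_mes + (1 - f_t_mic) * V_pt) / traj$V_t
  traj$phi_mac <- traj$V_mac / traj$V_t
  traj$phi_mat <- traj$phi_mic + traj$phi_mes
  traj$phi <- traj$phi_mat + traj$phi_mac
  traj$phi_s_mic <- traj$V_ps_mic / traj$V_t
  traj$phi_s_mes <- traj$V_ps_mes / traj$V_t
  traj$bulk_density <- gamma_s * (1 - traj$phi)
  traj$layer_thickness <- traj$V_t / initial$A_xs
  traj$f_surf <- if (mode == "surface-casting" && is.finite(worms$phi_mac_c))
    surface_cast_fraction(traj$phi_mac, worms$phi_mac_c) else 0
  structure(traj, class = c("pore_trajectory", "data.frame"),
            initial = initial, gamma_s = gamma_s, mode = mode)
}

#' Extract the pore-space state at one output time of a trajectory
#'
#' @param traj A `pore_trajectory`.
#' @param time Requested output time, yr (must match an output row).
#' @return A [pore_space_state()].
#' @export
state_at <- function(traj, time) {
  i <- which(abs(traj$time - time) < 1e-9)
  if (!length(i)) stop("no output at time ", time, call. = FALSE)
  i <- i[1]
  init <- attr(traj, "initial")
  V_s <- init$V_s_mineral + init$V_s_organic
  pore_space_state(V_s_mineral = init$V_s_mineral,
                   V_s_organic = init$V_s_organic,
                   V_p_textural = init$V_p_textural,
                   V_ps_mic = traj$V_ps_mic[i], V_ps_mes = traj$V_ps_mes[i],
                   V_mac = traj$V_mac[i],
                   f_t_mic = init$f_t_mic, a_xs = init$A_xs)
}

#' First time a trajectory's macroporosity reaches its equilibrium
#'
#' Scans the trajectory for the first output time at which
#' `|phi_mac(t) - phi_mac*| <= rel_tol * phi_mac*`.  Returns `NA` (with a
#' `reached = FALSE` attribute) if the tolerance is never met — not an
#' error, since slow-recovery scenarios legitimately fail to equilibrate
#' within a simulation horizon.
#'
#' @param traj A `pore_trajectory`.
#' @param target The equilibrium, either a [steady_state()] object or a
#'   numeric `phi_mac*`.
#' @param rel_tol Relative tolerance on macroporosity.
#' @return Time in years, or `NA_real_` if never reached.
#' @export
time_to_equilibrium <- function(traj, target, rel_tol = 0.05) {
  phi_mac_star <- if (is.list(target)) target$phi_mac else target
  ok <- abs(traj$phi_mac - phi_mac_star) <= rel_tol * abs(phi_mac_star)
  if (!any(ok)) return(structure(NA_real_, reached = FALSE))
  structure(traj$time[which(ok)[1]], reached = TRUE)
}

#' Write a trajectory as tidy CSV
#'
#' @param traj A `pore_trajectory`.
#' @param path File path.
#' @export
write_trajectory <- function(traj, path) {
  cols <- c("time", "phi_mac", "phi_mes", "phi_mic", "phi_mat", "phi",
            "bulk_density", "layer_thickness", "f_surf")
  utils::write.csv(as.data.frame(traj)[, cols], path, row.names = FALSE)
  invisible(path)
}

# Fast fixed-step RK4 forward run of the surface-casting model, returning
# the state volumes at each requested time.  Same equations as
# simulate_structure(mode = "surface-casting"); kept as a tight loop because
# the calibration objective evaluates it thousands of times.  Returns NULL
# on an infeasible run (negative volumes) so callers can penalize.
.forward_recovery <- function(I_r_day, eps_casts, f_casts_mic, phi_mac_c,
                              E_bio, initial, gamma_s, times, dt = 0.02) {
  V_pt <- initial$V_p_textural
  f_t_mic <- initial$f_t_mic
  y <- c(initial$V_ps_mic, initial$V_ps_mes, initial$V_mac,
         total_volume(initial))
  Q <- I_r_day * 365 * E_bio * y[4] / gamma_s  # conserved biomass => constant
  deriv <- function(y) {
    V_t <- y[4]
    V_mat_p <- y[1] + y[2] + V_pt
    phi <- (V_mat_p + y[3]) / V_t
    eps <- (V_mat_p / V_t) / (1 - phi)
    fs <- max(0, 1 - (y[3] / V_t) / phi_mac_c)
    ss <- y[1] + y[2]
    s_mic <- if (ss > 1e-12) y[1] / ss else f_t_mic
    c(Q * (f_casts_mic * eps_casts - s_mic * eps),
      Q * ((1 - f_casts_mic) * eps_casts - (1 - s_mic) * eps),
      Q * (eps - eps_casts + fs * (1 + eps_casts)),
      Q * fs * (1 + eps_casts))
  }
  t_end <- max(times)
  nstep <- max(1L, ceiling(t_end / dt))
  h <- t_end / nstep
  out <- matrix(NA_real_, length(times), 4,
                dimnames = list(NULL, c("V_ps_mic", "V_ps_mes",
                                        "V_mac", "V_t")))
  t <- 0; ti <- 1
  for (k in 0:nstep) {
    while (ti <= length(times) && times[ti] <= t + 1e-9) {
      out[ti, ] <- y; ti <- ti + 1
    }
    if (k == nstep) break
    k1 <- deriv(y); k2 <- deriv(y + h / 2 * k1)
    k3 <- deriv(y + h / 2 * k2); k4 <- deriv(y + h * k3)
    y <- y + h / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
    t <- t + h
  }
  if (anyNA(out) || any(out < -1e-9 * out[, "V_t"])) return(NULL)
  out
}
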
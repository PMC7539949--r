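#' Normalize a compacted-plot series by its control plot
#'
#' Field monitoring series often show variation unrelated to the treatment
#' (seasonal wetness, sampling effects).  To isolate the recovery trend,
#' each observed value on the compacted plot is multiplied by the ratio of
#' the *initial* control value to the *current* control value, variable by
#' variable: `v_c(t) * v_ctrl(0) / v_ctrl(t)`.  If the control is constant
#' the series is unchanged.  (The operation is not idempotent for a drifting
#' control: applying it twice rescales twice.)
#'
#' @param compacted,control Observation data frames with columns `time_yr`,
#'   `bulk_density`, `porosity`, `theta_30`, `theta_100` (and optionally
#'   `sd_*` and `plot`).
#' @param time_tol Matching tolerance between compacted and control
#'   observation times, yr.
#' @return The compacted data frame with the four observable columns
#'   normalized.
#' @export
normalize_to_control <- function(compacted, control, time_tol = 0.02) {
  vars <- c("bulk_density", "porosity", "theta_30", "theta_100")
  idx <- vapply(compacted$time_yr, function(t) {
    d <- abs(control$time_yr - t)
    i <- which.min(d)
    if (d[i] > time_tol) NA_integer_ else i
  }, integer(1))
  if (anyNA(idx))
    stop("no control observation within ", time_tol, " yr of compacted ",
         "time(s): ",
         paste(compacted$time_yr[is.na(idx)], collapse = ", "),
         call. = FALSE)
  out <- compacted
  for (v in vars) {
    v0 <- control[[v]][which.min(control$time_yr)]
    vt <- control[[v]][idx]
    if (any(vt == 0)) stop("control value of ", v, " is zero", call. = FALSE)
    out[[v]] <- compacted[[v]] * v0 / vt
  }
  out
}

#' Map a pore-space state to the measured observables
#'
#' With pore classes bounded at 30 and 100 micrometres (pressure heads -100
#' and -30 cm), the water content at -100 cm equals the microporosity (all
#' meso- and macropores drained) and the water content at -30 cm equals the
#' matrix porosity (only macropores drained).  Together with total porosity
#' and bulk density these are the four quantities monitored in
#' compaction-recovery experiments.
#'
#' @param state A [pore_space_state()].
#' @param gamma_s Particle density, g/cm^3.
#' @return Named vector `c(bulk_density, porosity, theta_30, theta_100)`.
#' @export
observables <- function(state, gamma_s) {
  p <- porosities(state, gamma_s)
  c(bulk_density = p$bulk_density, porosity = p$phi,
    theta_30 = p$phi_mat, theta_100 = p$phi_mic)
}

#' Initial pore-space state from the first observation row
#'
#' Inverts [observables()]: `phi_mic = theta_100`,
#' `phi_mes = theta_30 - theta_100`, `phi_mac = porosity - theta_30`, then
#' builds the volume state via [state_from_porosities()].
#'
#' @param obs_row A one-row observation data frame (the post-compaction
#'   measurement).
#' @param phi_min Minimum matrix porosity.
#' @param f_t_mic Textural micropore fraction.
#' @param layer_thickness Layer thickness, cm.
#' @return A [pore_space_state()].
#' @export
initial_state_from_obs <- function(obs_row, phi_min, f_t_mic,
                                   layer_thickness = 30) {
  state_from_porosities(phi_mic = obs_row$theta_100,
                        phi_mes = obs_row$theta_30 - obs_row$theta_100,
                        phi_mac = obs_row$porosity - obs_row$theta_30,
                        phi_min = phi_min, f_t_mic = f_t_mic,
                        layer_thickness = layer_thickness)
}

# per-variable scales for residual standardization: reported sds if
# present, else the sd of the observed series, else its range, else 1.
.obs_scales <- function(obs) {
  vars <- c("bulk_density", "porosity", "theta_30", "theta_100")
  vapply(vars, function(v) {
    sdcol <- paste0("sd_", v)
    s <- if (sdcol %in% names(obs)) mean(obs[[sdcol]], na.rm = TRUE)
    else NA_real_
    if (!is.finite(s) || s <= 0) s <- stats::sd(obs[[v]])
    if (!is.finite(s) || s <= 0) s <- diff(range(obs[[v]]))
    if (!is.finite(s) || s <= 0) s <- 1
    s
  }, numeric(1))
}

#' Calibration objective for the surface-casting recovery model
#'
#' Forward-simulates the bare-soil surface-casting model from the initial
#' state to the observation times and returns the sum of squared residuals
#' over the four observables, each standardized by its per-variable scale
#' (reported standard deviations if available, otherwise the spread of the
#' series) so that bulk density (~1.5 g/cm^3) does not dominate porosity
#' residuals (~0.05 cm^3/cm^3).  Infeasible forward runs (negative pore
#' volumes) return a large finite penalty.
#'
#' @param par Numeric vector `c(I_r, eps_casts, f_casts_mic, phi_mac_c)`
#'   with `I_r` in g soil g^-1 biomass day^-1.
#' @param obs Observation data frame (compacted plot, typically already
#'   normalized by [normalize_to_control()]).
#' @param fixed List of fixed quantities: `gamma_s`, `E_bio` (g/cm^3), and
#'   for building a default initial state `phi_min`, `f_t_mic`,
#'   `layer_thickness`.
#' @param initial Optional [pore_space_state()]; by default built from the
#'   first observation row via [initial_state_from_obs()].
#' @param dt Integration step of the fixed-step forward run, yr.
#' @return Scalar objective value.
#' @export
recovery_objective <- function(par, obs, fixed, initial = NULL, dt = 0.02) {
  if (is.null(initial))
    initial <- initial_state_from_obs(obs[which.min(obs$time_yr), ],
                                      fixed$phi_min, fixed$f_t_mic,
                                      fixed$layer_thickness %||% 30)
  scales <- attr(obs, "scales") %||% .obs_scales(obs)
  times <- obs$time_yr - min(obs$time_yr)
  ord <- order(times)  # the forward run needs ascending times
  sim_sorted <- .forward_recovery(par[1], par[2], par[3], par[4],
                                  E_bio = fixed$E_bio, initial = initial,
                                  gamma_s = fixed$gamma_s,
                                  times = times[ord], dt = dt)
  if (is.null(sim_sorted)) return(1e8)
  sim <- sim_sorted
  sim[ord, ] <- sim_sorted
  V_pt <- initial$V_p_textural
  f_t_mic <- initial$f_t_mic
  phi_mic <- (sim[, "V_ps_mic"] + f_t_mic * V_pt) / sim[, "V_t"]
  phi_mat <- phi_mic +
    (sim[, "V_ps_mes"] + (1 - f_t_mic) * V_pt) / sim[, "V_t"]
  phi <- phi_mat + sim[, "V_mac"] / sim[, "V_t"]
  res <- c((fixed$gamma_s * (1 - phi) - obs$bulk_density) /
             scales[["bulk_density"]],
           (phi - obs$porosity) / scales[["porosity"]],
           (phi_mat - obs$theta_30) / scales[["theta_30"]],
           (phi_mic - obs$theta_100) / scales[["theta_100"]])
  sum(res^2)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Multi-start Powell calibration of the recovery model
#'
#' Estimates the four free parameters of the surface-casting recovery model
#' — ingestion rate `I_r`, cast void ratio `eps_casts`, cast micropore
#' fraction `f_casts_mic` and the surface-casting macroporosity threshold
#' `phi_mac_c` — by minimizing [recovery_objective()] with [powell()] from
#' `n_restarts` uniform-random start points within the bounds.  Restarting
#' assesses the uniqueness of the optimum; the full restart table is
#' returned.
#'
#' @param obs Observation data frame (see [recovery_objective()]).
#' @param fixed List of fixed quantities (`gamma_s`, `E_bio`, `phi_min`,
#'   `f_t_mic`, optionally `layer_thickness`).
#' @param initial Optional initial [pore_space_state()].
#' @param bounds 2 x 4 matrix (rows lower/upper) or list with `lower` and
#'   `upper`; defaults span the plausible field ranges: `I_r` in (0, 10]
#'   g/g/day, `eps_casts` in (0, 2], `f_casts_mic` in [0, 1], `phi_mac_c`
#'   in (0, 0.2].
#' @param n_restarts Number of random starts (>= 1).
#' @param seed Integer seed for the start draws (logged in the result).
#' @param control Passed to [powell()].
#' @param dt Forward-integration step, yr.
#' @return An object of class `calibration_result`: list with `par` (named
#'   best estimate), `value`, `restarts` (data frame of start and end points
#'   and objectives per restart), `scales`, `seed`, `convergence`.
#' @export
calibrate_recovery <- function(obs, fixed, initial = NULL, bounds = NULL,
                               n_restarts = 100, seed = NULL,
                               control = list(), dt = 0.02) {
  if (n_restarts < 1) stop("`n_restarts` must be >= 1", call. = FALSE)
  pn <- c("I_r", "eps_casts", "f_casts_mic", "phi_mac_c")
  if (is.null(bounds))
    bounds <- list(lower = c(1e-3, 1e-3, 0, 1e-3),
                   upper = c(10, 2, 1, 0.2))
  lower <- bounds$lower %||% bounds[1, ]
  upper <- bounds$upper %||% bounds[2, ]
  if (any(!is.finite(lower)) || any(!is.finite(upper)))
    stop("bounds must be finite", call. = FALSE)
  if (is.null(initial))
    initial <- initial_state_from_obs(obs[which.min(obs$time_yr), ],
                                      fixed$phi_min, fixed$f_t_mic,
                                      fixed$layer_thickness %||% 30)
  scales <- .obs_scales(obs)
  attr(obs, "scales") <- scales
  obj <- function(p) recovery_objective(p, obs, fixed, initial, dt = dt)

  if (!is.null(seed)) set.seed(seed)
  starts <- matrix(stats::runif(4 * n_restarts, lower, upper),
                   ncol = 4, byrow = TRUE)
  rows <- vector("list", n_restarts)
  best <- NULL
  for (r in seq_len(n_restarts)) {
    fit <- tryCatch(powell(starts[r, ], obj, lower, upper, control),
                    error = function(e) NULL)
    if (is.null(fit)) {
      rows[[r]] <- data.frame(restart = r, t(starts[r, ]),
                              t(rep(NA_real_, 4)), objective = NA_real_,
                              convergence = NA_integer_)
      next
    }
    rows[[r]] <- data.frame(restart = r, t(starts[r, ]), t(fit$par),
                            objective = fit$value,
                            convergence = fit$convergence)
    if (is.null(best) || fit$value < best$value) best <- fit
  }
  if (is.null(best))
    stop("all calibration restarts failed", call. = FALSE)
  restarts <- do.call(rbind, rows)
  names(restarts) <- c("restart", paste0("start_", pn), paste0("end_", pn),
                       "objective", "convergence")
  par <- stats::setNames(best$par, pn)
  structure(list(par = par, value = best$value, restarts = restarts,
                 scales = scales, seed = seed,
                 convergence = best$convergence, fixed = fixed),
            class = "calibration_result")
}

#' @export
print.calibration_result <- function(x, ...) {
  cat("<calibration_result>  objective =", format(x$value), "\n")
  print(round(x$par, 4))
  ok <- sum(!is.na(x$restarts$objective))
  cat(sprintf("%d/%d restarts completed; best found %d time(s) within 1e-6\n",
              ok, nrow(x$restarts),
              sum(x$restarts$objective <= x$value + 1e-6, na.rm = TRUE)))
  invisible(x)
}

#' Read and write observation series CSV
#'
#' Columns `time_yr`, `plot` (`compacted`/`control`), `bulk_density`,
#' `porosity`, `theta_30`, `theta_100` and optional `sd_*` columns; leading
#' `#` lines are metadata.
#'
#' @param obs Observation data frame.
#' @param path File path.
#' @param meta Optional metadata lines.
#' @export
write_observations <- function(obs, path, meta = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(meta)) writeLines(paste0("# ", meta), con)
  utils::write.csv(obs, con, row.names = FALSE)
  invisible(path)
}

#' @rdname write_observations
#' @export
read_observations <- function(path) {
  utils::read.csv(path, comment.char = "#")
}
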
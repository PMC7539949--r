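#' Root and earthworm parameter sets for structure dynamics
#'
#' `root_params()` describes root biomass turnover: at steady state the
#' growth rate equals the decay rate, `R_g = B_r * tau_r = R_d`.  Either give
#' `B_r` and `tau_r`, or give `R_g` directly (as in scenario tables).
#'
#' `worm_params()` describes earthworm bioturbation.  The soil-mass turnover
#' rate `tau_s` (1/yr) may be given directly, or expressed through the
#' ingestion rate `I_r` (g soil per g biomass per **day**, the unit used in
#' field studies; converted internally with 365 d/yr) and the earthworm
#' biomass concentration `E_bio` (g/cm^3): `tau_s = 365 * I_r * E_bio /
#' gamma_b`.  Casts have their own void ratio `eps_casts` and micropore
#' fraction `f_casts_mic`; `phi_mac_c` is the macroporosity threshold below
#' which casting is increasingly diverted to the soil surface.
#'
#' @param B_r Root biomass, g/cm^3.
#' @param tau_r Root turnover rate, 1/yr.
#' @param gamma_r Root tissue density, g/cm^3.
#' @param f_r_c Coarse-root fraction of root biomass, in `[0, 1]`.
#' @param R_g,R_d Root growth and decay rates, g cm^-3 yr^-1.
#' @return `root_params()` returns a `root_params` object.
#' @export
root_params <- function(B_r = 0, tau_r = 0, gamma_r = 1.2, f_r_c = 0.2,
                        R_g = B_r * tau_r, R_d = R_g) {
  if (gamma_r <= 0) stop("`gamma_r` must be positive", call. = FALSE)
  if (f_r_c < 0 || f_r_c > 1) stop("`f_r_c` must lie in [0, 1]", call. = FALSE)
  if (any(c(B_r, tau_r, R_g, R_d) < 0))
    stop("root rates and biomass must be >= 0", call. = FALSE)
  if (missing(B_r) && !missing(R_g)) { B_r <- R_g; tau_r <- 1 }
  structure(list(B_r = B_r, tau_r = tau_r, gamma_r = gamma_r,
                 f_r_c = f_r_c, R_g = R_g, R_d = R_d),
            class = "root_params")
}

#' @rdname root_params
#' @param tau_s Soil mass turnover rate by earthworms, 1/yr (alternative to
#'   `I_r` + `E_bio`).
#' @param I_r Soil ingestion rate, g soil g^-1 biomass day^-1.
#' @param E_bio Earthworm biomass concentration, g/cm^3.
#' @param eps_casts Void ratio of earthworm casts.
#' @param f_casts_mic Micropore fraction of cast pore space, in `[0, 1]`.
#' @param phi_mac_c Macroporosity threshold for surface casting, cm^3/cm^3.
#' @param E_c,E_i Within-soil casting and ingestion rates, g soil cm^-3
#'   yr^-1 (equal at steady state).
#' @return `worm_params()` returns a `worm_params` object.
#' @export
worm_params <- function(tau_s = NULL, I_r = NULL, E_bio = NULL,
                        eps_casts = 0.6, f_casts_mic = 0.8,
                        phi_mac_c = NA_real_, E_c = 0, E_i = 0) {
  if (is.null(tau_s) && (is.null(I_r) || is.null(E_bio)))
    stop("give either `tau_s` or both `I_r` and `E_bio`", call. = FALSE)
  if (!is.null(tau_s) && tau_s < 0) stop("`tau_s` must be >= 0", call. = FALSE)
  if (!is.null(I_r) && I_r < 0) stop("`I_r` must be >= 0", call. = FALSE)
  if (!is.null(E_bio) && E_bio < 0) stop("`E_bio` must be >= 0", call. = FALSE)
  if (eps_casts < 0) stop("`eps_casts` must be >= 0", call. = FALSE)
  if (f_casts_mic < 0 || f_casts_mic > 1)
    stop("`f_casts_mic` must lie in [0, 1]", call. = FALSE)
  structure(list(tau_s = tau_s, I_r = I_r, E_bio = E_bio,
                 eps_casts = eps_casts, f_casts_mic = f_casts_mic,
                 phi_mac_c = phi_mac_c, E_c = E_c, E_i = E_i),
            class = "worm_params")
}

#' Soil mass turnover rate from ingestion rate and worm biomass
#'
#' `tau_s = I_r_yr * E_bio / gamma_b`: the fraction of the soil mass passing
#' through earthworm guts per year.
#'
#' @param I_r_yr Soil ingestion rate, g soil g^-1 biomass **yr^-1**.
#' @param E_bio Earthworm biomass concentration, g/cm^3.
#' @param gamma_b Soil bulk density, g/cm^3 (> 0).
#' @return tau_s, 1/yr.
#' @export
turnover_rate <- function(I_r_yr, E_bio, gamma_b) {
  if (any(gamma_b <= 0)) stop("`gamma_b` must be positive", call. = FALSE)
  I_r_yr * E_bio / gamma_b
}

# Effective tau_s for a worm_params given the current bulk density.
worm_tau_s <- function(worms, gamma_b) {
  if (!is.null(worms$tau_s)) return(worms$tau_s)
  turnover_rate(per_day_to_per_year(worms$I_r), worms$E_bio, gamma_b)
}

#' Net rate of change of the solid volume
#'
#' Solids change through net root growth and through net within-soil worm
#' casting minus ingestion:
#' `dV_s/dt = V_t * ((R_g - R_d)/gamma_r + (E_c - E_i)/gamma_s)`.
#' At steady state (`R_g = R_d`, `E_c = E_i`) the solid volume, and hence the
#' total porosity, are constant even though pore volume moves between
#' classes.
#'
#' @param roots A [root_params()].
#' @param worms A [worm_params()].
#' @param V_t Total soil volume, cm^3.
#' @param gamma_s Particle density, g/cm^3.
#' @return dV_s/dt, cm^3/yr.
#' @export
solids_rate <- function(roots, worms, V_t, gamma_s) {
  if (gamma_s <= 0) stop("`gamma_s` must be positive", call. = FALSE)
  V_t * ((roots$R_g - roots$R_d) / roots$gamma_r +
           (worms$E_c - worms$E_i) / gamma_s)
}

#' Structural micro/meso shares with a degenerate-pool rule
#'
#' The share of structural matrix pore space in the micropore class,
#' `phi_s_mic / (phi_s_mic + phi_s_mes)`.  When both structural matrix pools
#' are (numerically) empty the share is undefined; ingestion and compression
#' then act on what remains — the textural pores — so the textural split
#' `(f_t_mic, 1 - f_t_mic)` is used instead.
#'
#' @param phi_s_mic,phi_s_mes Structural micro- and mesoporosity (or the
#'   corresponding volumes; only the ratio matters).
#' @param f_t_mic Textural micropore fraction (fallback split).
#' @return Named vector `c(mic = ..., mes = ...)` summing to 1.
#' @export
structural_shares <- function(phi_s_mic, phi_s_mes, f_t_mic) {
  tot <- phi_s_mic + phi_s_mes
  if (tot < 1e-12) return(c(mic = f_t_mic, mes = 1 - f_t_mic))
  c(mic = phi_s_mic / tot, mes = phi_s_mes / tot)
}

#' Pore-change factor table for root and earthworm processes
#'
#' Pore-change factors (m^3 pores per m^3 solids) for the four volume-
#' conserving processes: root growth compresses structural micro- and
#' mesopores in proportion to their shares (growth into macropores is
#' neglected); root decay creates macropores (coarse roots) and mesopores
#' (fine roots); worm ingestion of matrix creates an equivalent macropore
#' volume `-( 1 + eps)` and destroys structural matrix pores by their
#' shares; within-soil casting fills macropores `-(1 + eps_casts)` and
#' creates cast pores split by `f_casts_mic`.  Every column sums to -1, so
#' each process conserves the total soil volume.
#'
#' @param shares Structural micro/meso shares, e.g. from
#'   [structural_shares()] (named vector with `mic` and `mes`).
#' @param eps Current matrix void ratio `phi_mat / (1 - phi)`.
#' @param worms A [worm_params()].
#' @param roots A [root_params()].
#' @return A 3 x 4 matrix, rows `mic`, `mes`, `mac`, columns `root_growth`,
#'   `root_decay`, `worm_casting`, `worm_ingestion`.
#' @export
table3_factors <- function(shares, eps, worms, roots) {
  s_mic <- shares[["mic"]]; s_mes <- shares[["mes"]]
  m <- cbind(
    root_growth    = c(mic = -s_mic, mes = -s_mes, mac = 0),
    root_decay     = c(mic = 0, mes = roots$f_r_c - 1, mac = -roots$f_r_c),
    worm_casting   = c(mic = worms$f_casts_mic * worms$eps_casts,
                       mes = (1 - worms$f_casts_mic) * worms$eps_casts,
                       mac = -(1 + worms$eps_casts)),
    worm_ingestion = c(mic = s_mic * eps, mes = s_mes * eps,
                       mac = -(1 + eps)))
  m
}

#' Apply pore-change factors to solid-volume changes
#'
#' The structural pore volume in class i changes as
#' `dV_ps_i = sum_j f_ij * dV_s_j` over agents j, and the total volume as
#' `dV_t = sum_i dV_ps_i + sum_j dV_s_j`.  If an agent's three factors sum
#' to -1, it leaves the total soil volume unchanged.  Works equally for
#' rates (per yr) or finite increments.
#'
#' @param dV_s_by_agent Named numeric vector of solid-volume changes, cm^3,
#'   one entry per agent (e.g. `c(root_decay = -1, som = 0.5)`).
#' @param factors Named list mapping each agent to its factor triple
#'   `c(mic, mes, mac)`; columns of [table3_factors()] work directly.  A
#'   microbial soil-organic-matter agent typically has factors summing to
#'   between 2 and 4 (aggregation creates much more pore space than the OM
#'   volume itself).
#' @return List with `dV_ps_mic`, `dV_ps_mes`, `dV_mac`, `dV_t` (cm^3).
#' @export
pore_change_step <- function(dV_s_by_agent, factors) {
  agents <- names(dV_s_by_agent)
  if (is.null(agents) || any(!nzchar(agents)))
    stop("`dV_s_by_agent` must be a named vector", call. = FALSE)
  missing_f <- setdiff(agents, names(factors))
  if (length(missing_f))
    stop("no pore-change factors for agent(s): ",
         paste(missing_f, collapse = ", "), call. = FALSE)
  d <- c(mic = 0, mes = 0, mac = 0)
  for (a in agents) {
    f <- factors[[a]]
    if (length(f) != 3) stop("factor triple needed for agent ", a, call. = FALSE)
    if (is.null(names(f))) names(f) <- c("mic", "mes", "mac")
    d <- d + f[c("mic", "mes", "mac")] * dV_s_by_agent[[a]]
  }
  list(dV_ps_mic = unname(d[["mic"]]), dV_ps_mes = unname(d[["mes"]]),
       dV_mac = unname(d[["mac"]]),
       dV_t = sum(d) + sum(dV_s_by_agent))
}

#' Matrix volume change from swelling or shrinkage
#'
#' The matrix pore volume follows the soil water volume along the shrinkage
#' characteristic: `dV_mat = f_slope * dV_w`, with `f_slope = 1` for normal
#' shrinkage (volume change equals water loss) and `f_slope = 0` for a rigid
#' soil.  Solids are unchanged.
#'
#' @param dV_w Change in soil water volume, cm^3.
#' @param f_slope Slope of the shrinkage characteristic, in `[0, 1]`.
#' @return dV_mat, cm^3.
#' @export
swell_shrink_step <- function(dV_w, f_slope) {
  if (f_slope < 0 || f_slope > 1)
    stop("`f_slope` must lie in [0, 1]", call. = FALSE)
  f_slope * dV_w
}

#' Porosity class rates in the constant-volume (steady-flux) regime
#'
#' With root biomass and casting at steady state (`R_g = R_d`, `E_c = E_i`)
#' the total porosity is constant but pore volume moves between classes:
#' \deqn{d\phi_{mac}/dt = f_{r(c)} B_r \tau_r / \gamma_r +
#'   (\epsilon - \epsilon_{casts}) \gamma_b \tau_s / \gamma_s}
#' and the corresponding expressions for the structural meso- and micropore
#' classes, with the matrix void ratio `eps = phi_mat / (1 - phi)` evaluated
#' from the current profile.  The three rates sum to zero.
#'
#' @param profile A [porosities()] profile (or the output of
#'   [steady_state()]).
#' @param roots A [root_params()].
#' @param worms A [worm_params()].
#' @param gamma_s Particle density, g/cm^3.
#' @return Named vector `c(dphi_mac, dphi_s_mes, dphi_s_mic)`, 1/yr.
#' @export
steady_flux_rates <- function(profile, roots, worms, gamma_s) {
  phi <- profile$phi
  eps <- profile$phi_mat / (1 - phi)
  gamma_b <- gamma_s * (1 - phi)
  tau_s <- worm_tau_s(worms, gamma_b)
  sh <- structural_shares(profile$phi_s_mic, profile$phi_s_mes,
                          profile$phi_t_mic / max(profile$phi_t, 1e-300))
  root_term <- roots$B_r * roots$tau_r / roots$gamma_r
  worm_term <- gamma_b * tau_s / gamma_s
  d_mac <- roots$f_r_c * root_term + (eps - worms$eps_casts) * worm_term
  d_mes <- (1 - roots$f_r_c - sh[["mes"]]) * root_term +
    ((1 - worms$f_casts_mic) * worms$eps_casts - sh[["mes"]] * eps) * worm_term
  d_mic <- -sh[["mic"]] * root_term +
    (worms$f_casts_mic * worms$eps_casts - sh[["mic"]] * eps) * worm_term
  c(dphi_mac = d_mac, dphi_s_mes = d_mes, dphi_s_mic = d_mic)
}

#' Closed-form steady state of the constant-volume regime
#'
#' Setting the three class rates of [steady_flux_rates()] to zero gives the
#' equilibrium pore-size distribution in closed form.  The matrix void ratio
#' settles at
#' `eps* = eps_casts - f_r_c * B_r * tau_r * gamma_s / (gamma_r * tau_s *
#' gamma_b)`, so `phi_mat* = (1 - phi) * eps*`; on bare soil (`B_r = 0`) the
#' matrix void ratio equals the cast void ratio exactly.  The structural
#' micropore share follows from balancing cast deposition against ingestion
#' and root compression, and the remaining classes from the additivity
#' identities.  A parameter set implying `phi_mat* <= 0` (extreme root
#' pressure at negligible bioturbation) is rejected as infeasible.
#'
#' @param roots A [root_params()].
#' @param worms A [worm_params()]; `tau_s` (or `I_r` + `E_bio`) must be
#'   positive.
#' @param phi Total porosity (constant in this regime), cm^3/cm^3.
#' @param phi_min Minimum matrix porosity, cm^3/cm^3.
#' @param f_t_mic Textural micropore fraction.
#' @param gamma_s Particle density, g/cm^3.
#' @return A list of class `steady_state` with `phi_mat`, `phi_mic`,
#'   `phi_mes`, `phi_mac`, `phi_s_mic`, `phi_s_mes`, `phi`, `phi_t`,
#'   `phi_s`, `phi_t_mic`, `phi_t_mes`, `bulk_density` and `eps`.
#' @export
steady_state <- function(roots, worms, phi, phi_min, f_t_mic, gamma_s) {
  if (phi <= 0 || phi >= 1) stop("`phi` must lie in (0, 1)", call. = FALSE)
  gamma_b <- gamma_s * (1 - phi)
  tau_s <- worm_tau_s(worms, gamma_b)
  if (tau_s <= 0)
    stop("steady state requires a positive bioturbation rate", call. = FALSE)
  # root-to-worm flux ratio: (B_r tau_r / gamma_r) / (gamma_b tau_s / gamma_s)
  r_ratio <- (roots$B_r * roots$tau_r / roots$gamma_r) /
    (gamma_b * tau_s / gamma_s)
  eps_star <- worms$eps_casts - roots$f_r_c * r_ratio
  phi_mat <- (1 - phi) * eps_star
  if (phi_mat <= 0)
    stop("infeasible parameters: closed-form matrix porosity is not ",
         "positive (root compression exceeds cast formation); the ",
         "steady state does not exist", call. = FALSE)
  if (phi_mat > phi)
    stop("infeasible parameters: closed-form matrix porosity exceeds the ",
         "total porosity", call. = FALSE)
  # micropore share of structural matrix pores from the class-i balance
  s_mic <- worms$f_casts_mic * worms$eps_casts / (r_ratio + eps_star)
  phi_s_mat <- phi_mat - phi_min
  if (phi_s_mat < 0)
    stop("infeasible parameters: steady-state matrix porosity below the ",
         "textural minimum", call. = FALSE)
  phi_s_mic <- s_mic * phi_s_mat
  phi_mic <- phi_s_mic + f_t_mic * phi_min
  structure(
    list(phi = phi, phi_t = phi_min, phi_s = phi - phi_min,
         phi_mat = phi_mat, phi_mac = phi - phi_mat,
         phi_mic = phi_mic, phi_mes = phi_mat - phi_mic,
         phi_t_mic = f_t_mic * phi_min, phi_t_mes = (1 - f_t_mic) * phi_min,
         phi_s_mic = phi_s_mic, phi_s_mes = phi_s_mat - phi_s_mic,
         bulk_density = gamma_b, eps = eps_star),
    class = c("steady_state", "porosity_profile"))
}

#' Fraction of casts deposited at the soil surface
#'
#' One-parameter threshold function: surface casting increases linearly as
#' the macroporosity falls below the threshold `phi_mac_c`,
#' `f_surf = max(0, 1 - phi_mac / phi_mac_c)`.  In freshly compacted soil
#' (`phi_mac = 0`) all casts go to the surface; at or above the threshold
#' none do.
#'
#' @param phi_mac Current macroporosity, cm^3/cm^3.
#' @param phi_mac_c Threshold macroporosity, cm^3/cm^3 (> 0).
#' @return f_surf in `[0, 1]` (for `phi_mac >= 0`).
#' @export
surface_cast_fraction <- function(phi_mac, phi_mac_c) {
  if (any(!is.finite(phi_mac_c)) || any(phi_mac_c <= 0))
    stop("`phi_mac_c` must be positive", call. = FALSE)
  pmax(0, 1 - phi_mac / phi_mac_c)
}

#' Volume rates under bioturbation with surface casting (bare soil)
#'
#' The worm gut flux is `Q = V_t * I_r_yr * E_bio / gamma_s` (cm^3 solids per
#' yr).  Ingestion of matrix creates macropores; casts are deposited into
#' macropores within the soil or at the surface (fraction `f_surf` from
#' [surface_cast_fraction()]).  Cast pore space feeds the structural meso-
#' and micropore pools split by `f_casts_mic`; matrix pore destruction by
#' ingestion is apportioned by the structural shares.  The total volume
#' grows at `Q * f_surf * (1 + eps_casts)` — surface casting raises the soil
#' surface — while the solid volume is conserved.
#'
#' @param state A [pore_space_state()].
#' @param worms A [worm_params()] with `I_r` and `E_bio` (or `tau_s`).
#' @param gamma_s Particle density, g/cm^3.
#' @return List with `dV_mac`, `dV_ps_mes`, `dV_ps_mic`, `dV_t` (cm^3/yr)
#'   and the diagnostic `f_surf`.
#' @export
bioturbation_volume_rates <- function(state, worms, gamma_s) {
  V_t <- total_volume(state)
  prof <- porosities(state, gamma_s)
  eps <- prof$phi_mat / (1 - prof$phi)
  if (!is.null(worms$I_r) && !is.null(worms$E_bio)) {
    Q <- V_t * per_day_to_per_year(worms$I_r) * worms$E_bio / gamma_s
  } else {
    Q <- V_t * worm_tau_s(worms, prof$bulk_density) * prof$bulk_density /
      gamma_s
  }
  f_surf <- if (is.finite(worms$phi_mac_c))
    surface_cast_fraction(prof$phi_mac, worms$phi_mac_c) else 0
  sh <- structural_shares(state$V_ps_mic, state$V_ps_mes, state$f_t_mic)
  ec <- worms$eps_casts; fcm <- worms$f_casts_mic
  list(dV_mac = Q * (eps - ec + f_surf * (1 + ec)),
       dV_ps_mes = Q * ((1 - fcm) * ec - sh[["mes"]] * eps),
       dV_ps_mic = Q * (fcm * ec - sh[["mic"]] * eps),
       dV_t = Q * f_surf * (1 + ec),
       f_surf = f_surf)
}
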
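#' Textural pore and mineral solid volumes for a soil layer
#'
#' The textural pore space is the pore volume inherent to the closest random
#' packing of the mineral particles.  Both it and the mineral solid volume are
#' fixed for a given layer and are derived from a user-defined minimum matrix
#' porosity `phi_min` and a minimum layer thickness `dz_min`, i.e. the state
#' the layer would collapse to in the complete absence of biological activity
#' and organic matter.
#'
#' @param phi_min Minimum (textural) matrix porosity, cm^3/cm^3, in (0, 1).
#' @param dz_min Minimum layer thickness, cm (> 0).
#' @param a_xs Nominal cross-sectional area, cm^2 (> 0); defaults to 1 so
#'   that volumes are numerically equal to equivalent depths in cm.
#' @return A list with components `V_p_textural` and `V_s_mineral` (cm^3).
#' @examples
#' textural_volumes(0.3, 25)   # V_p_textural = 7.5, V_s_mineral = 17.5
#' @export
textural_volumes <- function(phi_min, dz_min, a_xs = 1) {
  if (!is.finite(phi_min) || phi_min <= 0 || phi_min >= 1)
    stop("`phi_min` must lie strictly between 0 and 1", call. = FALSE)
  if (!is.finite(dz_min) || dz_min <= 0)
    stop("`dz_min` must be positive", call. = FALSE)
  if (!is.finite(a_xs) || a_xs <= 0)
    stop("`a_xs` must be positive", call. = FALSE)
  V_p_textural <- phi_min * dz_min * a_xs
  list(V_p_textural = V_p_textural,
       V_s_mineral  = V_p_textural * (1 / phi_min - 1))
}

#' Construct a pore-space state for one homogeneous soil layer
#'
#' The canonical state of the model is a set of partial volumes: mineral and
#' organic solids, the static textural pore volume, and the dynamic structural
#' pore volumes in the micropore, mesopore and macropore classes.  All
#' porosities, the bulk density and the layer thickness are derived from these
#' volumes, never stored.  Pore classes are bounded at equivalent diameters of
#' 30 and 100 micrometres; micropores and mesopores together form the soil
#' matrix, the remainder are macropores.
#'
#' Volumes in a narrow band of round-off below zero (down to `-1e-9` times the
#' total volume) are clamped to zero; anything more negative is an error.
#'
#' @param V_s_mineral Mineral solid volume, cm^3.
#' @param V_p_textural Textural pore volume, cm^3 (constant in time).
#' @param V_ps_mic,V_ps_mes Structural micropore and mesopore volumes, cm^3.
#' @param V_mac Macropore volume, cm^3 (all macropores are structural).
#' @param V_s_organic Organic solid volume, cm^3; 0 unless soil organic
#'   matter is modelled as a dynamic agent.
#' @param f_t_mic Fraction of the textural pore volume in the micropore
#'   class, in `[0, 1]`; usually estimated from the particle size
#'   distribution.
#' @param a_xs Nominal cross-sectional area, cm^2.
#' @return An object of class `pore_space_state`.
#' @seealso [porosities()], [state_from_porosities()], [textural_volumes()]
#' @export
pore_space_state <- function(V_s_mineral, V_p_textural,
                             V_ps_mic = 0, V_ps_mes = 0, V_mac = 0,
                             V_s_organic = 0, f_t_mic = 0.8, a_xs = 1) {
  st <- structure(
    list(A_xs = a_xs,
         V_s_mineral = V_s_mineral, V_s_organic = V_s_organic,
         V_p_textural = V_p_textural,
         V_ps_mic = V_ps_mic, V_ps_mes = V_ps_mes, V_mac = V_mac,
         f_t_mic = f_t_mic),
    class = "pore_space_state")
  validate_state(st)
}

#' @rdname pore_space_state
#' @param state A `pore_space_state`.
#' @export
total_volume <- function(state) {
  with(state, V_s_mineral + V_s_organic + V_p_textural +
         V_ps_mic + V_ps_mes + V_mac)
}

# Round-off guard: clamp tiny negative volumes, reject real ones.
validate_state <- function(state) {
  vol_fields <- c("V_s_mineral", "V_s_organic", "V_p_textural",
                  "V_ps_mic", "V_ps_mes", "V_mac")
  vals <- unlist(state[vol_fields])
  if (any(!is.finite(vals)))
    stop("non-finite volume in pore-space state", call. = FALSE)
  V_t <- sum(vals)
  tol <- 1e-9 * max(V_t, .Machine$double.eps)
  if (any(vals < -tol)) {
    bad <- vol_fields[vals < -tol]
    stop("negative volume(s) in pore-space state: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  for (f in vol_fields) if (state[[f]] < 0) state[[f]] <- 0
  if (!is.finite(state$A_xs) || state$A_xs <= 0)
    stop("`a_xs` must be positive", call. = FALSE)
  if (state$f_t_mic < 0 || state$f_t_mic > 1)
    stop("`f_t_mic` must lie in [0, 1]", call. = FALSE)
  state
}

#' Derive porosities, bulk density and layer thickness from a state
#'
#' Computes the full porosity profile of a layer: total, textural, structural,
#' matrix and macro porosity, the micro/meso split, the cross-partitioned
#' (textural/structural by micro/meso) porosities, the bulk density
#' `gamma_s * (1 - phi)` and the layer thickness `V_t / A_xs`.  The identities
#' `phi_mic + phi_mes = phi_mat` and `phi_mat + phi_mac = phi = phi_t + phi_s`
#' hold to double precision by construction.
#'
#' @param state A [pore_space_state()].
#' @param gamma_s Particle density, g/cm^3 (2.65 is typical for mineral soil).
#' @return An object of class `porosity_profile`: a named list with entries
#'   `phi`, `phi_t`, `phi_s`, `phi_mat`, `phi_mac`, `phi_mic`, `phi_mes`,
#'   `phi_t_mic`, `phi_t_mes`, `phi_s_mic`, `phi_s_mes`, `bulk_density`
#'   (g/cm^3) and `layer_thickness` (cm).
#' @export
porosities <- function(state, gamma_s) {
  if (!is.finite(gamma_s) || gamma_s <= 0)
    stop("`gamma_s` must be positive", call. = FALSE)
  V_t <- total_volume(state)
  if (V_t <= 0) stop("total soil volume is zero", call. = FALSE)
  V_pt_mic <- state$f_t_mic * state$V_p_textural
  V_pt_mes <- (1 - state$f_t_mic) * state$V_p_textural
  phi_mic <- (state$V_ps_mic + V_pt_mic) / V_t
  phi_mes <- (state$V_ps_mes + V_pt_mes) / V_t
  phi_mac <- state$V_mac / V_t
  phi_t <- state$V_p_textural / V_t
  phi_s <- (state$V_ps_mic + state$V_ps_mes + state$V_mac) / V_t
  phi <- phi_t + phi_s
  structure(
    list(phi = phi, phi_t = phi_t, phi_s = phi_s,
         phi_mat = phi_mic + phi_mes, phi_mac = phi_mac,
         phi_mic = phi_mic, phi_mes = phi_mes,
         phi_t_mic = V_pt_mic / V_t, phi_t_mes = V_pt_mes / V_t,
         phi_s_mic = state$V_ps_mic / V_t, phi_s_mes = state$V_ps_mes / V_t,
         bulk_density = gamma_s * (1 - phi),
         layer_thickness = V_t / state$A_xs),
    class = "porosity_profile")
}

#' Build a pore-space state that realizes target class porosities
#'
#' Inverts [porosities()]: given target micro-, meso- and macroporosity for a
#' layer of known thickness, together with the minimum matrix porosity and
#' the textural micropore fraction, reconstructs the partial volumes.  The
#' textural pore volume is set to `phi_min * V_t`, i.e. the textural
#' porosity of the constructed state equals the minimum matrix porosity —
#' the convention under which the matrix-partition formulas (structural =
#' total - textural with `phi_t = phi_min`) hold.  `V_p_textural` then stays
#' constant through any subsequent dynamics, so the textural porosity
#' dilutes if the total volume later grows by surface casting.
#'
#' @param phi_mic,phi_mes,phi_mac Target class porosities, cm^3/cm^3.
#' @param phi_min Minimum matrix porosity, cm^3/cm^3.
#' @param f_t_mic Fraction of textural pores in the micropore class.
#' @param layer_thickness Current layer thickness, cm.
#' @param a_xs Nominal cross-sectional area, cm^2.
#' @return A [pore_space_state()] whose [porosities()] reproduce the targets.
#' @export
state_from_porosities <- function(phi_mic, phi_mes, phi_mac,
                                  phi_min, f_t_mic,
                                  layer_thickness, a_xs = 1) {
  phi <- phi_mic + phi_mes + phi_mac
  if (phi >= 1) stop("total porosity must be < 1", call. = FALSE)
  V_t <- layer_thickness * a_xs
  V_s <- (1 - phi) * V_t
  V_pt <- phi_min * V_t
  st <- pore_space_state(
    V_s_mineral = V_s, V_p_textural = V_pt,
    V_ps_mic = phi_mic * V_t - f_t_mic * V_pt,
    V_ps_mes = phi_mes * V_t - (1 - f_t_mic) * V_pt,
    V_mac = phi_mac * V_t,
    f_t_mic = f_t_mic, a_xs = a_xs)
  st
}

#' @export
print.pore_space_state <- function(x, ...) {
  cat("<pore_space_state>  V_t =", format(total_volume(x)), "cm^3\n")
  v <- unlist(x[c("V_s_mineral", "V_s_organic", "V_p_textural",
                  "V_ps_mic", "V_ps_mes", "V_mac")])
  print(round(v, 6))
  cat("f_t_mic =", x$f_t_mic, "  A_xs =", x$A_xs, "cm^2\n")
  invisible(x)
}

#' @export
print.porosity_profile <- function(x, ...) {
  cat("<porosity_profile>\n")
  print(round(unlist(x), 4))
  invisible(x)
}

#' @export
as.data.frame.pore_space_state <- function(x, ...) {
  as.data.frame(unclass(x), ...)
}

#' @export
as.data.frame.porosity_profile <- function(x, ...) {
  as.data.frame(unclass(x), ...)
}

#' Read and write pore-space states as flat CSV
#'
#' One row per state; column names mirror the field names of
#' [pore_space_state()].
#'
#' @param state A `pore_space_state`.
#' @param path File path.
#' @return `read_state()` returns a `pore_space_state`.
#' @export
write_state <- function(state, path) {
  utils::write.csv(as.data.frame(state), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_state
#' @export
read_state <- function(path) {
  df <- utils::read.csv(path)
  pore_space_state(V_s_mineral = df$V_s_mineral,
                   V_p_textural = df$V_p_textural,
                   V_ps_mic = df$V_ps_mic, V_ps_mes = df$V_ps_mes,
                   V_mac = df$V_mac, V_s_organic = df$V_s_organic,
                   f_t_mic = df$f_t_mic, a_xs = df$A_xs)
}
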
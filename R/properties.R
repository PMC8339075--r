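#' Thermal properties of tissue for the two-phase freezing model
#'
#' Bundles the conductivities, specific heats, density and latent heat of the
#' frozen and unfrozen phases. Thermal diffusivities are derived internally as
#' \eqn{\alpha = k / (\rho c)} and kept consistent with the primary fields.
#' Density is a single value for both phases: the classical Neumann solution
#' assumes no volume change on freezing.
#'
#' @param k_frozen,k_unfrozen Thermal conductivity of the frozen / unfrozen
#'   phase, W/(m K).
#' @param rho Density, kg/m^3 (shared by both phases).
#' @param c_frozen,c_unfrozen Specific heat, J/(kg K).
#' @param L Latent heat of fusion, J/kg. May be set to a very small positive
#'   value to approach the pure-conduction limit.
#'
#' @return An object of class `tissue_properties`: a list with the supplied
#'   fields plus `alpha_frozen` and `alpha_unfrozen` (m^2/s).
#' @seealso [liver_tissue_properties()] for the default liver-like set.
#' @export
#' @examples
#' tissue_properties(k_frozen = 2.2, k_unfrozen = 0.55, rho = 1050,
#'                   c_frozen = 2000, c_unfrozen = 3600, L = 159000)
tissue_properties <- function(k_frozen, k_unfrozen, rho, c_frozen, c_unfrozen, L) {
  vals <- c(k_frozen = k_frozen, k_unfrozen = k_unfrozen, rho = rho,
            c_frozen = c_frozen, c_unfrozen = c_unfrozen, L = L)
  if (any(!is.finite(vals)) || any(vals <= 0)) {
    stopf("all tissue properties must be finite and strictly positive")
  }
  structure(list(
    k_frozen = k_frozen, k_unfrozen = k_unfrozen, rho = rho,
    c_frozen = c_frozen, c_unfrozen = c_unfrozen, L = L,
    alpha_frozen = k_frozen / (rho * c_frozen),
    alpha_unfrozen = k_unfrozen / (rho * c_unfrozen)
  ), class = "tissue_properties")
}

#' Default liver-like tissue property set
#'
#' A documented default parameterisation for ex vivo liver tissue used
#' throughout examples and tests: frozen conductivity 2.2 and unfrozen 0.55
#' W/(m K), specific heats 2000 (frozen) and 3600 (unfrozen) J/(kg K),
#' density 1050 kg/m^3 and latent heat 159 kJ/kg (the mean measured for the
#' wettest liver cohort). Every value can be overridden.
#'
#' @param ... Named overrides passed to [tissue_properties()].
#' @return A `tissue_properties` object.
#' @export
liver_tissue_properties <- function(...) {
  defaults <- list(k_frozen = 2.2, k_unfrozen = 0.55, rho = 1050,
                   c_frozen = 2000, c_unfrozen = 3600, L = 159000)
  args <- utils::modifyList(defaults, list(...))
  do.call(tissue_properties, args)
}

#' Boundary conditions for the freezing-front problem
#'
#' @param T_surface Constant ablative (probe) temperature at the tissue
#'   surface, degC.
#' @param T_onset Phase-change (ice-onset) temperature, degC.
#' @param T_body Initial tissue temperature far from the probe, degC.
#'
#' @details The physical ordering `T_surface < T_onset < T_body` must hold:
#' a frozen layer only forms when the probe is colder than the onset
#' temperature, inside tissue warmer than it. `T_surface >= T_onset` raises a
#' degenerate-no-frozen-phase error.
#'
#' @return An object of class `boundary_conditions`.
#' @export
#' @examples
#' boundary_conditions(T_surface = -54, T_onset = -23, T_body = 37)
boundary_conditions <- function(T_surface, T_onset, T_body) {
  if (any(!is.finite(c(T_surface, T_onset, T_body)))) {
    stopf("boundary temperatures must be finite")
  }
  if (T_surface >= T_onset) {
    stopf("degenerate-no-frozen-phase: T_surface (%.3g) must be below T_onset (%.3g)",
          T_surface, T_onset)
  }
  if (T_onset >= T_body) {
    stopf("T_onset (%.3g) must be below T_body (%.3g)", T_onset, T_body)
  }
  structure(list(T_surface = T_surface, T_onset = T_onset, T_body = T_body),
            class = "boundary_conditions")
}
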
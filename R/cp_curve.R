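#' Specific heat capacity curve
#'
#' A specific heat capacity as a function of temperature on a monotone grid,
#' the common currency of the DSC processing stage. Stored with the grid in
#' ascending temperature order.
#'
#' @param temperature Temperature grid, degC (monotone; reordered ascending).
#' @param cp Specific heat capacity values, J/(g K), finite.
#' @return An object of class `cp_curve` (also a data.frame with columns
#'   `temperature` and `cp`).
#' @export
#' @examples
#' cp_curve(seq(-40, 20, by = 1), rep(3.4, 61))
cp_curve <- function(temperature, cp) {
  if (length(temperature) != length(cp)) stopf("temperature and cp lengths differ")
  if (length(temperature) < 2) stopf("a cp curve needs at least two points")
  if (any(!is.finite(temperature)) || any(!is.finite(cp))) {
    stopf("cp curve values must be finite")
  }
  d <- diff(temperature)
  if (!(all(d > 0) || all(d < 0))) stopf("temperature grid must be strictly monotone")
  if (d[1] < 0) {
    temperature <- rev(temperature)
    cp <- rev(cp)
  }
  structure(data.frame(temperature = temperature, cp = cp),
            class = c("cp_curve", "data.frame"))
}

#' Evaluate a cp curve at arbitrary temperatures
#'
#' Linear interpolation within the grid, constant extrapolation outside it.
#'
#' @param curve A [cp_curve()].
#' @param temperature Temperatures, degC.
#' @return cp values, J/(g K).
#' @export
cp_at <- function(curve, temperature) {
  stopifnot(inherits(curve, "cp_curve"))
  approx(curve$temperature, curve$cp, xout = temperature, rule = 2)$y
}

same_grid <- function(a, b) {
  length(a$temperature) == length(b$temperature) &&
    isTRUE(all.equal(a$temperature, b$temperature, tolerance = 1e-12))
}

#' Heat capacity of a water/dry-matter mixture
#'
#' Linear mixing rule: the specific heat of moist tissue is the
#' mass-fraction-weighted combination of its fluid and dehydrated (solid)
#' components, `w * cp_fluid + (1 - w) * cp_solid`. Used to verify measured
#' tissue heat capacities against the separately measured components.
#'
#' @param w Mass fraction of water (fluid component), in `[0, 1]`.
#' @param cp_fluid,cp_solid [cp_curve()] objects on a common grid.
#' @return A `cp_curve` on the shared grid.
#' @export
mixture_cp <- function(w, cp_fluid, cp_solid) {
  stopifnot(inherits(cp_fluid, "cp_curve"), inherits(cp_solid, "cp_curve"))
  if (w < 0 || w > 1) stopf("water fraction w must be in [0, 1]")
  if (!same_grid(cp_fluid, cp_solid)) {
    stopf("grid mismatch: cp_fluid and cp_solid must share a temperature grid")
  }
  cp_curve(cp_fluid$temperature, w * cp_fluid$cp + (1 - w) * cp_solid$cp)
}

#' Water mass fraction from drying masses
#'
#' The evaporated mass is assumed to be water only, so the water and
#' dry-matter mass fractions (both referred to the initial mass) are
#' complementary: `w = (m_initial - m_dry) / m_initial`.
#'
#' @param m_initial Initial sample mass, mg.
#' @param m_dry Dehydrated sample mass, mg.
#' @return Water mass fraction in `[0, 1]`.
#' @export
#' @examples
#' water_mass_fraction(100, 28.7)  # 0.713
water_mass_fraction <- function(m_initial, m_dry) {
  if (any(m_initial <= 0)) stopf("m_initial must be positive")
  if (any(m_dry < 0) || any(m_dry > m_initial)) {
    stopf("m_dry must satisfy 0 <= m_dry <= m_initial")
  }
  (m_initial - m_dry) / m_initial
}
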
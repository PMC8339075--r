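#' Grid specification for the finite-difference freezing solver
#'
#' @param domain_length Length of the computational domain, m. Should be at
#'   least five times the deepest front position expected during the run so
#'   the far boundary stays effectively semi-infinite.
#' @param n_nodes Number of grid nodes (including the two boundary nodes).
#' @param t_end End time of the march, s.
#' @param dt Time step, s. If `NULL` (default) it is set to
#'   `0.45 * dx^2 / max(alpha)`, inside the explicit stability limit
#'   `dt <= dx^2 / (2 max(alpha))`.
#' @param mushy_halfwidth Half-width, K, of the band around the transition
#'   temperature over which the latent heat is smeared (apparent-heat-capacity
#'   formulation). Default 0.5 K.
#' @return A `grid_spec` object.
#' @export
grid_spec <- function(domain_length, n_nodes, t_end, dt = NULL,
                      mushy_halfwidth = 0.5) {
  if (domain_length <= 0 || n_nodes < 5 || t_end <= 0 || mushy_halfwidth <= 0) {
    stopf("invalid grid specification")
  }
  structure(list(domain_length = domain_length, n_nodes = as.integer(n_nodes),
                 t_end = t_end, dt = dt, mushy_halfwidth = mushy_halfwidth),
            class = "grid_spec")
}

#' Finite-difference solution of the freezing problem (verification oracle)
#'
#' Brute-force, transparent counterpart of [solve_front_constant()]: an
#' explicit conservative enthalpy-method march of the one-dimensional
#' two-phase conduction problem, used in tests and cross-validation of the
#' analytical Neumann solution. The latent heat is released over a narrow
#' mushy band around the onset temperature; the front is located by linear
#' interpolation of the onset-temperature isotherm between nodes.
#'
#' @inheritParams solve_front_constant
#' @param grid A [grid_spec()] object.
#' @param out_times Times at which profiles are recorded, s. Defaults to ten
#'   logarithmically spaced times ending at `t_end`.
#' @return A list of class `fd_solution`:
#' \describe{
#'   \item{x}{node depths, m}
#'   \item{times}{recorded times, s}
#'   \item{temperature}{matrix `length(times)` x `length(x)`, degC}
#'   \item{front}{interpolated front depth at each recorded time, m}
#'   \item{flux_surface}{discrete conductive flux magnitude at the surface, W/m^2}
#'   \item{energy_balance}{relative closure of (boundary-flux time integral)
#'     against the total enthalpy change of the interior nodes}
#' }
#' @export
#' @examples
#' \donttest{
#' props <- liver_tissue_properties()
#' bc <- boundary_conditions(-54, -23, 37)
#' fd <- fd_solve(props, bc, grid_spec(0.01, 201, t_end = 5), out_times = c(1, 5))
#' fd$front
#' }
fd_solve <- function(props, bc, grid, out_times = NULL) {
  props <- as_tissue_properties(props)
  bc <- as_boundary_conditions(bc)
  if (!inherits(grid, "grid_spec")) stopf("grid must be a grid_spec object")

  dx <- grid$domain_length / (grid$n_nodes - 1)
  amax <- max(props$alpha_frozen, props$alpha_unfrozen)
  dt_stab <- dx^2 / (2 * amax)
  dt <- if (is.null(grid$dt)) 0.45 * dx^2 / amax else grid$dt
  if (dt > dt_stab) {
    stopf("explicit stability violated: dt = %.3e exceeds dx^2/(2 max alpha) = %.3e",
          dt, dt_stab)
  }
  if (is.null(out_times)) {
    out_times <- exp(seq(log(grid$t_end / 100), log(grid$t_end), length.out = 10))
  }
  out_times <- sort(unique(out_times))
  if (any(out_times < 0) || max(out_times) > grid$t_end + 1e-9) {
    stopf("out_times must lie within [0, t_end]")
  }
  nsteps <- as.integer(ceiling(grid$t_end / dt))
  out_steps <- pmin(as.integer(round(out_times / dt)), nsteps)

  raw <- .fd_enthalpy_march(
    n = grid$n_nodes, dx = dx, dt = dt, nsteps = nsteps,
    out_steps = out_steps,
    Ts = bc$T_surface, Ti = bc$T_body,
    k1 = props$k_frozen, k2 = props$k_unfrozen,
    c1 = props$c_frozen, c2 = props$c_unfrozen,
    rho = props$rho, L = props$L,
    Tm = bc$T_onset, delta = grid$mushy_halfwidth)

  x <- seq(0, grid$domain_length, length.out = grid$n_nodes)
  front <- apply(raw$temperature, 1, function(Tv) isotherm_depth(x, Tv, bc$T_onset))
  eb <- abs(raw$boundary_energy - raw$enthalpy_change) /
    max(abs(raw$enthalpy_change), .Machine$double.eps)

  structure(list(x = x, times = raw$times, temperature = raw$temperature,
                 front = front, flux_surface = abs(raw$flux_surface),
                 energy_balance = eb, dx = dx, dt = dt,
                 props = props, bc = bc, grid = grid),
            class = "fd_solution")
}

# Depth of the first crossing of `level` along a monotone-in-x profile,
# linearly interpolated between the bracketing nodes.
isotherm_depth <- function(x, Tv, level) {
  below <- Tv <= level
  if (!any(below)) return(0)
  if (all(below)) return(x[length(x)])
  i <- max(which(below))
  x[i] + (level - Tv[i]) / (Tv[i + 1] - Tv[i]) * (x[i + 1] - x[i])
}

#' @export
print.fd_solution <- function(x, ...) {
  cat("Explicit enthalpy-method freezing solution\n")
  cat(sprintf("  grid: %d nodes, dx = %.3g mm, dt = %.3g s, t_end = %g s\n",
              length(x$x), 1000 * x$dx, x$dt, x$grid$t_end))
  cat(sprintf("  energy-balance closure: %.2e (relative)\n", x$energy_balance))
  cat(sprintf("  front at final recorded time %.3g s: %.3f mm\n",
              max(x$times), 1000 * x$front[length(x$front)]))
  invisible(x)
}
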
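#' One-call steady simulation of a conduit flow
#'
#' Convenience wrapper: builds the grid and mask, initializes the state
#' (local-Poiseuille guess by default, which shortens the transient
#' considerably compared to starting from rest), ramps the inflow, advances
#' to steady state, and optionally relaxes the Eulerian linear-damage field
#' over the frozen steady flow.
#'
#' @param geom a [nozzle_geometry()]
#' @param Q volumetric flow rate (m^3/s)
#' @param rheology a `rheology` object
#' @param dr,dz grid spacings (m)
#' @param eos an [eos_params()]
#' @param control a [solver_control()]
#' @param coeff optional [hemolysis_coefficients()]; when supplied the
#'   linear-damage field is solved (scalar transport over the frozen steady
#'   flow, then reported in the returned state)
#' @param init `"poiseuille"` or `"rest"`
#' @param damage_t_end physical-time budget (s) for the damage transport
#'   phase; the default covers several mean transit times
#' @return list with `state`, `grid`, `mask`, `inflow`, `converged`,
#'   `steps`, `residuals`, `max_density_fluctuation`, and (with `coeff`)
#'   `damage` (the damage-phase report)
#' @export
simulate_steady <- function(geom, Q, rheology, dr, dz = 2 * dr,
                            eos = eos_params(), control = solver_control(),
                            coeff = NULL, init = c("poiseuille", "rest"),
                            damage_t_end = NULL) {
  init <- match.arg(init)
  grid <- axi_grid(geom, dr = dr, dz = dz)
  inflow <- inflow_spec(Q, geom)
  st0 <- if (init == "poiseuille")
    make_poiseuille_field(geom, grid, Q, rho0 = eos$rho0)
  else flow_state(grid, rho0 = eos$rho0)
  res <- advance_to_steady(st0, geom, rheology, eos, inflow, control)
  out <- list(state = res$state, grid = grid,
              mask = build_mask(geom, grid), inflow = inflow,
              converged = res$converged, status = res$status,
              steps = res$steps, residuals = res$residuals,
              max_density_fluctuation = res$max_density_fluctuation,
              geom = geom, rheology = rheology, eos = eos)
  if (!is.null(coeff)) {
    if (is.null(damage_t_end)) {
      vol <- geometry_volume(geom)
      damage_t_end <- 8 * vol / Q          # several mean transit times
    }
    dctl <- control
    dctl$t_end <- damage_t_end
    dmg <- solve_damage_field(res$state, geom, rheology, eos, inflow,
                              coeff, dctl)
    out$state <- dmg$state
    out$damage <- dmg[c("converged", "status", "steps", "t")]
  }
  out
}

#' Volumetric flow rate for a target throat Reynolds number
#'
#' \eqn{Re = \rho \bar v D/\mu = 2\rho Q/(\pi \mu R)}, so
#' \eqn{Q = Re\,\pi\,\mu R/(2\rho)}. With the benchmark blood analog
#' (\eqn{\rho} = 1056 kg/m^3, \eqn{\mu} = 3.5 mPa s) and the 2 mm throat
#' radius, Re = 500 gives \eqn{Q \approx 5.21\times 10^{-6}} m^3/s.
#'
#' @param Re target Reynolds number at the throat
#' @param R_throat throat radius (m)
#' @param mu dynamic viscosity (Pa s)
#' @param rho density (kg/m^3)
#' @return volumetric flow rate (m^3/s)
#' @export
flow_rate_for_re <- function(Re = 500, R_throat = 0.002, mu = 0.0035,
                             rho = 1056) {
  Re * pi * mu * R_throat / (2 * rho)
}
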
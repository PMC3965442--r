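#' Solver control parameters
#'
#' @param cfl Courant number for the explicit SSP-RK3 integrator (acoustic
#'   and viscous limits are both enforced), in (0, 1]
#' @param interior_order linear upwind flux-interpolation order in the fluid
#'   interior: 1, 3, 5 or 7; near walls and domain edges the scheme falls
#'   back to 3rd then 1st order automatically
#' @param tol steady-state tolerance: windowed max-norm relative change of
#'   the momentum fields (of the damage field in scalar mode)
#' @param check_every window size in steps between residual checks
#' @param max_steps hard step budget
#' @param t_end hard physical-time budget (s)
#' @param ramp_time inflow ramp duration (s); a smooth ramp suppresses the
#'   start-up acoustic transient
#' @param sponge_cells number of outflow-adjacent columns over which density
#'   and radial momentum relax toward the outlet reference state, absorbing
#'   outgoing acoustic waves; 0 disables the sponge
#' @param sponge_sigma peak relaxation rate (1/s); `NULL` selects
#'   `c0 / (12 L_sponge)` at run time, gentle enough that the sponge itself
#'   reflects only a few percent while still anchoring the mean pressure
#' @param outflow_relax pull strength of the outflow sound speed toward the
#'   reference outlet state, in (0, 1]; it approximates the acoustic
#'   reflection coefficient of the outflow, so small values are nearly
#'   transparent while still anchoring the outlet pressure
#' @param body_force external force per unit mass `c(fr, fz)` (m/s^2)
#' @return a list of class `solver_control`
#' @export
solver_control <- function(cfl = 0.4, interior_order = 7, tol = 1e-8,
                           check_every = 100L, max_steps = 2000000L,
                           t_end = Inf, ramp_time = 0.05,
                           sponge_cells = 16L, sponge_sigma = NULL,
                           outflow_relax = 0, body_force = c(0, 0)) {
  stopifnot(cfl > 0, cfl <= 1, interior_order %in% c(1, 3, 5, 7), tol > 0)
  structure(list(cfl = cfl, interior_order = as.integer(interior_order),
                 tol = tol, check_every = as.integer(check_every),
                 max_steps = as.integer(max_steps), t_end = t_end,
                 ramp_time = ramp_time, sponge_cells = as.integer(sponge_cells),
                 sponge_sigma = sponge_sigma, outflow_relax = outflow_relax,
                 body_force = body_force),
            class = "solver_control")
}

# assemble the parameter list handed to the C++ core
solver_par <- function(grid, rheology, eos, inflow, control,
                       coeff = NULL, bc = c("inout", "periodic"),
                       scalar_only = FALSE, p_out = NULL) {
  bc <- match.arg(bc)
  r <- list(rheol = 0L, mu = 0.0035, mu0 = 0, muinf = 0, lambda = 1,
            acy = 1, ncy = 0.5, ktau = 0, kmu = 1, gcut = 1)
  if (inherits(rheology, "rheology_newtonian")) {
    r$rheol <- 0L; r$mu <- rheology$mu
  } else if (inherits(rheology, "rheology_carreau_yasuda")) {
    r$rheol <- 1L
    r$mu0 <- rheology$mu0; r$muinf <- rheology$mu_inf
    r$lambda <- rheology$lambda; r$acy <- rheology$a; r$ncy <- rheology$n
  } else if (inherits(rheology, "rheology_casson")) {
    r$rheol <- 2L
    r$ktau <- rheology$k_tau; r$kmu <- rheology$k_mu
    r$gcut <- rheology$gamma_cutoff
  } else stop("unknown rheology")
  hemo_on <- 0L; c1a <- 0; ba <- 1
  if (!is.null(coeff)) {
    stopifnot(inherits(coeff, "hemolysis_coefficients"))
    hemo_on <- 1L
    c1a <- coeff$C^(1 / coeff$a); ba <- coeff$b / coeff$a
  }
  sigma <- control$sponge_sigma
  if (is.null(sigma))
    sigma <- eos$c0 / (12 * max(control$sponge_cells * grid$dz, grid$dz))
  list(ghost = grid$ghost, dr = grid$dr, dz = grid$dz, zmin = grid$z_min,
       rho0 = eos$rho0, c0 = eos$c0, p0 = eos$p0, gam = eos$gamma_ad,
       rheol = r$rheol, mu = r$mu, mu0 = r$mu0, muinf = r$muinf,
       lambda = r$lambda, acy = r$acy, ncy = r$ncy,
       ktau = r$ktau, kmu = r$kmu, gcut = r$gcut,
       vmax = inflow$vmax, Rin = inflow$R_inlet,
       ramp = if (scalar_only) 0 else control$ramp_time,
       bc = if (bc == "periodic") 1L else 0L,
       sponge_n = if (bc == "periodic") 0L else control$sponge_cells,
       sponge_sigma = sigma,
       hemo_on = hemo_on, c1a = c1a, ba = ba,
       fr = control$body_force[1], fz = control$body_force[2],
       order = control$interior_order,
       out_relax = control$outflow_relax,
       p_out = if (is.null(p_out)) eos$p0 else p_out,
       scalar_only = if (scalar_only) 1L else 0L)
}

#' Inflow specification from a volumetric flow rate
#'
#' @param Q volumetric flow rate (m^3/s)
#' @param geom a [nozzle_geometry()]; the inlet radius is `R(z_min)`
#' @return list with `Q`, `R_inlet`, `vmax` (Poiseuille centerline velocity)
#' @export
inflow_spec <- function(Q, geom) {
  R <- radius_at(geom, geom$z_min)
  list(Q = Q, R_inlet = R, vmax = poiseuille_vmax(Q, R))
}

#' Right-hand side of the semi-discrete system
#'
#' Evaluates the time derivative of all conservative fields (mass, momentum,
#' linear-damage density) for a given state, after filling ghost layers with
#' the boundary operators. Mainly a verification hook: the rest state has an
#' identically zero RHS, and an analytic Poiseuille state with its matching
#' pressure gradient has a momentum residual converging to zero with the
#' grid.
#'
#' @param state a [flow_state()]
#' @param geom a [nozzle_geometry()]
#' @param rheology,eos model objects
#' @param inflow an [inflow_spec()]; use `inflow_spec(0, geom)` for closed
#'   tests
#' @param control a [solver_control()]
#' @param bc `"inout"` (characteristic inflow/outflow) or `"periodic"`
#' @param coeff optional [hemolysis_coefficients()] enabling the damage
#'   source
#' @return list of matrices `drho`, `dmr`, `dmz`, `drhoDl`
#' @export
ns_rhs <- function(state, geom, rheology, eos, inflow = NULL,
                   control = solver_control(), bc = "inout", coeff = NULL) {
  grid <- state$grid
  if (is.null(inflow)) inflow <- inflow_spec(0, geom)
  if (!all(is.finite(state$rho)) || !all(is.finite(state$mr)) ||
      !all(is.finite(state$mz)) || !all(is.finite(state$rhoDl))) {
    bad <- which(!is.finite(state$rho) | !is.finite(state$mr) |
                   !is.finite(state$mz) | !is.finite(state$rhoDl),
                 arr.ind = TRUE)
    stop("non-finite state at cell (", bad[1, 1], ", ", bad[1, 2], ")")
  }
  mask <- build_mask(geom, grid)
  par <- solver_par(grid, rheology, eos, inflow, control, coeff, bc)
  par$ramp <- 0   # single evaluations see the un-ramped inflow
  cpp_rhs(state$rho, state$mr, state$mz, state$rhoDl,
          matrix(as.integer(mask), grid$nr, grid$nz), par, state$t)
}

#' Apply boundary operators and return the ghost-padded state
#'
#' Fills the ghost layers: Poiseuille velocity at the inflow (density free
#' via the outgoing characteristic), reference-pressure anchoring of the
#' incoming characteristic at the outflow, reflection parity across the
#' symmetry axis, and no-slip extrapolation into wall cells. Returned
#' matrices are `(nr + 2 ghost) x (nz + 2 ghost)`.
#'
#' @inheritParams ns_rhs
#' @return list of padded matrices `rho`, `mr`, `mz`, `rhoDl`, the padded
#'   availability `mask` and the signed radial coordinates `r`
#' @export
apply_boundaries <- function(state, geom, rheology, eos, inflow = NULL,
                             control = solver_control(), bc = "inout") {
  grid <- state$grid
  if (is.null(inflow)) inflow <- inflow_spec(0, geom)
  mask <- build_mask(geom, grid)
  par <- solver_par(grid, rheology, eos, inflow, control, NULL, bc)
  par$ramp <- 0
  cpp_fill_ghosts(state$rho, state$mr, state$mz, state$rhoDl,
                  matrix(as.integer(mask), grid$nr, grid$nz), par, state$t)
}

#' Advance the flow to a steady state
#'
#' Explicit SSP-RK3 time stepping under a combined acoustic + viscous CFL
#' limit, until the windowed max-norm relative change of the momentum fields
#' drops below `control$tol` (or a step/time budget is reached). The inflow
#' is ramped up smoothly over `control$ramp_time` to suppress start-up
#' acoustic waves; the non-reflecting outflow treatment and the sponge layer
#' absorb what remains. Deterministic given the configuration.
#'
#' @param state initial [flow_state()] (e.g. rest, or a
#'   [make_poiseuille_field()] guess, which converges much faster)
#' @param geom a [nozzle_geometry()]
#' @param rheology,eos model objects
#' @param inflow an [inflow_spec()]
#' @param control a [solver_control()]
#' @param coeff optional [hemolysis_coefficients()]: when given, the
#'   conservative linear-damage field is co-evolved with its shear-stress
#'   source
#' @param bc `"inout"` or `"periodic"`
#' @return list with the final `state` (a [flow_state()]), `converged`
#'   (logical), `status` (`"converged"`, `"max_steps"` or `"diverged"`),
#'   `steps`, `t`, `residuals`, `max_density_fluctuation`
#' @export
advance_to_steady <- function(state, geom, rheology, eos, inflow,
                              control = solver_control(), coeff = NULL,
                              bc = "inout") {
  grid <- state$grid
  mask <- build_mask(geom, grid)
  par <- solver_par(grid, rheology, eos, inflow, control, coeff, bc)
  out <- cpp_advance(state$rho, state$mr, state$mz, state$rhoDl,
                     matrix(as.integer(mask), grid$nr, grid$nz), par,
                     state$t, control$t_end, control$max_steps,
                     control$cfl, control$tol, control$check_every, 0L)
  if (out$status == 3)
    stop("solver diverged (non-finite fields) after ", out$steps, " steps")
  st <- flow_state(grid, rho = out$rho, mr = out$mr, mz = out$mz,
                   rhoDl = out$rhoDl, t = out$t)
  list(state = st, converged = out$converged,
       status = c("converged", "converged", "max_steps", "diverged")[out$status + 1],
       steps = out$steps, t = out$t, residuals = out$residuals,
       max_density_fluctuation = out$max_density_fluctuation)
}

#' Evolve the Eulerian linear-damage field over a frozen velocity field
#'
#' Advects the conservative linear-damage density with its shear-stress
#' source while holding the (already steady) flow fixed. Because the
#' acoustic CFL constraint disappears in this mode, the damage field reaches
#' its own steady state at a fraction of the cost of co-evolving it with
#' the flow; the result is identical up to the steady-state tolerance.
#'
#' @inheritParams advance_to_steady
#' @param coeff a [hemolysis_coefficients()] (required)
#' @return same structure as [advance_to_steady()]
#' @export
solve_damage_field <- function(state, geom, rheology, eos, inflow, coeff,
                               control = solver_control(), bc = "inout") {
  stopifnot(inherits(coeff, "hemolysis_coefficients"))
  grid <- state$grid
  mask <- build_mask(geom, grid)
  par <- solver_par(grid, rheology, eos, inflow, control, coeff, bc,
                    scalar_only = TRUE)
  out <- cpp_advance(state$rho, state$mr, state$mz, state$rhoDl,
                     matrix(as.integer(mask), grid$nr, grid$nz), par,
                     state$t, control$t_end, control$max_steps,
                     control$cfl, control$tol, control$check_every, 1L)
  if (out$status == 3)
    stop("damage transport diverged after ", out$steps, " steps")
  st <- flow_state(grid, rho = out$rho, mr = out$mr, mz = out$mz,
                   rhoDl = out$rhoDl, t = out$t)
  list(state = st, converged = out$converged,
       status = c("converged", "converged", "max_steps", "diverged")[out$status + 1],
       steps = out$steps, t = out$t, residuals = out$residuals)
}
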
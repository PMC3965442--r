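#' Flow state container
#'
#' Conservative fields of the weakly-compressible axisymmetric system on a
#' cell-centered grid: density `rho`, momentum densities `mr`, `mz`
#' (kg m^-2 s^-1), and the conservative linear-damage density `rhoDl`
#' (density times the dimensionless linear damage). Solid cells hold the
#' reference density and zero momentum.
#'
#' @param grid an [axi_grid()]
#' @param rho,mr,mz,rhoDl `nr x nz` matrices (defaults: rest state at `rho0`)
#' @param rho0 reference density used to fill defaults (kg/m^3)
#' @param t simulation time carried by the state (s)
#' @return object of class `flow_state`
#' @export
flow_state <- function(grid, rho = NULL, mr = NULL, mz = NULL, rhoDl = NULL,
                       rho0 = 1056, t = 0) {
  stopifnot(inherits(grid, "axi_grid"))
  dims <- c(grid$nr, grid$nz)
  zero <- matrix(0, dims[1], dims[2])
  if (is.null(rho)) rho <- matrix(rho0, dims[1], dims[2])
  if (is.null(mr)) mr <- zero
  if (is.null(mz)) mz <- zero
  if (is.null(rhoDl)) rhoDl <- zero
  for (f in list(rho, mr, mz, rhoDl))
    stopifnot(all(dim(f) == dims), all(is.finite(f)))
  if (any(rho <= 0)) stop("density must be strictly positive everywhere")
  if (any(rhoDl < 0)) stop("linear-damage density must be non-negative")
  structure(list(rho = rho, mr = mr, mz = mz, rhoDl = rhoDl,
                 t = t, grid = grid),
            class = "flow_state")
}

#' @export
print.flow_state <- function(x, ...) {
  cat(sprintf("<flow_state> %d x %d cells, t = %g s, max |v| = %.4g m/s\n",
              x$grid$nr, x$grid$nz, x$t,
              max(sqrt((x$mr / x$rho)^2 + (x$mz / x$rho)^2))))
  invisible(x)
}

#' Velocity components of a flow state
#'
#' @param state a [flow_state()]
#' @return list with matrices `vr`, `vz` (m/s)
#' @export
velocity <- function(state) {
  stopifnot(inherits(state, "flow_state"))
  list(vr = state$mr / state$rho, vz = state$mz / state$rho)
}

#' Poiseuille centerline velocity for a volumetric flow rate
#'
#' Integrating the parabolic profile
#' \eqn{v_z(r) = v_{\max}\,[1-(r/R)^2]} over the cross-section gives
#' \eqn{Q = \pi R^2 v_{\max}/2}, hence \eqn{v_{\max} = 2Q/(\pi R^2)}.
#'
#' @param Q volumetric flow rate (m^3/s)
#' @param R tube radius (m)
#' @return centerline velocity (m/s)
#' @export
poiseuille_vmax <- function(Q, R) 2 * Q / (pi * R^2)

#' Analytic Poiseuille flow field fixture
#'
#' Builds a [flow_state()] whose axial velocity is the local Poiseuille
#' profile for the given flow rate at every axial station,
#' \eqn{v_z(r,z) = \frac{2Q}{\pi R(z)^2}\,[1-(r/R(z))^2]}, with
#' \eqn{v_r = 0} and uniform density. For a straight tube this is the exact
#' steady Navier-Stokes solution; for slowly varying geometry it is the
#' local-Poiseuille approximation underlying the analytic hemolysis bound.
#' The returned state carries an `analytic` attribute with closed-form
#' shear stress, wall shear stress and transit-time oracles (Newtonian
#' viscosity `mu`).
#'
#' @param geom a [nozzle_geometry()]
#' @param grid an [axi_grid()]
#' @param Q volumetric flow rate (m^3/s), non-negative
#' @param rho0 density (kg/m^3)
#' @param mu Newtonian viscosity used by the analytic metadata (Pa s)
#' @return a [flow_state()]; `attr(, "analytic")` holds functions
#'   `vz(r, z)`, `tau(r, z)`, `wss(z)`, `transit_time(s)` (relative seed
#'   radius `s`, straight tubes), and the mask.
#' @export
make_poiseuille_field <- function(geom, grid, Q, rho0 = 1056, mu = 0.0035) {
  stopifnot(Q >= 0)
  mask <- build_mask(geom, grid)
  R <- radius_at(geom, pmin(pmax(grid$z, geom$z_min), geom$z_max))
  vz <- matrix(0, grid$nr, grid$nz)
  for (j in seq_len(grid$nz)) {
    prof <- 2 * Q / (pi * R[j]^2) * (1 - (grid$r / R[j])^2)
    prof[grid$r > R[j]] <- 0
    vz[, j] <- prof
  }
  vz[!mask] <- 0
  st <- flow_state(grid,
                   rho = matrix(rho0, grid$nr, grid$nz),
                   mz = rho0 * vz, rho0 = rho0)
  L <- geom$z_max - geom$z_min
  analytic <- list(
    mask = mask,
    vz = function(r, z) {
      Rz <- radius_at(geom, z)
      ifelse(r <= Rz, 2 * Q / (pi * Rz^2) * (1 - (r / Rz)^2), 0)
    },
    tau = function(r, z) {
      Rz <- radius_at(geom, z)
      ifelse(r <= Rz, 4 * mu * Q * r / (pi * Rz^4), 0)
    },
    wss = function(z) {
      Rz <- radius_at(geom, z)
      4 * mu * Q / (pi * Rz^3)
    },
    dpdz = function(z) {
      Rz <- radius_at(geom, z)
      -8 * mu * Q / (pi * Rz^4)
    },
    transit_time = function(s) {
      # straight tube: t = L / v_z(s); s = r/R relative radius
      R0 <- radius_at(geom, geom$z_min)
      L / (2 * Q / (pi * R0^2) * (1 - s^2))
    })
  attr(st, "analytic") <- analytic
  st
}

#' Divergence-free perturbed Poiseuille fixture
#'
#' Adds a smooth, exactly divergence-free axisymmetric perturbation to the
#' Poiseuille fixture, built from a Stokes streamfunction
#' \eqn{\psi(r,z) = A\, r^2 (1-(r/R)^2)^2 \sum_k \sin(k_z z + \phi_k)} with
#' randomized axial phases, so that \eqn{v_r = -\partial_z\psi / r},
#' \eqn{v_z = \partial_r\psi / r} vanish at the wall and on the axis.
#' Used to exercise the robustness of indicators and pathline tracing.
#'
#' @param geom,grid,Q,rho0,mu as in [make_poiseuille_field()]
#' @param amplitude perturbation velocity scale (m/s), non-negative
#' @param seed integer seed fixing the random phases
#' @param n_modes number of axial Fourier modes
#' @return a [flow_state()]
#' @export
make_perturbed_field <- function(geom, grid, Q, amplitude, seed = 1L,
                                 rho0 = 1056, mu = 0.0035, n_modes = 3L) {
  if (amplitude < 0) stop("perturbation amplitude must be non-negative")
  base <- make_poiseuille_field(geom, grid, Q, rho0 = rho0, mu = mu)
  if (amplitude == 0) return(base)
  mask <- attr(base, "analytic")$mask
  rng <- local({ set.seed(seed); list(ph = stats::runif(n_modes, 0, 2 * pi),
                                      am = stats::runif(n_modes, 0.5, 1)) })
  L <- grid$z_max - grid$z_min
  Rz <- radius_at(geom, pmin(pmax(grid$z, geom$z_min), geom$z_max))
  vr <- matrix(0, grid$nr, grid$nz); vz <- matrix(0, grid$nr, grid$nz)
  for (j in seq_len(grid$nz)) {
    R <- Rz[j]
    r <- grid$r
    shape  <- r^2 * (1 - (r / R)^2)^2            # psi / (A sin term)
    dshape <- 2 * r * (1 - (r / R)^2)^2 +
      r^2 * 2 * (1 - (r / R)^2) * (-2 * r / R^2)
    s <- 0; ds <- 0
    for (k in seq_len(n_modes)) {
      kz <- 2 * pi * k / L
      s  <- s  + rng$am[k] * sin(kz * grid$z[j] + rng$ph[k])
      ds <- ds + rng$am[k] * kz * cos(kz * grid$z[j] + rng$ph[k])
    }
    vr[, j] <- -shape * ds / r
    vz[, j] <- dshape * s / r
    vr[r > R, j] <- 0; vz[r > R, j] <- 0
  }
  # normalize so the perturbation's max speed equals `amplitude`
  sc <- amplitude / max(sqrt(vr^2 + vz^2))
  vmix <- velocity(base)
  st <- flow_state(grid, rho = base$rho,
                   mr = rho0 * sc * vr,
                   mz = rho0 * (vmix$vz + sc * vz), rho0 = rho0)
  st$mr[!mask] <- 0; st$mz[!mask] <- 0
  attr(st, "analytic") <- attr(base, "analytic")
  st
}
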
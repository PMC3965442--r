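#' Trace pathlines through a steady flow field
#'
#' Integrates \eqn{dx/dt = v(x)} with classical RK4 and an adaptive step
#' bounded by a fraction of the local cell-transit time, from seeds on an
#' inlet radial section to the outlet. Velocity and shear-stress magnitude
#' are interpolated bilinearly from cell centers (solid cells carry zero
#' velocity, so trajectories cannot penetrate walls). Under steady
#' conditions pathlines and streamlines coincide.
#'
#' Seeds are placed by default at equal-flow-increment radii of the inlet
#' Poiseuille profile — the flux fraction inside relative radius \eqn{s} is
#' \eqn{F(s) = 2s^2 - s^4}, so the k-th of n seeds sits at
#' \eqn{s_k = \sqrt{1 - \sqrt{1 - F_k}}}, \eqn{F_k = (k-1/2)/n} — giving
#' every pathline the same flow weight. Pathlines that fail to reach the
#' outlet within `max_transit_factor` times the mean transit time (e.g.
#' trapped in a recirculation bubble) are flagged `stalled` and excluded
#' from averages, with a count in the returned set.
#'
#' @param state a steady [flow_state()]
#' @param geom a [nozzle_geometry()]
#' @param rheology a `rheology` object used to evaluate the shear-stress
#'   magnitude \eqn{\tau = \mu(\dot\gamma)\dot\gamma} along the path
#' @param n_seeds number of seeds on the inlet section
#' @param seed_fracs optional explicit relative radii \eqn{s \in (0,1)} of
#'   the seeds (overrides `n_seeds`; weights then follow the inlet profile
#'   flux increments)
#' @param step_frac RK step as a fraction of the local cell-transit time
#' @param max_transit_factor stall budget in mean-transit-time units
#' @param sample_every keep every k-th integration sample in the stored
#'   history (damage accumulation always uses every step)
#' @return object of class `pathline_set`: list with `pathlines` (each has
#'   `t`, `r`, `z`, `tau` histories, final `Dl`, `weight`, `stalled`),
#'   `n_stalled`, and the hemolysis coefficients are *not* applied here —
#'   damage conversion happens in [average_nih_pathlines()].
#' @param coeff a [hemolysis_coefficients()]; the linear-damage rate
#'   \eqn{C^{1/a}\tau^{b/a}} is accumulated exactly along the integration
#' @export
trace_pathlines <- function(state, geom, rheology, coeff,
                            n_seeds = 64L, seed_fracs = NULL,
                            step_frac = 0.25, max_transit_factor = 50,
                            sample_every = 5L) {
  stopifnot(inherits(state, "flow_state"), inherits(geom, "nozzle_geometry"),
            inherits(rheology, "rheology"),
            inherits(coeff, "hemolysis_coefficients"))
  grid <- state$grid
  mask <- build_mask(geom, grid)
  v <- velocity(state)
  v$vr[!mask] <- 0; v$vz[!mask] <- 0
  S <- shear_rate_tensor(v$vr, v$vz, grid, mask)
  gam <- effective_shear_rate(S)
  tau_f <- viscosity(rheology, gam) * gam
  tau_f[!mask] <- 0

  interp <- function(F, r, z) bilinear(F, grid, r, z)

  R_in <- radius_at(geom, geom$z_min)
  if (is.null(seed_fracs)) {
    Fk <- (seq_len(n_seeds) - 0.5) / n_seeds
    s <- sqrt(1 - sqrt(1 - Fk))
    w <- rep(1 / n_seeds, n_seeds)
  } else {
    s <- sort(seed_fracs)
    stopifnot(all(s > 0), all(s < 1))
    edges <- c(0, (s[-1] + s[-length(s)]) / 2, 1)
    Fr <- function(x) 2 * x^2 - x^4
    w <- diff(Fr(edges))
  }
  z0 <- grid$z[1]
  z_out <- grid$z[grid$nz]
  # mean transit time: fluid volume / Q estimate from the inlet flux
  mdot_r <- sum(state$rho[, 1] * v$vz[, 1] * grid$r * mask[, 1]) *
    2 * pi * grid$dr
  Qest <- mdot_r / mean(state$rho[mask[, 1], 1])
  vol <- geometry_volume(geom)
  t_budget <- max_transit_factor * vol / max(Qest, .Machine$double.eps)

  rate_coef <- coeff$C^(1 / coeff$a); rate_exp <- coeff$b / coeff$a
  hmin <- min(grid$dr, grid$dz)

  pathlines <- vector("list", length(s))
  for (k in seq_along(s)) {
    r <- s[k] * R_in; z <- z0; t <- 0; Dl <- 0
    ts <- t; rs <- r; zs <- z
    tau_prev <- interp(tau_f, r, z)
    taus <- tau_prev
    n_step <- 0L; stalled <- FALSE
    repeat {
      vr1 <- interp(v$vr, r, z); vz1 <- interp(v$vz, r, z)
      sp <- sqrt(vr1^2 + vz1^2)
      if (sp < 1e-12) { stalled <- TRUE; break }
      # direction-aware step: a fraction of the local cell-transit time
      h <- step_frac / (abs(vr1) / grid$dr + abs(vz1) / grid$dz)
      # RK4 on (r, z)
      k1r <- vr1; k1z <- vz1
      k2r <- interp(v$vr, r + h / 2 * k1r, z + h / 2 * k1z)
      k2z <- interp(v$vz, r + h / 2 * k1r, z + h / 2 * k1z)
      k3r <- interp(v$vr, r + h / 2 * k2r, z + h / 2 * k2z)
      k3z <- interp(v$vz, r + h / 2 * k2r, z + h / 2 * k2z)
      k4r <- interp(v$vr, r + h * k3r, z + h * k3z)
      k4z <- interp(v$vz, r + h * k3r, z + h * k3z)
      r_new <- r + h / 6 * (k1r + 2 * k2r + 2 * k3r + k4r)
      z_new <- z + h / 6 * (k1z + 2 * k2z + 2 * k3z + k4z)
      r_new <- max(r_new, grid$dr / 2)
      tau_new <- interp(tau_f, r_new, z_new)
      Dl <- Dl + h * rate_coef * (tau_prev^rate_exp + tau_new^rate_exp) / 2
      tau_prev <- tau_new
      t <- t + h; r <- r_new; z <- z_new
      n_step <- n_step + 1L
      if (n_step %% sample_every == 0L || z >= z_out) {
        ts <- c(ts, t); rs <- c(rs, r); zs <- c(zs, z); taus <- c(taus, tau_new)
      }
      if (z >= z_out) break
      if (t > t_budget) { stalled <- TRUE; break }
    }
    pathlines[[k]] <- list(seed_s = s[k], seed_r = s[k] * R_in,
                           t = ts, r = rs, z = zs, tau = taus,
                           transit_time = t, Dl = Dl, weight = w[k],
                           stalled = stalled)
  }
  stalled_n <- sum(vapply(pathlines, function(p) p$stalled, logical(1)))
  if (stalled_n > 0)
    warning(stalled_n, " pathline(s) stalled before reaching the outlet; ",
            "excluded from averages")
  structure(list(pathlines = Filter(function(p) !p$stalled, pathlines),
                 all_pathlines = pathlines,
                 n_stalled = stalled_n, n_seeds = length(s)),
            class = "pathline_set")
}

#' @export
print.pathline_set <- function(x, ...) {
  cat(sprintf("<pathline_set> %d seeds, %d completed, %d stalled\n",
              x$n_seeds, length(x$pathlines), x$n_stalled))
  invisible(x)
}

# bilinear interpolation of a cell-centered field; clamps to the domain
bilinear <- function(F, grid, r, z) {
  x <- (r / grid$dr) + 0.5        # fractional radial index
  y <- (z - grid$z_min) / grid$dz + 0.5
  x <- min(max(x, 1), grid$nr); y <- min(max(y, 1), grid$nz)
  i0 <- floor(x); j0 <- floor(y)
  i0 <- min(max(i0, 1), grid$nr - 1); j0 <- min(max(j0, 1), grid$nz - 1)
  fx <- x - i0; fy <- y - j0
  F[i0, j0] * (1 - fx) * (1 - fy) + F[i0 + 1, j0] * fx * (1 - fy) +
    F[i0, j0 + 1] * (1 - fx) * fy + F[i0 + 1, j0 + 1] * fx * fy
}
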
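# Independent oracles and shared small fixtures.

default_coeff <- hemolysis_coefficients()

# Lagrangian-Poiseuille brute-force oracle for the averaged damage:
# assume a Poiseuille profile with flow rate Q at every z; streamlines sit
# at fixed relative radius s with tau = 4 mu Q s / (pi R^3) and
# dt = pi R^2 dz / (2 Q (1 - s^2)); integrate the linear-damage rate in z,
# un-linearize, flow-weight-average over s (dF = 4 s (1 - s^2) ds).
# Quadrature is performed segment-wise so radius jumps are handled exactly.
lagrangian_poiseuille_oracle <- function(geom, mu, Q, coeff) {
  seg <- geom$segments
  Dl_of_s <- function(s) {
    tot <- 0
    for (k in seq_len(nrow(seg))) {
      f <- function(z) {
        R <- seg$R_start[k] + (z - seg$z_start[k]) /
          (seg$z_end[k] - seg$z_start[k]) * (seg$R_end[k] - seg$R_start[k])
        (4 * mu * Q * s / (pi * R^3))^(coeff$b / coeff$a) * pi * R^2 /
          (2 * Q * (1 - s^2))
      }
      tot <- tot + stats::integrate(f, seg$z_start[k], seg$z_end[k],
                                    rel.tol = 1e-12)$value
    }
    coeff$C^(1 / coeff$a) * tot
  }
  D <- stats::integrate(
    Vectorize(function(s) Dl_of_s(s)^coeff$a * 4 * s * (1 - s^2)),
    0, 1, rel.tol = 1e-10)$value
  list(D = D, NIH = nih_from_damage(D, coeff))
}

# memoized small solver runs shared between solver tests
.run_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!is.null(.run_cache[[key]])) return(.run_cache[[key]])
  .run_cache[[key]] <- force(expr)
  .run_cache[[key]]
}

# small straight-tube steady solve used by several tests
poiseuille_steady_run <- function() {
  cached("poiseuille_steady", {
    geom <- straight_tube(0.002, 0.02)
    Q <- 2e-6
    ctl <- solver_control(tol = 1e-7, t_end = 0.45, ramp_time = 0.02,
                          sponge_cells = 8L)
    sim <- simulate_steady(geom, Q, rheology_newtonian(), dr = 2.5e-4,
                           dz = 5e-4, control = ctl, init = "rest")
    sim$Q <- Q
    sim
  })
}
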
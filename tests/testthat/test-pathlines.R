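co <- default_coeff

test_that("uniform axial flow gives equal transit times; axis seed stays on axis", {
  geom <- straight_tube(0.002, 0.02)
  grid <- axi_grid(geom, dr = 1e-4, dz = 5e-4)
  v0 <- 0.25
  st <- flow_state(grid, mz = matrix(1056 * v0, grid$nr, grid$nz))
  pl <- trace_pathlines(st, geom, rheology_newtonian(), co,
                        seed_fracs = c(0.05, 0.3, 0.6, 0.9))
  expect_equal(pl$n_stalled, 0)
  tt <- vapply(pl$pathlines, function(p) p$transit_time, numeric(1))
  # transit ~ L / v0 for every seed (first/last half-cells excluded by the
  # cell-centered seeding/termination stations)
  L_eff <- grid$z[grid$nz] - grid$z[1]
  expect_equal(tt, rep(L_eff / v0, 4), tolerance = 0.02)
  # radial drift stays within a cell for all seeds
  for (p in pl$pathlines)
    expect_lt(max(abs(p$r - p$seed_r)), grid$dr)
})

test_that("Poiseuille pathlines carry constant analytic shear stress and transit times", {
  geom <- straight_tube(0.002, 0.04)
  grid <- axi_grid(geom, dr = 1e-4, dz = 5e-4)
  Q <- flow_rate_for_re(500)
  fix <- make_poiseuille_field(geom, grid, Q)
  ana <- attr(fix, "analytic")
  pl <- trace_pathlines(fix, geom, rheology_newtonian(), co,
                        seed_fracs = c(0.2, 0.5, 0.8))
  for (p in pl$pathlines) {
    tau_ana <- ana$tau(p$seed_r, 0.02)
    expect_equal(stats::median(p$tau), tau_ana, tolerance = 0.02)
    expect_equal(p$transit_time, ana$transit_time(p$seed_s), tolerance = 0.03)
  }
})

test_that("pathline NIH approaches the analytic bound on a Poiseuille tube", {
  geom <- straight_tube(0.002, 0.04)
  grid <- axi_grid(geom, dr = 1e-4, dz = 5e-4)
  Q <- flow_rate_for_re(500)
  fix <- make_poiseuille_field(geom, grid, Q)
  ana <- analytic_lower_bound(geom, 0.0035, Q, co)
  pl64 <- trace_pathlines(fix, geom, rheology_newtonian(), co, n_seeds = 64)
  nih64 <- average_nih_pathlines(pl64, co)$NIH
  # the flow-weighted damage density is weakly singular at the wall, so the
  # equal-flow-increment seed quadrature converges slowly from below
  expect_equal(nih64, ana$NIH, tolerance = 0.08)
  pl128 <- trace_pathlines(fix, geom, rheology_newtonian(), co, n_seeds = 128)
  nih128 <- average_nih_pathlines(pl128, co)$NIH
  expect_lt(abs(nih128 - ana$NIH), abs(nih64 - ana$NIH))  # seed convergence
  expect_equal(nih128, ana$NIH, tolerance = 0.05)
})

test_that("Eulerian averaging of a manufactured linear-damage field matches the closed form", {
  geom <- straight_tube(0.002, 0.04)
  grid <- axi_grid(geom, dr = 1e-4, dz = 5e-4)
  Q <- flow_rate_for_re(500)
  fix <- make_poiseuille_field(geom, grid, Q)
  mu <- 0.0035
  Dl_sz <- function(r, z) {
    R <- 0.002; s <- pmin(r / R, 1)
    co$C^(1 / co$a) * (4 * mu * Q / pi)^(co$b / co$a) * s^(co$b / co$a) *
      pi / (2 * Q * (1 - s^2)) * (z - geom$z_min) * R^(2 - 3 * co$b / co$a)
  }
  st <- flow_state(grid, rho = fix$rho, mr = fix$mr, mz = fix$mz,
                   rhoDl = fix$rho * outer(grid$r, grid$z, Dl_sz))
  prof <- eulerian_nih_profile(st, geom, co)
  expect_true(all(diff(prof$value) >= -1e-15))     # non-decreasing along z
  expect_lt(prof$value[1] / max(prof$value), 0.02) # ~zero at the inlet
  ana <- analytic_lower_bound(geom, mu, Q, co)
  expect_equal(utils::tail(prof$value, 1), ana$NIH, tolerance = 0.01)
  # zero damage field gives identically zero NIH
  st0 <- flow_state(grid, rho = fix$rho, mr = fix$mr, mz = fix$mz)
  expect_equal(max(abs(eulerian_nih_profile(st0, geom, co)$value)), 0)
})

test_that("cross-route consistency: pathline vs Eulerian NIH on the fixture", {
  geom <- straight_tube(0.002, 0.04)
  grid <- axi_grid(geom, dr = 1e-4, dz = 5e-4)
  Q <- flow_rate_for_re(500)
  fix <- make_poiseuille_field(geom, grid, Q)
  mu <- 0.0035
  Dl_sz <- function(r, z) {
    R <- 0.002; s <- pmin(r / R, 1)
    co$C^(1 / co$a) * (4 * mu * Q / pi)^(co$b / co$a) * s^(co$b / co$a) *
      pi / (2 * Q * (1 - s^2)) * (z - geom$z_min) * R^(2 - 3 * co$b / co$a)
  }
  st <- flow_state(grid, rho = fix$rho, mr = fix$mr, mz = fix$mz,
                   rhoDl = fix$rho * outer(grid$r, grid$z, Dl_sz))
  eul <- utils::tail(eulerian_nih_profile(st, geom, co)$value, 1)
  pl <- trace_pathlines(fix, geom, rheology_newtonian(), co, n_seeds = 128)
  path <- average_nih_pathlines(pl, co)$NIH
  expect_equal(path, eul, tolerance = 0.05)
})
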
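eos <- eos_params()

test_that("rest state is a discrete equilibrium of the RHS", {
  geom <- straight_tube(0.002, 0.02)
  grid <- axi_grid(geom, dr = 2.5e-4, dz = 5e-4)
  st <- flow_state(grid)
  rhs <- ns_rhs(st, geom, rheology_newtonian(), eos)
  expect_equal(max(abs(rhs$drho)), 0)
  expect_equal(max(abs(rhs$drhoDl)), 0)
  # momentum residual is pure roundoff of the large p/r cancellation
  expect_lt(max(abs(rhs$dmr)), 1e-6)
  expect_lt(max(abs(rhs$dmz)), 1e-6)
  bad <- st
  bad$mr[2, 3] <- NaN
  expect_error(ns_rhs(bad, geom, rheology_newtonian(), eos), "non-finite")
})

test_that("boundary fill: rest no-op, Poiseuille inflow ghosts, axis parity", {
  geom <- straight_tube(0.002, 0.02)
  grid <- axi_grid(geom, dr = 2.5e-4, dz = 5e-4)
  st <- flow_state(grid)
  Q <- 2e-6
  bf <- apply_boundaries(st, geom, rheology_newtonian(), eos,
                         inflow = inflow_spec(Q, geom))
  g <- grid$ghost
  # interior untouched
  expect_equal(bf$rho[(g + 1):(g + grid$nr), (g + 1):(g + grid$nz)], st$rho)
  # inflow ghost velocity peaks at v_max = 2Q/(pi R^2) near the axis
  vz_ghost <- bf$mz[g + 1, 1:g] / bf$rho[g + 1, 1:g]
  vmax <- poiseuille_vmax(Q, 0.002)
  expect_equal(vz_ghost, rep(vmax * (1 - (grid$r[1] / 0.002)^2), g),
               tolerance = 1e-12)
  # axis parity: rho even, m_r odd
  expect_equal(bf$rho[g, ], bf$rho[g + 1, ])
  expect_equal(bf$mr[g, ], -bf$mr[g + 1, ])
})

test_that("closed periodic box conserves mass to roundoff per step", {
  geom <- straight_tube(0.002, 0.01)
  grid <- axi_grid(geom, dr = 2.5e-4, dz = 5e-4)
  set.seed(5)
  rho <- matrix(1056, grid$nr, grid$nz) +
    matrix(rnorm(grid$nr * grid$nz, 0, 0.5), grid$nr, grid$nz)
  st <- flow_state(grid, rho = rho)
  ctl <- solver_control(tol = 1e-30, t_end = Inf, max_steps = 400L,
                        ramp_time = 0)
  out <- advance_to_steady(st, geom, rheology_newtonian(), eos,
                           inflow_spec(0, geom), ctl, bc = "periodic")
  mass0 <- sum(rho * grid$r)
  mass1 <- sum(out$state$rho * grid$r)
  expect_lt(abs(mass1 - mass0) / mass0 / 400, 1e-12)
})

test_that("straight-tube steady solve recovers Poiseuille flow and pressure slope", {
  sim <- poiseuille_steady_run()
  expect_true(sim$converged)
  grid <- sim$grid
  v <- velocity(sim$state)
  vz_ana <- poiseuille_vmax(sim$Q, 0.002) * (1 - (grid$r / 0.002)^2)
  j <- round(grid$nz * 0.6)
  l2 <- sqrt(sum((v$vz[, j] - vz_ana)^2) / sum(vz_ana^2))
  expect_lt(l2, 0.01)
  pd <- pressure_drop_profile(sim$state, eos)
  jj <- 8:32
  slope <- stats::coef(stats::lm(pd$value[jj] ~ grid$z[jj]))[[2]]
  expect_equal(slope, -8 * 0.0035 * sim$Q / (pi * 0.002^4), tolerance = 0.02)
  # weak compressibility: density stays within a small band
  expect_lt(sim$max_density_fluctuation, 5e-3)
})

test_that("zero inflow from rest stays at rest", {
  geom <- straight_tube(0.002, 0.01)
  grid <- axi_grid(geom, dr = 2.5e-4, dz = 5e-4)
  st <- flow_state(grid)
  ctl <- solver_control(tol = 1e-12, t_end = 0.01, ramp_time = 0)
  out <- advance_to_steady(st, geom, rheology_newtonian(), eos,
                           inflow_spec(0, geom), ctl)
  expect_lt(max(abs(velocity(out$state)$vz)), 1e-12)
  expect_equal(out$state$rho, st$rho, tolerance = 1e-12)
})

test_that("outflow is non-reflecting: pulse reflection below 5% of a hard wall's", {
  geom <- straight_tube(0.002, 0.04)
  grid <- axi_grid(geom, dr = 2.5e-4, dz = 2.5e-4)
  gauss <- exp(-((grid$z - 0.012) / 0.003)^2)
  drho <- matrix(gauss, grid$nr, grid$nz, byrow = TRUE)
  mk <- function(dir) flow_state(grid, rho = 1056 + drho,
                                 mz = dir * eos$c0 * drho)
  run <- function(st, t_end) {
    ctl <- solver_control(tol = 1e-30, t_end = t_end, ramp_time = 0,
                          max_steps = 100000L)
    advance_to_steady(st, geom, rheology_newtonian(), eos,
                      inflow_spec(0, geom), ctl)
  }
  # rightward pulse exits the outflow; any reflection returns to the left half
  r_out <- run(mk(+1), 0.0055)
  refl_out <- max(abs(r_out$state$rho[, grid$z < 0.02] - 1056))
  # leftward pulse hits the velocity-pinned inflow: a hard-wall control
  r_wall <- run(mk(-1), 0.0035)
  refl_wall <- max(abs(r_wall$state$rho[, grid$z > 0.02] - 1056))
  expect_gt(refl_wall, 0.5)            # the control does reflect
  expect_lt(refl_out, 0.05)            # incident amplitude is 1
  expect_lt(refl_out / refl_wall, 0.05)
})

test_that("reduced sound speed does not change the steady flow", {
  geom <- straight_tube(0.002, 0.015)
  run_c0 <- function(c0) {
    ctl <- solver_control(tol = 1e-7, t_end = 0.4, ramp_time = 0.02,
                          sponge_cells = 8L)
    simulate_steady(geom, 2e-6, rheology_newtonian(), dr = 2.5e-4, dz = 5e-4,
                    eos = eos_params(c0 = c0), control = ctl, init = "rest")
  }
  a <- cached("c0_10", run_c0(10))
  b <- cached("c0_20", run_c0(20))
  va <- velocity(a$state)$vz; vb <- velocity(b$state)$vz
  expect_lt(sqrt(sum((va - vb)^2) / sum(va^2)), 0.01)
})

test_that("steady solution is independent of the CFL number", {
  geom <- straight_tube(0.002, 0.015)
  run_cfl <- function(cfl) {
    ctl <- solver_control(cfl = cfl, tol = 1e-7, t_end = 0.4,
                          ramp_time = 0.02, sponge_cells = 8L)
    simulate_steady(geom, 2e-6, rheology_newtonian(), dr = 2.5e-4, dz = 5e-4,
                    control = ctl, init = "rest")
  }
  a <- cached("cfl_04", run_cfl(0.4))
  b <- cached("cfl_02", run_cfl(0.2))
  va <- velocity(a$state)$vz; vb <- velocity(b$state)$vz
  expect_lt(sqrt(sum((va - vb)^2) / sum(va^2)), 1e-3)
})

test_that("co-evolved damage field matches the frozen-flow scalar transport", {
  geom <- straight_tube(0.002, 0.02)
  co <- default_coeff
  Q <- 3e-6
  ctl <- solver_control(tol = 1e-7, t_end = 0.4, ramp_time = 0.02,
                        sponge_cells = 8L)
  grid <- axi_grid(geom, dr = 2.5e-4, dz = 5e-4)
  inflow <- inflow_spec(Q, geom)
  st0 <- make_poiseuille_field(geom, grid, Q)
  # co-evolved with the flow
  full <- advance_to_steady(st0, geom, rheology_newtonian(), eos, inflow,
                            ctl, coeff = co)
  # frozen-flow scalar transport from a cleared damage field
  stc <- full$state; stc$rhoDl[] <- 0
  dctl <- ctl; dctl$t_end <- 1.5
  scal <- solve_damage_field(stc, geom, rheology_newtonian(), eos, inflow,
                             co, dctl)
  eul_full <- eulerian_nih_profile(full$state, geom, co)
  eul_scal <- eulerian_nih_profile(scal$state, geom, co)
  j <- round(grid$nz * 0.8)
  expect_equal(eul_scal$value[j], eul_full$value[j], tolerance = 0.02)
})
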
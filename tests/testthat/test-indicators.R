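test_that("mass flow profile is flat on the analytic Poiseuille fixture", {
  geom <- straight_tube(0.002, 0.02)
  grid <- axi_grid(geom, dr = 1e-4, dz = 5e-4)
  Q <- 2e-6
  fix <- make_poiseuille_field(geom, grid, Q)
  mf <- mass_flow_profile(fix, geom)
  expect_equal(mf$value[1], 0)                     # zero at inlet by definition
  expect_lt(max(abs(mf$value)), 1e-12)             # flat everywhere
  mf2 <- mass_flow_profile(fix, geom, mdot_ref = 1056 * Q)
  expect_lt(max(abs(mf2$value)), 2e-3)             # midpoint-rule quadrature
})

test_that("Bernoulli drop is exact algebra with unit conversion", {
  expect_equal(bernoulli_drop(0, 1000), 0)
  expect_equal(bernoulli_drop(1, 1000), 500)
  expect_equal(pa_to_mmhg(133.322387415), 1)
  expect_error(bernoulli_drop(-1, 1000))
})

test_that("pressure drop profile recovers an imposed EOS density gradient", {
  geom <- straight_tube(0.002, 0.02)
  grid <- axi_grid(geom, dr = 2.5e-4, dz = 5e-4)
  eos <- eos_params()
  st <- flow_state(grid)
  expect_equal(max(abs(pressure_drop_profile(st, eos)$value)), 0)
  dpdz <- -800
  p <- eos$p0 + dpdz * (grid$z - grid$z[1])
  rho <- matrix(eos_density(p, eos), grid$nr, grid$nz, byrow = TRUE)
  st2 <- flow_state(grid, rho = rho)
  prof <- pressure_drop_profile(st2, eos)
  slope <- stats::coef(stats::lm(prof$value ~ prof$coordinate))[[2]]
  expect_equal(slope, dpdz, tolerance = 1e-9)
})

test_that("shear stress field is linear in r on a Poiseuille fixture and zero at rest", {
  geom <- straight_tube(0.002, 0.02)
  grid <- axi_grid(geom, dr = 1e-4, dz = 5e-4)
  Q <- 2e-6
  ssf0 <- shear_stress_field(flow_state(grid), geom, rheology_newtonian())
  expect_equal(max(ssf0$tau), 0)
  fix <- make_poiseuille_field(geom, grid, Q)
  ssf <- shear_stress_field(fix, geom, rheology_newtonian(),
                            cuts = c(0.01))
  ana <- 4 * 0.0035 * Q * grid$r / (pi * 0.002^4)
  expect_equal(ssf$profiles[[1]]$value, ana, tolerance = 1e-6)
})

test_that("WSS sampling two cells below the wall approaches the analytic value under refinement", {
  geom <- straight_tube(0.002, 0.02)
  Q <- 2e-6
  wss_wall <- 4 * 0.0035 * Q / (pi * 0.002^3)
  got <- sapply(c(2e-4, 1e-4, 5e-5), function(h) {
    grid <- axi_grid(geom, dr = h, dz = 5e-4)
    fix <- make_poiseuille_field(geom, grid, Q)
    stats::median(wss_profile(fix, geom, rheology_newtonian())$value)
  })
  # sampled radius r = R - 2.5 dr, so tau = wss * (1 - 2.5 dr / R)
  expect_equal(got, wss_wall * (1 - 2.5 * c(2e-4, 1e-4, 5e-5) / 0.002),
               tolerance = 1e-3)
  err <- abs(got - wss_wall) / wss_wall
  expect_true(all(diff(err) < 0))                  # converges to the wall value
  # a rest state yields zero WSS
  grid <- axi_grid(geom, dr = 1e-4, dz = 5e-4)
  expect_equal(max(abs(wss_profile(flow_state(grid), geom,
                                   rheology_newtonian())$value)), 0)
})

test_that("profile extraction: centerline and cuts, with grid-line identity", {
  geom <- straight_tube(0.002, 0.02)
  grid <- axi_grid(geom, dr = 1e-4, dz = 5e-4)
  Q <- 2e-6
  fix <- make_poiseuille_field(geom, grid, Q)
  eos <- eos_params()
  pr <- extract_profiles(fix, geom, eos, rheology_newtonian(),
                         cuts = c(0.005, 0.015))
  vmax <- poiseuille_vmax(Q, 0.002)
  # centerline row sits at r = dr/2
  expect_equal(pr$centerline$vz$value,
               rep(vmax * (1 - (grid$r[1] / 0.002)^2), grid$nz),
               tolerance = 1e-12)
  # radial cut reproduces the parabola and equals the stored grid column
  j <- which.min(abs(grid$z - 0.005))
  expect_identical(pr$cuts[[1]]$vz$value, velocity(fix)$vz[, j])
  expect_error(extract_profiles(fix, geom, eos, rheology_newtonian(),
                                cuts = 1), "outside")
})

test_that("profile_series validates and writes CSV round trips", {
  expect_error(profile_series(c(1, 1, 2), 1:3), "monotone")
  p <- profile_series(1:5 / 100, (1:5)^2, quantity = "vz", units = "m/s",
                      meta = list(cut = "centerline"))
  f <- tempfile(fileext = ".csv")
  write_profile_csv(p, f)
  txt <- readLines(f)
  expect_true(any(grepl("quantity: vz", txt)))
  back <- utils::read.csv(f, comment.char = "#")
  expect_equal(back$value, (1:5)^2)
  unlink(f)
})
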
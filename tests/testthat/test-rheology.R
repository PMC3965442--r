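test_that("viscosity laws honor their limits and the Casson cutoff", {
  cy <- rheology_preset("carreau_yasuda_abraham")
  expect_equal(viscosity(cy, 0), cy$mu0)                     # zero-shear limit
  expect_lt(abs(viscosity(cy, 1e7) / cy$mu_inf - 1), 0.01)   # high-shear limit
  # frozen high-precision direct evaluation at 100 1/s
  g <- 100
  expect_equal(viscosity(cy, g),
               0.0035 + 0.1565 * (1 + (8.2 * 100)^0.64)^((0.2128 - 1) / 0.64),
               tolerance = 1e-14)

  cas <- rheology_preset("casson_perktold")
  expect_equal(viscosity(cas, cas$gamma_cutoff / 10),
               viscosity(cas, cas$gamma_cutoff))             # cutoff clamp
  cas0 <- rheology_casson(k_tau = 0, k_mu = 0.004)
  expect_equal(viscosity(cas0, c(0.1, 10, 1e4)), rep(0.004, 3))

  newt <- rheology_newtonian(0.0035)
  expect_equal(viscosity(newt, c(0, 5, 1e5)), rep(0.0035, 3))
  expect_error(viscosity(cy, -1), "non-negative")
})

test_that("CY viscosity is strictly decreasing and bounded; Casson non-increasing and >= k_mu", {
  cy <- rheology_preset("carreau_yasuda_abraham")
  g <- 10^seq(-3, 5, length.out = 200)
  mu <- viscosity(cy, g)
  expect_true(all(diff(mu) < 0))
  expect_true(all(mu <= cy$mu0 & mu >= cy$mu_inf))

  cas <- rheology_preset("casson_perktold")
  muc <- viscosity(cas, g)
  expect_true(all(diff(muc) <= 0))
  expect_true(all(is.finite(muc)))
  expect_true(all(muc >= cas$k_mu))
})

test_that("low-shear model ordering is Casson >= CY >= Newtonian", {
  cas <- rheology_preset("casson_perktold")
  cy <- rheology_preset("carreau_yasuda_abraham")
  newt <- rheology_preset("newtonian")
  g <- cas$gamma_cutoff
  expect_gte(viscosity(cas, g), viscosity(cy, g))
  expect_gte(viscosity(cy, g), viscosity(newt, g))
})

test_that("strain-rate tensor vanishes for uniform flow and captures simple shear", {
  geom <- straight_tube(0.002, 0.01)
  grid <- axi_grid(geom, dr = 2e-4, dz = 5e-4)
  uni_vz <- matrix(0.3, grid$nr, grid$nz)
  zero <- matrix(0, grid$nr, grid$nz)
  S <- shear_rate_tensor(zero, uni_vz, grid)
  for (comp in S) expect_equal(max(abs(comp)), 0)
  expect_equal(max(effective_shear_rate(S)), 0)

  # v_z = k r: S_rz = k/2, effective shear = |dv_z/dr| = k
  k <- 150
  lin_vz <- matrix(k * grid$r, grid$nr, grid$nz)
  S2 <- shear_rate_tensor(zero, lin_vz, grid)
  inner <- 2:(grid$nr - 1)
  expect_equal(S2$S_rz[inner, 5], rep(k / 2, length(inner)), tolerance = 1e-10)
  expect_equal(effective_shear_rate(S2)[inner, 5], rep(k, length(inner)),
               tolerance = 1e-10)
})

test_that("effective shear rate equals the brute-force tensor invariant", {
  set.seed(7)
  for (i in 1:20) {
    s <- list(S_rr = matrix(rnorm(1), 1, 1), S_rz = matrix(rnorm(1), 1, 1),
              S_zz = matrix(rnorm(1), 1, 1), S_tt = matrix(rnorm(1), 1, 1))
    # build the full 3x3 axisymmetric tensor and contract explicitly
    M <- matrix(c(s$S_rr[1], 0, s$S_rz[1],
                  0, s$S_tt[1], 0,
                  s$S_rz[1], 0, s$S_zz[1]), 3, 3)
    expect_equal(effective_shear_rate(s)[1, 1], sqrt(2 * sum(M * M)),
                 tolerance = 1e-12)
  }
})

test_that("Poiseuille strain rate matches the analytic derivative", {
  geom <- straight_tube(0.002, 0.01)
  grid <- axi_grid(geom, dr = 1e-4, dz = 5e-4)
  Q <- 3e-6
  fix <- make_poiseuille_field(geom, grid, Q)
  v <- velocity(fix)
  S <- shear_rate_tensor(v$vr, v$vz, grid, build_mask(geom, grid))
  gam <- effective_shear_rate(S)
  ana <- 4 * Q * grid$r / (pi * 0.002^4)
  # central differences are exact on the parabola in the interior
  expect_equal(gam[2:(grid$nr - 1), 10], ana[2:(grid$nr - 1)],
               tolerance = 1e-9)
  # 2nd-order one-sided closure keeps the wall row accurate too
  expect_equal(gam[grid$nr, 10], ana[grid$nr], tolerance = 1e-9)
})

test_that("viscosity_field maps shear fields pointwise and preserves monotonicity", {
  geom <- straight_tube(0.002, 0.01)
  grid <- axi_grid(geom, dr = 1e-4, dz = 5e-4)
  fix <- make_poiseuille_field(geom, grid, 3e-6)
  v <- velocity(fix)
  S <- shear_rate_tensor(v$vr, v$vz, grid, build_mask(geom, grid))
  gam <- effective_shear_rate(S)
  cy <- rheology_preset("carreau_yasuda_abraham")
  mu <- viscosity_field(cy, S)
  expect_equal(mu, viscosity(cy, gam))                     # elementwise
  expect_true(all(diff(mu[, 10]) < 0))  # high viscosity at axis, low at wall
  newt <- rheology_newtonian(0.004)
  expect_equal(max(viscosity_field(newt, S)), 0.004)
  expect_equal(min(viscosity_field(newt, S)), 0.004)
})
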
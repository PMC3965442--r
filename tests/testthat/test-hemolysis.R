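co <- default_coeff

test_that("constant-exposure damage law: zero stress, sublinearity, direct value", {
  expect_equal(damage_constant_exposure(0, 10, co), 0)
  D1 <- damage_constant_exposure(50, 1, co)
  expect_equal(damage_constant_exposure(50, 2, co) / D1, 2^co$a,
               tolerance = 1e-12)
  expect_lt(2^co$a, 2)                              # sublinear in time
  # frozen arbitrary-precision evaluation of C tau^b t^a at tau=100, t=1
  expect_equal(damage_constant_exposure(100, 1, co),
               3.62e-7 * exp(2.416 * log(100)), tolerance = 1e-14)
  expect_error(damage_constant_exposure(-1, 1, co), "non-negative")
})

test_that("linear-damage rate integrates back to the power law", {
  expect_equal(linear_damage_rate(0, co), 0)
  tau <- 37.5; t <- 0.83
  Dl <- linear_damage_rate(tau, co) * t
  expect_equal(Dl^co$a, damage_constant_exposure(tau, t, co),
               tolerance = 1e-12)
  # piecewise-constant history vs brute-force fine-step integration
  taus <- c(10, 80, 25); dts <- c(0.2, 0.05, 0.4)
  Dl_pw <- sum(linear_damage_rate(taus, co) * dts)
  tfine <- seq(0, sum(dts), by = 1e-5)
  tau_of <- function(t) taus[findInterval(t, cumsum(c(0, dts)),
                                          rightmost.closed = TRUE)]
  Dl_fine <- sum(linear_damage_rate(tau_of(tfine[-1] - 5e-6), co)) * 1e-5
  expect_equal(Dl_pw, Dl_fine, tolerance = 1e-10 + 1e-5)
})

test_that("NIH conversion is linear in Hb and in the plasma fraction", {
  D <- 3e-6
  base <- nih_from_damage(D, co)
  co2 <- hemolysis_coefficients(Hb = 2 * co$Hb)
  expect_equal(nih_from_damage(D, co2), 2 * base)
  co3 <- hemolysis_coefficients(Hct = 0.1)
  expect_equal(nih_from_damage(D, co3), base * (1 - 0.1) / (1 - co$Hct))
})

test_that("analytic bound equals the Lagrangian-Poiseuille oracle on straight, stepped and cone tubes", {
  Q <- flow_rate_for_re(500)
  mu <- 0.0035
  geoms <- list(straight = straight_tube(0.002, 0.04),
                stepped = stepped_tube(0.002, 0.006, 0.04, 0.04),
                cone = cone_tube(0.006, 0.002, 0.0226852851438521),
                fda = fda_nozzle())
  for (nm in names(geoms)) {
    cf <- analytic_lower_bound(geoms[[nm]], mu, Q, co)
    orc <- lagrangian_poiseuille_oracle(geoms[[nm]], mu, Q, co)
    expect_equal(cf$D, orc$D, tolerance = 1e-6, label = paste("D on", nm))
  }
  expect_equal(analytic_lower_bound(geoms$fda, mu, 0, co)$NIH, 0)
})

test_that("stepped-tube bound decomposes into the two-term closed form", {
  Q <- 4e-6; mu <- 0.0035
  q <- 2 - 3 * co$b / co$a
  geom <- stepped_tube(0.002, 0.004, 0.03, 0.05)
  I <- 0.03 * 0.002^q + 0.05 * 0.004^q
  expect_equal(analytic_lower_bound(geom, mu, Q, co)$I_m, I, tolerance = 1e-12)
})

test_that("pathline averaging un-linearizes before the weighted mean", {
  mk <- function(Dl, w) list(t = c(0, 1), tau = c(1, 1), Dl = Dl, weight = w)
  same <- list(mk(2e-5, 0.25), mk(2e-5, 0.75))
  avg <- average_nih_pathlines(same, co)
  expect_equal(avg$D, (2e-5)^co$a)
  two <- list(mk(1e-5, 0.3), mk(8e-5, 0.7))
  avg2 <- average_nih_pathlines(two, co)
  expect_equal(avg2$D, 0.3 * (1e-5)^co$a + 0.7 * (8e-5)^co$a)
  expect_equal(avg2$NIH, nih_from_damage(avg2$D, co))
  expect_error(average_nih_pathlines(list(), co), "empty")
})

test_that("linear averaging overestimates: Jensen ratio >= 1, equality when homogeneous", {
  expect_equal(linear_averaging_overestimate(rep(3e-5, 5), a = co), 1)
  set.seed(11)
  for (i in 1:25) {
    Dl <- rexp(8, rate = 1e5)
    w <- runif(8)
    r <- linear_averaging_overestimate(Dl, w, a = co$a)
    expect_gte(r, 1)
  }
  # Poiseuille damage distribution: ratio matches direct quadrature
  Q <- flow_rate_for_re(500); mu <- 0.0035
  geom <- straight_tube(0.002, 0.04)
  q <- 2 - 3 * co$b / co$a
  Iz <- geometry_integral(geom, q)
  Dl_s <- function(s) co$C^(1 / co$a) * (4 * mu * Q / pi)^(co$b / co$a) *
    s^(co$b / co$a) * pi / (2 * Q * (1 - s^2)) * Iz
  num <- stats::integrate(function(s) Dl_s(s) * 4 * s * (1 - s^2), 0, 1,
                          rel.tol = 1e-10)$value^co$a
  den <- stats::integrate(function(s) Dl_s(s)^co$a * 4 * s * (1 - s^2), 0, 1,
                          rel.tol = 1e-10)$value
  ratio_exact <- num / den
  s <- seq(0.005, 0.995, length.out = 4000)
  w <- 4 * s * (1 - s^2)
  ratio_disc <- linear_averaging_overestimate(Dl_s(s), w, co$a)
  expect_gt(ratio_exact, 1.2)                      # a sizable overestimation
  expect_equal(ratio_disc, ratio_exact, tolerance = 0.02)
})

test_that("time-explicit (Arora) route is exact for constant stress and origin-sensitive", {
  tau <- 60; Tend <- 0.7
  tgrid <- seq(0, Tend, length.out = 4001)
  pl <- list(list(t = tgrid, tau = rep(tau, length(tgrid)),
                  Dl = NA, weight = 1))
  res0 <- arora_nih(pl, co, time_origin = 0)
  expect_equal(res0$D, damage_constant_exposure(tau, Tend, co),
               tolerance = 1e-4)
  res1 <- arora_nih(pl, co, time_origin = 0.5)
  res2 <- arora_nih(pl, co, time_origin = 2)
  expect_lt(res1$D, res0$D)                        # earlier origin => smaller
  expect_lt(res2$D, res1$D)
  expect_error(arora_nih(pl, co, time_origin = -1), "non-negative")
})
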
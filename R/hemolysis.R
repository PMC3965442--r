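#' Power-law hemolysis coefficients and blood composition
#'
#' The Giersiepen-family damage law models the released-hemoglobin fraction
#' under constant shear stress \eqn{\tau} (Pa) and exposure time \eqn{t} (s)
#' as \deqn{D = C\, \tau^{b}\, t^{a},} with \eqn{a < 1} (sublinear growth in
#' time). The defaults are the Giersiepen coefficients with \eqn{D} expressed
#' as a fraction: \eqn{C = 3.62\times 10^{-7}}, \eqn{a = 0.785},
#' \eqn{b = 2.416}. `Hct` (hematocrit volume fraction) and `Hb` (blood
#' hemoglobin content, g/L) convert damage fractions into the normalized
#' index of hemolysis via [nih_from_damage()].
#'
#' @param C damage-scale coefficient (dimensionless, fraction convention)
#' @param a time exponent, in (0, 1)
#' @param b stress exponent, > 0
#' @param Hct hematocrit volume fraction, in (0, 1)
#' @param Hb hemoglobin content of blood (g/L)
#' @return object of class `hemolysis_coefficients`
#' @export
hemolysis_coefficients <- function(C = 3.62e-7, a = 0.785, b = 2.416,
                                   Hct = 0.45, Hb = 150) {
  stopifnot(C > 0, a > 0, a < 1, b > 0, Hct > 0, Hct < 1, Hb > 0)
  structure(list(C = C, a = a, b = b, Hct = Hct, Hb = Hb),
            class = "hemolysis_coefficients")
}

#' @export
print.hemolysis_coefficients <- function(x, ...) {
  cat(sprintf("<hemolysis_coefficients> C = %g, a = %g, b = %g, Hct = %g, Hb = %g g/L\n",
              x$C, x$a, x$b, x$Hct, x$Hb))
  invisible(x)
}

#' Blood damage under constant shear exposure
#'
#' \eqn{D = C \tau^b t^a}: the empirical power law calibrated under constant
#' shear stress. Because \eqn{a < 1}, doubling the exposure time multiplies
#' the damage by \eqn{2^a < 2}.
#'
#' @param tau shear stress (Pa), non-negative
#' @param t exposure time (s), non-negative
#' @param coeff a [hemolysis_coefficients()]
#' @return damage fraction D (dimensionless)
#' @export
damage_constant_exposure <- function(tau, t, coeff) {
  stopifnot(inherits(coeff, "hemolysis_coefficients"))
  if (any(tau < 0) || any(t < 0)) stop("tau and t must be non-negative")
  coeff$C * tau^coeff$b * t^coeff$a
}

#' Linear-damage growth rate
#'
#' Linearizing the power law in time, \eqn{D_l = D^{1/a}}, yields a rate
#' independent of the accumulated damage,
#' \deqn{\frac{dD_l}{dt} = C^{1/a}\, \tau^{b/a},}
#' the form integrated along pathlines and used as the source of the Eulerian
#' linear-damage transport field. For constant \eqn{\tau}, integrating and
#' un-linearizing (\eqn{D = D_l^{\,a}}) recovers the constant-exposure law
#' exactly.
#'
#' @inheritParams damage_constant_exposure
#' @return rate \eqn{dD_l/dt} (1/s-scaled, dimensionless damage per second)
#' @export
linear_damage_rate <- function(tau, coeff) {
  stopifnot(inherits(coeff, "hemolysis_coefficients"))
  if (any(tau < 0)) stop("tau must be non-negative")
  coeff$C^(1 / coeff$a) * tau^(coeff$b / coeff$a)
}

#' Normalized index of hemolysis from a damage fraction
#'
#' \deqn{{\rm NIH}\ ({\rm g}/100\,{\rm L}) = 100\,(1 - {\rm Hct})\,
#' {\rm Hb}\, D,} linear in both the hemoglobin content and the plasma
#' fraction \eqn{(1-{\rm Hct})}.
#'
#' @param D damage fraction(s)
#' @param coeff a [hemolysis_coefficients()]
#' @return NIH in g/100 L
#' @export
nih_from_damage <- function(D, coeff) {
  stopifnot(inherits(coeff, "hemolysis_coefficients"))
  100 * (1 - coeff$Hct) * coeff$Hb * D
}

#' Flow-weighted NIH from pathlines
#'
#' For each pathline the accumulated linear damage \eqn{D_l} is
#' un-linearized to actual damage \eqn{D = D_l^{\,a}} *before* averaging —
#' the order of operations is essential because \eqn{D_l} is only an
#' auxiliary variable; averaging it directly overestimates damage (see
#' [linear_averaging_overestimate()]). The flow-weighted mean damage is then
#' converted to NIH.
#'
#' @param pathlines a `pathline_set` from [trace_pathlines()], or a list of
#'   pathline objects each with elements `Dl` (final linear damage) and
#'   `weight` (flow weight)
#' @param coeff a [hemolysis_coefficients()]
#' @return list with `D` (flow-weighted mean damage fraction), `NIH`
#'   (g/100 L), and per-pathline vectors `Dl`, `D_i`, `weights`
#' @export
average_nih_pathlines <- function(pathlines, coeff) {
  stopifnot(inherits(coeff, "hemolysis_coefficients"))
  pl <- if (inherits(pathlines, "pathline_set")) pathlines$pathlines else pathlines
  if (length(pl) == 0) stop("empty pathline set")
  Dl <- vapply(pl, function(p) p$Dl, numeric(1))
  w <- vapply(pl, function(p) p$weight, numeric(1))
  w <- w / sum(w)
  D_i <- Dl^coeff$a
  D <- sum(w * D_i)
  list(D = D, NIH = nih_from_damage(D, coeff),
       Dl = Dl, D_i = D_i, weights = w)
}

#' Eulerian NIH profile along the axis
#'
#' From a steady state carrying the converged conservative linear-damage
#' field \eqn{\rho D_l}: at each axial station the pointwise damage
#' \eqn{D = (\rho D_l/\rho)^{a}} is flow-weighted over the radial cut
#' (weights \eqn{\rho v_z\, 2\pi r\, \Delta r}, i.e. the local mass flux)
#' and converted to NIH. In a conduit without recirculation the profile is
#' non-decreasing along the flow direction.
#'
#' @param state a steady [flow_state()] with evolved `rhoDl`
#' @param geom a [nozzle_geometry()]
#' @param coeff a [hemolysis_coefficients()]
#' @param mask optional precomputed fluid mask
#' @return a [profile_series()] of NIH versus z
#' @export
eulerian_nih_profile <- function(state, geom, coeff, mask = NULL) {
  stopifnot(inherits(state, "flow_state"),
            inherits(coeff, "hemolysis_coefficients"))
  grid <- state$grid
  if (is.null(mask)) mask <- build_mask(geom, grid)
  v <- velocity(state)
  Dl <- state$rhoDl / state$rho
  D <- Dl^coeff$a
  nih <- numeric(grid$nz)
  for (j in seq_len(grid$nz)) {
    f <- mask[, j]
    w <- state$rho[f, j] * v$vz[f, j] * grid$r[f]
    sw <- sum(w)
    nih[j] <- if (abs(sw) > 0) sum(w * D[f, j]) / sw else 0
  }
  profile_series(grid$z, nih_from_damage(nih, coeff),
                 quantity = "NIH", units = "g/100L",
                 meta = list(method = "eulerian"))
}

#' Closed-form axisymmetric hemolysis lower bound
#'
#' Assumes a local Poiseuille profile with the prescribed flow rate at every
#' axial station of a Newtonian flow. Streamlines then sit at fixed relative
#' radius \eqn{s = r/R(z)}; the wall-scaled shear stress
#' \eqn{\tau = 4\mu Q s/(\pi R^3)} and the transit element
#' \eqn{dt = \pi R^2 (1 - s^2)^{-1} dz/(2Q)} give, per streamline,
#' \deqn{D_l(s) = C^{1/a} \left(\frac{4\mu Q}{\pi}\right)^{b/a}
#'   \frac{\pi\, s^{b/a}}{2 Q (1-s^2)}\; I, \qquad
#'   I = \int R(z)^{\,2 - 3b/a}\, dz,}
#' and the flow-weighted average of \eqn{D = D_l^{\,a}} reduces to a Beta
#' function:
#' \deqn{\langle D\rangle = 2 C \left(\frac{4\mu Q}{\pi}\right)^{b}
#'   \left(\frac{\pi}{2Q}\right)^{a} I^{\,a}\,
#'   B\!\left(\tfrac{b}{2}+1,\; 2-a\right).}
#' Because the Poiseuille approximation ignores the extra shear of jets and
#' recirculation, the result is a lower bound on the damage of the real flow
#' through the same geometry.
#'
#' @param geom a [nozzle_geometry()]
#' @param mu Newtonian viscosity (Pa s)
#' @param Q volumetric flow rate (m^3/s), non-negative
#' @param coeff a [hemolysis_coefficients()]
#' @return list with `D` (mean damage fraction), `NIH` (g/100 L), the
#'   geometry integral `I_m` (SI units, m^(1+q)), its millimetre-convention
#'   value `I_mm`, the radius exponent `q`, and the millimetre-convention
#'   prefactor `K_mm` such that `D = K_mm * mu^b * Q^(b-a) * I_mm^a`.
#' @export
analytic_lower_bound <- function(geom, mu, Q, coeff) {
  stopifnot(inherits(geom, "nozzle_geometry"),
            inherits(coeff, "hemolysis_coefficients"), mu > 0, Q >= 0)
  a <- coeff$a; b <- coeff$b
  q <- 2 - 3 * b / a
  I_m <- geometry_integral(geom, q, "m")
  I_mm <- geometry_integral(geom, q, "mm")
  if (Q == 0)
    return(list(D = 0, NIH = 0, I_m = I_m, I_mm = I_mm, q = q, K_mm = NA_real_))
  D <- 2 * coeff$C * (4 * mu * Q / pi)^b * (pi / (2 * Q))^a * I_m^a *
    beta(b / 2 + 1, 2 - a)
  K_mm <- 2 * coeff$C * (4 / pi)^b * (pi / 2)^a * beta(b / 2 + 1, 2 - a) *
    (1e-3)^(a * (1 + q))
  list(D = D, NIH = nih_from_damage(D, coeff),
       I_m = I_m, I_mm = I_mm, q = q, K_mm = K_mm)
}

#' Time-explicit (Arora-type) damage route along pathlines
#'
#' Instead of the damage-linearizing route, the power law can be
#' differentiated at fixed time origin, giving the time-explicit rate
#' \deqn{\frac{dD}{dt} = C\, a\, t^{a-1}\, \tau(t)^{b},}
#' which reproduces the constant-exposure law exactly when \eqn{\tau} is
#' constant and the origin coincides with the start of the exposure. The
#' result depends on the choice of time origin: shifting the origin earlier
#' (larger `time_origin` offset) strictly decreases the computed damage,
#' since \eqn{t^{a-1}} decays for \eqn{a < 1}.
#'
#' @param pathlines a `pathline_set` from [trace_pathlines()] (with sampled
#'   `t` and `tau` histories)
#' @param coeff a [hemolysis_coefficients()]
#' @param time_origin non-negative offset (s) between the assumed damage
#'   time origin and each pathline's seeding time; 0 starts the clock when
#'   the particle enters the domain
#' @return list with `D`, `NIH`, and per-pathline damages `D_i`
#' @export
arora_nih <- function(pathlines, coeff, time_origin = 0) {
  stopifnot(inherits(coeff, "hemolysis_coefficients"))
  if (time_origin < 0) stop("time_origin offset must be non-negative")
  pl <- if (inherits(pathlines, "pathline_set")) pathlines$pathlines else pathlines
  if (length(pl) == 0) stop("empty pathline set")
  a <- coeff$a; b <- coeff$b; C <- coeff$C
  # integrate C a t^(a-1) tau(t)^b exactly in t on each sampling interval
  # (tau taken as the interval mean), which is robust at the integrable
  # t^(a-1) singularity of the origin
  D_i <- vapply(pl, function(p) {
    t <- p$t + time_origin
    n <- length(t)
    taub <- (p$tau[-1]^b + p$tau[-n]^b) / 2
    sum(C * taub * (t[-1]^a - t[-n]^a))
  }, numeric(1))
  w <- vapply(pl, function(p) p$weight, numeric(1))
  w <- w / sum(w)
  D <- sum(w * D_i)
  list(D = D, NIH = nih_from_damage(D, coeff), D_i = D_i, weights = w)
}

#' Overestimation from averaging linear damage
#'
#' Quantifies the error of averaging the auxiliary linear damage before
#' un-linearizing: \deqn{{\rm ratio} = \frac{(\sum_i w_i D_{l,i})^{a}}
#' {\sum_i w_i D_{l,i}^{\,a}} \ \ge\ 1,} with equality iff the damage is
#' homogeneous across pathlines (Jensen's inequality, \eqn{x^a} concave for
#' \eqn{a<1}).
#'
#' @param Dl vector of per-pathline linear damages
#' @param weights flow weights (normalized internally); default equal
#' @param a time exponent of the damage law (or a
#'   [hemolysis_coefficients()] object)
#' @return the overestimation ratio (>= 1 for a < 1)
#' @export
linear_averaging_overestimate <- function(Dl, weights = NULL, a = 0.785) {
  if (inherits(a, "hemolysis_coefficients")) a <- a$a
  if (length(Dl) < 1) stop("need at least one pathline damage")
  if (is.null(weights)) weights <- rep(1, length(Dl))
  w <- weights / sum(weights)
  (sum(w * Dl))^a / sum(w * Dl^a)
}
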
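#' Blood rheology models
#'
#' Constructors for the three viscosity laws supported by the solver. All
#' return an object of class `rheology` usable with [viscosity()],
#' [viscosity_field()] and the flow solver.
#'
#' * **Newtonian**: constant dynamic viscosity \eqn{\mu}.
#' * **Carreau-Yasuda** (shear-thinning):
#'   \eqn{\mu(\dot\gamma) = \mu_\infty + (\mu_0-\mu_\infty)
#'   [1+(\lambda\dot\gamma)^a]^{(n-1)/a}}, interpolating smoothly between the
#'   zero-shear viscosity \eqn{\mu_0} and the infinite-shear viscosity
#'   \eqn{\mu_\infty}.
#' * **Casson** (yield-stress-like):
#'   \eqn{\mu(\dot\gamma) = (\sqrt{k_\tau/\dot\gamma} + \sqrt{k_\mu})^2},
#'   divergent as \eqn{\dot\gamma \to 0} and therefore regularized with a
#'   low-shear cutoff: below `gamma_cutoff` the viscosity is held at its
#'   cutoff value.
#'
#' @param mu Newtonian dynamic viscosity (Pa s)
#' @param mu0,mu_inf zero- and infinite-shear viscosities (Pa s), `mu0 > mu_inf`
#' @param lambda relaxation time (s)
#' @param a Yasuda transition exponent (dimensionless, > 0)
#' @param n power-law index (dimensionless, < 1 for shear thinning)
#' @param k_tau yield-stress-like coefficient (Pa)
#' @param k_mu plastic-viscosity-like coefficient (Pa s)
#' @param gamma_cutoff low-shear cutoff (1/s)
#' @return an object of class `rheology`
#' @examples
#' cy <- rheology_preset("carreau_yasuda_abraham")
#' viscosity(cy, c(0, 1, 100, 1e6))
#' @name rheology
NULL

#' @rdname rheology
#' @export
rheology_newtonian <- function(mu = 0.0035) {
  stopifnot(mu > 0)
  structure(list(model = "newtonian", mu = mu),
            class = c("rheology_newtonian", "rheology"))
}

#' @rdname rheology
#' @export
rheology_carreau_yasuda <- function(mu0 = 0.16, mu_inf = 0.0035,
                                    lambda = 8.2, a = 0.64, n = 0.2128) {
  stopifnot(mu0 > mu_inf, mu_inf > 0, lambda > 0, a > 0, n < 1)
  structure(list(model = "carreau_yasuda", mu0 = mu0, mu_inf = mu_inf,
                 lambda = lambda, a = a, n = n),
            class = c("rheology_carreau_yasuda", "rheology"))
}

#' @rdname rheology
#' @export
rheology_casson <- function(k_tau = 0.1937^2, k_mu = 0.055^2,
                            gamma_cutoff = 1) {
  stopifnot(k_tau >= 0, k_mu > 0, gamma_cutoff > 0)
  structure(list(model = "casson", k_tau = k_tau, k_mu = k_mu,
                 gamma_cutoff = gamma_cutoff),
            class = c("rheology_casson", "rheology"))
}

#' Named rheology presets
#'
#' `"newtonian"` uses the infinite-shear Carreau-Yasuda viscosity (3.5 mPa s)
#' as its constant value, so the Newtonian model is the high-shear limit of
#' the non-Newtonian ones. `"carreau_yasuda_abraham"` carries the
#' Abraham-Behr-Heinkenschloss blood calibration; `"casson_perktold"` the
#' Perktold hematocrit-45% Casson constants with a 1/s cutoff.
#'
#' @param name preset name
#' @return an object of class `rheology`
#' @export
rheology_preset <- function(name = c("newtonian", "carreau_yasuda_abraham",
                                     "casson_perktold")) {
  name <- match.arg(name)
  switch(name,
    newtonian = rheology_newtonian(0.0035),
    carreau_yasuda_abraham = rheology_carreau_yasuda(
      mu0 = 0.16, mu_inf = 0.0035, lambda = 8.2, a = 0.64, n = 0.2128),
    casson_perktold = rheology_casson(
      k_tau = 0.1937^2, k_mu = 0.055^2, gamma_cutoff = 1))
}

#' @export
print.rheology <- function(x, ...) {
  pars <- x[setdiff(names(x), "model")]
  cat(sprintf("<rheology: %s> %s\n", x$model,
              paste(names(pars), unlist(pars), sep = " = ", collapse = ", ")))
  invisible(x)
}

#' Dynamic viscosity at given shear rates
#'
#' @param rheo an object of class `rheology`
#' @param gamma_eff effective shear rate(s), 1/s, non-negative
#' @return viscosity (Pa s), same shape as `gamma_eff`
#' @export
viscosity <- function(rheo, gamma_eff) UseMethod("viscosity")

#' @export
viscosity.rheology_newtonian <- function(rheo, gamma_eff) {
  check_gamma(gamma_eff)
  out <- gamma_eff
  out[] <- rheo$mu
  out
}

#' @export
viscosity.rheology_carreau_yasuda <- function(rheo, gamma_eff) {
  check_gamma(gamma_eff)
  rheo$mu_inf + (rheo$mu0 - rheo$mu_inf) *
    (1 + (rheo$lambda * gamma_eff)^rheo$a)^((rheo$n - 1) / rheo$a)
}

#' @export
viscosity.rheology_casson <- function(rheo, gamma_eff) {
  check_gamma(gamma_eff)
  g <- pmax(gamma_eff, rheo$gamma_cutoff)
  (sqrt(rheo$k_tau / g) + sqrt(rheo$k_mu))^2
}

check_gamma <- function(gamma_eff) {
  if (any(gamma_eff < 0, na.rm = TRUE))
    stop("effective shear rate must be non-negative")
  invisible(TRUE)
}

#' Strain-rate tensor on an axisymmetric grid
#'
#' Computes the components of the symmetric strain-rate tensor
#' \eqn{S = (\nabla v + \nabla v^T)/2} in cylindrical axisymmetric
#' coordinates on cell centers:
#' \eqn{S_{rr} = \partial_r v_r}, \eqn{S_{zz} = \partial_z v_z},
#' \eqn{S_{\theta\theta} = v_r / r},
#' \eqn{S_{rz} = (\partial_r v_z + \partial_z v_r)/2}.
#' Derivatives use centered second-order differences in the interior and
#' one-sided differences where a stencil would cross a wall or the domain
#' edge; across the symmetry axis the parity of each component
#' (\eqn{v_r} odd, \eqn{v_z} even) is used. With cell-centered coordinates
#' the hoop term \eqn{v_r/r} is evaluated directly (no center lies at
#' \eqn{r = 0}; on the axis itself \eqn{v_r/r \to \partial_r v_r} and the
#' two agree to discretization order).
#'
#' @param vr,vz velocity component matrices (`nr x nz`), m/s
#' @param grid an [axi_grid()]
#' @param mask logical fluid mask from [build_mask()]; components are set to
#'   zero (and derivatives one-sided) on/at solid cells. `NULL` treats all
#'   cells as fluid.
#' @return list with matrices `S_rr`, `S_rz`, `S_zz`, `S_tt`
#' @export
shear_rate_tensor <- function(vr, vz, grid, mask = NULL) {
  stopifnot(inherits(grid, "axi_grid"))
  nr <- grid$nr; nz <- grid$nz
  stopifnot(all(dim(vr) == c(nr, nz)), all(dim(vz) == c(nr, nz)))
  if (is.null(mask)) mask <- matrix(TRUE, nr, nz)

  dvr_dr <- masked_deriv(vr, grid$dr, mask, dim = 1L, axis_parity = -1)
  dvz_dr <- masked_deriv(vz, grid$dr, mask, dim = 1L, axis_parity = +1)
  dvr_dz <- masked_deriv(vr, grid$dz, mask, dim = 2L, axis_parity = NA)
  dvz_dz <- masked_deriv(vz, grid$dz, mask, dim = 2L, axis_parity = NA)

  S_tt <- sweep(vr, 1L, grid$r, `/`)
  out <- list(S_rr = dvr_dr, S_rz = 0.5 * (dvz_dr + dvr_dz),
              S_zz = dvz_dz, S_tt = S_tt)
  lapply(out, function(m) { m[!mask] <- 0; m })
}

# centered difference along `dim`, one-sided where the neighbor is solid or
# outside; radial derivatives use axis ghost parity at i = 1.
masked_deriv <- function(f, h, mask, dim, axis_parity = NA) {
  nr <- nrow(f); nz <- ncol(f)
  shift <- function(m, by) {
    out <- m * NA
    if (dim == 1L) {
      if (by > 0) out[seq_len(nr - by), ] <- m[(1 + by):nr, ]
      else out[(1 - by):nr, ] <- m[seq_len(nr + by), ]
    } else {
      if (by > 0) out[, seq_len(nz - by)] <- m[, (1 + by):nz]
      else out[, (1 - by):nz] <- m[, seq_len(nz + by)]
    }
    out
  }
  fp <- shift(f, 1L); fm <- shift(f, -1L)
  okp <- shift(mask, 1L); okp[is.na(okp)] <- FALSE
  okm <- shift(mask, -1L); okm[is.na(okm)] <- FALSE
  if (dim == 1L && !is.na(axis_parity)) {
    # reflect across the axis: ghost value at r = -dr/2 is parity * f[1, ]
    fm[1L, ] <- axis_parity * f[1L, ]
    okm[1L, ] <- mask[1L, ]
  }
  fp[!okp] <- NA; fm[!okm] <- NA
  # second neighbors for 2nd-order one-sided closures at walls/edges
  fpp <- shift(f, 2L); fmm <- shift(f, -2L)
  okpp <- shift(mask, 2L); okpp[is.na(okpp)] <- FALSE
  okmm <- shift(mask, -2L); okmm[is.na(okmm)] <- FALSE
  if (dim == 1L && !is.na(axis_parity)) {
    fmm[2L, ] <- axis_parity * f[1L, ]; okmm[2L, ] <- mask[1L, ]
    fmm[1L, ] <- axis_parity * f[2L, ]; okmm[1L, ] <- mask[2L, ]
  }
  fpp[!okpp] <- NA; fmm[!okmm] <- NA
  d <- (fp - fm) / (2 * h)
  use_f <- is.na(d) & !is.na(fp)   # forward-sided
  use_b <- is.na(d) & !is.na(fm)   # backward-sided
  two_f <- (-3 * f + 4 * fp - fpp) / (2 * h)
  two_b <- (3 * f - 4 * fm + fmm) / (2 * h)
  one_f <- (fp - f) / h
  one_b <- (f - fm) / h
  d[use_f] <- ifelse(is.na(two_f[use_f]), one_f[use_f], two_f[use_f])
  d[use_b] <- ifelse(is.na(two_b[use_b]), one_b[use_b], two_b[use_b])
  d[is.na(d)] <- 0
  d
}

#' Scalar effective shear rate
#'
#' The invariant \eqn{\dot\gamma_{\rm eff} = \sqrt{2\, S\!:\!S}} of the
#' symmetric strain-rate tensor, normalized so that in simple shear
#' \eqn{v_z(r)} it reduces to \eqn{|dv_z/dr|} — the convention required for
#' consistency between the viscosity laws, the shear-stress magnitude
#' \eqn{\tau = \mu \dot\gamma_{\rm eff}}, and the Poiseuille-based analytic
#' damage bound.
#'
#' @param tensor list from [shear_rate_tensor()]
#' @return matrix of effective shear rates (1/s), non-negative
#' @export
effective_shear_rate <- function(tensor) {
  with(tensor, sqrt(2 * (S_rr^2 + S_tt^2 + S_zz^2 + 2 * S_rz^2)))
}

#' Pointwise viscosity field
#'
#' @param rheo an object of class `rheology`
#' @param shear either a `gamma_eff` matrix or a tensor list from
#'   [shear_rate_tensor()]
#' @return matrix of viscosities (Pa s)
#' @export
viscosity_field <- function(rheo, shear) {
  g <- if (is.list(shear)) effective_shear_rate(shear) else shear
  viscosity(rheo, g)
}
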
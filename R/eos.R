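#' Cole (Tait) equation of state for slightly compressible blood
#'
#' Barotropic pressure-density relation
#' \deqn{p(\rho) = p_0 + \frac{\rho_0 c_0^2}{\gamma}
#'       \left[\left(\frac{\rho}{\rho_0}\right)^{\gamma} - 1\right],}
#' which makes the fluid slightly compressible with sound speed \eqn{c_0} at
#' the reference state. A reduced (artificial) sound speed far below the
#' physical one keeps the explicit time step affordable; as long as the flow
#' Mach number stays small the steady solution is insensitive to the choice,
#' and density fluctuations scale as \eqn{\delta\rho/\rho_0 \sim
#' \delta p/(\rho_0 c_0^2)}.
#'
#' @param rho0 reference density (kg/m^3); 1056 for the FDA blood analog
#' @param c0 sound speed at the reference state (m/s); the default 10 m/s is
#'   the reduced value used for all simulations in this package
#' @param p0 reference pressure (Pa); only pressure differences matter, the
#'   default is a typical arterial 13332 Pa (100 mmHg)
#' @param gamma_ad adiabatic index (7 is the customary Cole value)
#' @return object of class `eos_params`
#' @export
eos_params <- function(rho0 = 1056, c0 = 10, p0 = 13332, gamma_ad = 7) {
  stopifnot(rho0 > 0, c0 > 0, gamma_ad >= 1)
  structure(list(rho0 = rho0, c0 = c0, p0 = p0, gamma_ad = gamma_ad),
            class = "eos_params")
}

#' @export
print.eos_params <- function(x, ...) {
  cat(sprintf("<eos_params> rho0 = %g kg/m^3, c0 = %g m/s, p0 = %g Pa, gamma = %g\n",
              x$rho0, x$c0, x$p0, x$gamma_ad))
  invisible(x)
}

#' Pressure from density (Cole EOS)
#'
#' @param rho density (kg/m^3), strictly positive
#' @param eos an [eos_params()]
#' @return pressure (Pa)
#' @export
eos_pressure <- function(rho, eos) {
  stopifnot(inherits(eos, "eos_params"))
  if (any(rho <= 0, na.rm = TRUE)) stop("density must be strictly positive")
  eos$p0 + eos$rho0 * eos$c0^2 / eos$gamma_ad *
    ((rho / eos$rho0)^eos$gamma_ad - 1)
}

#' Density from pressure (exact algebraic inverse of the Cole EOS)
#'
#' @param p pressure (Pa), within the EOS range
#' @param eos an [eos_params()]
#' @return density (kg/m^3)
#' @export
eos_density <- function(p, eos) {
  stopifnot(inherits(eos, "eos_params"))
  arg <- 1 + eos$gamma_ad * (p - eos$p0) / (eos$rho0 * eos$c0^2)
  if (any(arg <= 0, na.rm = TRUE)) stop("pressure outside the EOS range")
  eos$rho0 * arg^(1 / eos$gamma_ad)
}

#' Local sound speed
#'
#' \eqn{c(\rho) = \sqrt{dp/d\rho} = c_0 (\rho/\rho_0)^{(\gamma-1)/2}}.
#'
#' @param rho density (kg/m^3)
#' @param eos an [eos_params()]
#' @return sound speed (m/s)
#' @export
eos_sound_speed <- function(rho, eos) {
  stopifnot(inherits(eos, "eos_params"))
  eos$c0 * (rho / eos$rho0)^((eos$gamma_ad - 1) / 2)
}
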
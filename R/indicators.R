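#' Sampled 1D profile of a physical quantity
#'
#' A light data.frame subclass holding a quantity sampled along an axial or
#' radial cut, with units and cut metadata — the common currency of the
#' indicator functions and the CSV writers.
#'
#' @param coordinate strictly monotone numeric vector (m)
#' @param value numeric vector of samples, same length
#' @param quantity name of the quantity
#' @param units unit string
#' @param meta named list of metadata (cut position, model tag, ...)
#' @return a `profile_series` (data.frame with columns `coordinate`, `value`)
#' @export
profile_series <- function(coordinate, value, quantity = "quantity",
                           units = "", meta = list()) {
  stopifnot(length(coordinate) == length(value))
  if (length(coordinate) > 1 && !(all(diff(coordinate) > 0) ||
                                  all(diff(coordinate) < 0)))
    stop("profile coordinates must be strictly monotone")
  structure(data.frame(coordinate = coordinate, value = value),
            quantity = quantity, units = units, meta = meta,
            class = c("profile_series", "data.frame"))
}

#' @export
print.profile_series <- function(x, ...) {
  cat(sprintf("<profile_series> %s [%s], %d samples on [%g, %g]\n",
              attr(x, "quantity"), attr(x, "units"), nrow(x),
              min(x$coordinate), max(x$coordinate)))
  invisible(x)
}

#' Mass-flow conservation metric
#'
#' At each axial station the mass flow rate is the transverse integral
#' \eqn{\dot m(z) = \int \rho v_z\, 2\pi r\, dr} (midpoint rule over fluid
#' cell centers). Deviations from the theoretical inlet value
#' \eqn{\dot m_{\rm in} = \rho_0 Q} are pure numerical error and concentrate
#' where the wall is hardest to fit on a regular mesh (e.g. the conical
#' collector of the benchmark nozzle), making this profile a primary
#' quality indicator of a run.
#'
#' @param state a [flow_state()]
#' @param geom a [nozzle_geometry()]
#' @param mdot_ref reference mass flow (kg/s); defaults to the inlet-station
#'   integral of the state itself
#' @param mask optional precomputed fluid mask
#' @return a [profile_series()] of the relative error
#'   \eqn{(\dot m(z)-\dot m_{\rm in})/\dot m_{\rm in}} versus z, with the
#'   absolute `mdot` attached as attribute `mdot`
#' @export
mass_flow_profile <- function(state, geom, mdot_ref = NULL, mask = NULL) {
  stopifnot(inherits(state, "flow_state"))
  grid <- state$grid
  if (is.null(mask)) mask <- build_mask(geom, grid)
  mdot <- numeric(grid$nz)
  for (j in seq_len(grid$nz)) {
    f <- mask[, j]
    mdot[j] <- 2 * pi * grid$dr * sum(state$mz[f, j] * grid$r[f])
  }
  if (is.null(mdot_ref)) mdot_ref <- mdot[1]
  out <- profile_series(grid$z, (mdot - mdot_ref) / mdot_ref,
                        quantity = "mass flow relative error", units = "1",
                        meta = list(mdot_ref = mdot_ref))
  attr(out, "mdot") <- mdot
  out
}

#' Centerline pressure drop profile
#'
#' Pressure is recovered pointwise from the density via the equation of
#' state — one of the benefits of the slightly-compressible formulation —
#' and reported along the centerline relative to the inlet value.
#' Centerline values are taken from the first cell row adjacent to the axis
#' (cell-centered grids have no row exactly at r = 0).
#'
#' @param state a [flow_state()]
#' @param eos an [eos_params()]
#' @return a [profile_series()] of \eqn{p(z) - p_{\rm inlet}} (Pa) versus z
#' @export
pressure_drop_profile <- function(state, eos) {
  stopifnot(inherits(state, "flow_state"), inherits(eos, "eos_params"))
  grid <- state$grid
  p <- eos_pressure(state$rho[1, ], eos)
  profile_series(grid$z, p - p[1],
                 quantity = "centerline pressure drop", units = "Pa")
}

#' Simplified Bernoulli pressure-drop estimate
#'
#' The clinical estimate \eqn{\Delta p = \tfrac12 \rho v_{\rm peak}^2} of the
#' drop across a narrowing from the peak velocity, assuming negligible inlet
#' velocity — what a physician infers from Doppler data. Being inviscid it
#' underestimates the true drop.
#'
#' @param v_peak peak velocity (m/s), non-negative
#' @param rho density (kg/m^3)
#' @return pressure drop (Pa)
#' @export
bernoulli_drop <- function(v_peak, rho) {
  stopifnot(v_peak >= 0, rho > 0)
  0.5 * rho * v_peak^2
}

#' Convert pascals to millimetres of mercury
#' @param p pressure (Pa)
#' @return pressure (mmHg)
#' @export
pa_to_mmhg <- function(p) p / 133.322387415

#' Shear-stress magnitude field
#'
#' Pointwise \eqn{\tau = \mu(\dot\gamma_{\rm eff})\, \dot\gamma_{\rm eff}}
#' from the strain-rate invariant of the velocity field.
#'
#' @param state a [flow_state()]
#' @param geom a [nozzle_geometry()]
#' @param rheology a `rheology` object
#' @param cuts optional axial stations (m) at which radial-cut profiles are
#'   extracted
#' @param mask optional precomputed fluid mask
#' @return list with matrix `tau` (Pa; zero on solid cells), `gamma_eff`,
#'   and `profiles` (list of [profile_series()], one per cut)
#' @export
shear_stress_field <- function(state, geom, rheology, cuts = NULL,
                               mask = NULL) {
  stopifnot(inherits(state, "flow_state"), inherits(rheology, "rheology"))
  grid <- state$grid
  if (is.null(mask)) mask <- build_mask(geom, grid)
  v <- velocity(state)
  v$vr[!mask] <- 0; v$vz[!mask] <- 0
  S <- shear_rate_tensor(v$vr, v$vz, grid, mask)
  gam <- effective_shear_rate(S)
  tau <- viscosity(rheology, gam) * gam
  tau[!mask] <- 0
  profiles <- list()
  if (!is.null(cuts)) {
    for (zc in cuts) {
      j <- which.min(abs(grid$z - zc))
      f <- mask[, j]
      profiles[[length(profiles) + 1]] <-
        profile_series(grid$r[f], tau[f, j], quantity = "shear stress",
                       units = "Pa", meta = list(z_cut = grid$z[j]))
    }
  }
  list(tau = tau, gamma_eff = gam, profiles = profiles)
}

#' Wall shear stress along the conduit
#'
#' For each axial column the outermost fluid cell is located and the
#' shear-stress magnitude is sampled `offset` cells radially inward
#' (default 2). Sampling below the staircase wall deliberately trades a
#' small systematic inward bias for robustness against the jagged staircase
#' representation of inclined walls; the bias vanishes under grid
#' refinement.
#'
#' @param state a [flow_state()]
#' @param geom a [nozzle_geometry()]
#' @param rheology a `rheology` object
#' @param offset cells below the wall at which to sample (default 2)
#' @param mask optional precomputed fluid mask
#' @return a [profile_series()] of WSS (Pa) versus z; columns with fewer
#'   than `offset + 1` fluid cells yield `NA`
#' @export
wss_profile <- function(state, geom, rheology, offset = 2L, mask = NULL) {
  grid <- state$grid
  if (is.null(mask)) mask <- build_mask(geom, grid)
  tau <- shear_stress_field(state, geom, rheology, mask = mask)$tau
  wss <- rep(NA_real_, grid$nz)
  for (j in seq_len(grid$nz)) {
    f <- which(mask[, j])
    if (length(f) < offset + 1L) next
    iw <- max(f)
    wss[j] <- tau[iw - offset, j]
  }
  profile_series(grid$z, wss, quantity = "WSS", units = "Pa",
                 meta = list(offset = offset))
}

#' Extract centerline and radial-cut profiles
#'
#' Bilinear sampling of the standard comparison quantities: axial and radial
#' velocity, pressure and shear-stress magnitude, along the centerline and
#' along radial cuts at requested axial stations. Sampling exactly on a
#' grid line reproduces the grid values.
#'
#' @param state a [flow_state()]
#' @param geom a [nozzle_geometry()]
#' @param eos an [eos_params()]
#' @param rheology a `rheology` object
#' @param cuts axial stations (m) for radial cuts; must lie inside the grid
#' @param quantities subset of `c("vz", "vr", "p", "tau")`
#' @return named list: `centerline` (list of [profile_series()] vs z) and
#'   `cuts` (list, one element per station, each a list of profiles vs r)
#' @export
extract_profiles <- function(state, geom, eos, rheology,
                             cuts = numeric(0),
                             quantities = c("vz", "vr", "p", "tau")) {
  grid <- state$grid
  if (length(cuts) && (any(cuts < grid$z_min) || any(cuts > grid$z_max)))
    stop("requested cut outside the domain")
  mask <- build_mask(geom, grid)
  v <- velocity(state)
  v$vr[!mask] <- 0; v$vz[!mask] <- 0
  fields <- list()
  if ("vz" %in% quantities) fields$vz <- list(m = v$vz, units = "m/s")
  if ("vr" %in% quantities) fields$vr <- list(m = v$vr, units = "m/s")
  if ("p" %in% quantities)
    fields$p <- list(m = eos_pressure(state$rho, eos), units = "Pa")
  if ("tau" %in% quantities)
    fields$tau <- list(m = shear_stress_field(state, geom, rheology,
                                              mask = mask)$tau, units = "Pa")
  centerline <- lapply(names(fields), function(q) {
    profile_series(grid$z, fields[[q]]$m[1, ], quantity = q,
                   units = fields[[q]]$units, meta = list(cut = "centerline"))
  })
  names(centerline) <- names(fields)
  cut_list <- lapply(cuts, function(zc) {
    j <- which.min(abs(grid$z - zc))
    out <- lapply(names(fields), function(q) {
      profile_series(grid$r, fields[[q]]$m[, j], quantity = q,
                     units = fields[[q]]$units, meta = list(z_cut = grid$z[j]))
    })
    names(out) <- names(fields)
    out
  })
  list(centerline = centerline, cuts = cut_list)
}

#' Write a profile series to CSV
#'
#' Plain CSV with a commented header carrying quantity, units and metadata.
#'
#' @param x a [profile_series()]
#' @param file output path
#' @return `file`, invisibly
#' @export
write_profile_csv <- function(x, file) {
  stopifnot(inherits(x, "profile_series"))
  meta <- attr(x, "meta")
  hdr <- c(sprintf("# quantity: %s", attr(x, "quantity")),
           sprintf("# units: %s", attr(x, "units")),
           if (length(meta)) sprintf("# %s: %s", names(meta),
                                     vapply(meta, format, character(1))))
  con <- file(file, "w")
  on.exit(close(con))
  writeLines(hdr, con)
  utils::write.csv(as.data.frame(x), con, row.names = FALSE)
  invisible(file)
}
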
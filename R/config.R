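#' Read a run configuration
#'
#' A run configuration is a YAML (or JSON) file with blocks `geometry`,
#' `grid`, `rheology`, `eos`, `inflow`, `solver`, `hemolysis`, `outputs`.
#' Presets are supported: `geometry: fda_nozzle`, rheology presets
#' `"newtonian"`, `"carreau_yasuda_abraham"`, `"casson_perktold"`, and the
#' Giersiepen hemolysis preset. See the example configuration shipped at
#' `system.file("extdata", "fda_re500.yaml", package = "hemocfd")`.
#'
#' @param file path to a YAML configuration
#' @return a named list of model objects ready for [run_simulation()]
#' @export
read_run_config <- function(file) {
  cfg <- yaml::read_yaml(file)
  out <- list()

  g <- cfg$geometry
  out$geom <- if (is.character(g) || !is.null(g$preset)) {
    preset <- if (is.character(g)) g else g$preset
    switch(preset,
           fda_nozzle = do.call(fda_nozzle, g[intersect(names(g),
                                c("z_inlet", "z_outlet"))] %||% list()),
           stop("unknown geometry preset: ", preset))
  } else {
    nozzle_geometry(as.data.frame(do.call(rbind, lapply(g$segments, as.data.frame))))
  }

  rh <- cfg$rheology %||% "newtonian"
  out$rheology <- if (is.character(rh)) rheology_preset(rh)
  else switch(rh$model,
              newtonian = rheology_newtonian(rh$mu %||% 0.0035),
              carreau_yasuda = do.call(rheology_carreau_yasuda,
                                       rh[intersect(names(rh),
                                       c("mu0", "mu_inf", "lambda", "a", "n"))]),
              casson = do.call(rheology_casson,
                               rh[intersect(names(rh),
                               c("k_tau", "k_mu", "gamma_cutoff"))]),
              stop("unknown rheology model: ", rh$model))

  e <- cfg$eos %||% list()
  out$eos <- do.call(eos_params,
                     e[intersect(names(e), c("rho0", "c0", "p0", "gamma_ad"))])

  stopifnot(!is.null(cfg$inflow$Q) || !is.null(cfg$inflow$Re))
  out$Q <- cfg$inflow$Q %||%
    flow_rate_for_re(cfg$inflow$Re,
                     R_throat = cfg$inflow$R_throat %||% 0.002,
                     mu = cfg$inflow$mu %||% 0.0035, rho = out$eos$rho0)

  gr <- cfg$grid
  stopifnot(!is.null(gr$dr))
  out$dr <- gr$dr; out$dz <- gr$dz %||% (2 * gr$dr)

  s <- cfg$solver %||% list()
  out$control <- do.call(solver_control,
                         s[intersect(names(s),
                           names(formals(solver_control)))])

  h <- cfg$hemolysis
  out$coeff <- if (is.null(h)) NULL
  else if (is.character(h) && h == "giersiepen") hemolysis_coefficients()
  else do.call(hemolysis_coefficients,
               h[intersect(names(h), c("C", "a", "b", "Hct", "Hb"))])

  out$outputs <- cfg$outputs %||% list()
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run a configured simulation and write its outputs
#'
#' Solves the steady flow (and, if hemolysis coefficients are configured,
#' the Eulerian linear-damage field), then writes CSV profiles (mass-flow
#' error, centerline pressure drop, WSS, centerline velocity, NIH along the
#' axis) and a rectilinear VTK snapshot of the fields into `out_dir`.
#'
#' @param config path to a YAML file or a list from [read_run_config()]
#' @param out_dir output directory (created if missing)
#' @return invisibly, the result of [simulate_steady()]
#' @export
run_simulation <- function(config, out_dir = "hemocfd-out") {
  cfg <- if (is.character(config)) read_run_config(config) else config
  sim <- simulate_steady(cfg$geom, cfg$Q, cfg$rheology, dr = cfg$dr,
                         dz = cfg$dz, eos = cfg$eos, control = cfg$control,
                         coeff = cfg$coeff)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  geom <- cfg$geom
  write_profile_csv(mass_flow_profile(sim$state, geom,
                                      mdot_ref = cfg$eos$rho0 * cfg$Q),
                    file.path(out_dir, "mass_flow_error.csv"))
  write_profile_csv(pressure_drop_profile(sim$state, cfg$eos),
                    file.path(out_dir, "pressure_drop.csv"))
  write_profile_csv(wss_profile(sim$state, geom, cfg$rheology),
                    file.path(out_dir, "wss.csv"))
  pr <- extract_profiles(sim$state, geom, cfg$eos, cfg$rheology)
  write_profile_csv(pr$centerline$vz,
                    file.path(out_dir, "centerline_vz.csv"))
  if (!is.null(cfg$coeff))
    write_profile_csv(eulerian_nih_profile(sim$state, geom, cfg$coeff,
                                           mask = sim$mask),
                      file.path(out_dir, "nih_profile.csv"))
  write_vtk_rectilinear(sim$state, file.path(out_dir, "fields.vtr.vtk"),
                        eos = cfg$eos)
  conv <- data.frame(step = seq_along(sim$residuals) *
                       cfg$control$check_every,
                     residual = sim$residuals)
  utils::write.csv(conv, file.path(out_dir, "residuals.csv"),
                   row.names = FALSE)
  invisible(sim)
}

#' Write a flow state as a legacy-ASCII rectilinear VTK file
#'
#' Plain-text structured-grid output readable by ParaView and VisIt. The
#' axisymmetric (r, z) fields are written as a 2D rectilinear grid with
#' point data: density, velocity components, pressure and linear damage.
#'
#' @param state a [flow_state()]
#' @param file output path
#' @param eos an [eos_params()] used to attach the pressure field
#' @return `file`, invisibly
#' @export
write_vtk_rectilinear <- function(state, file, eos = eos_params()) {
  grid <- state$grid
  v <- velocity(state)
  con <- file(file, "w")
  on.exit(close(con))
  w <- function(...) writeLines(sprintf(...), con)
  w("# vtk DataFile Version 3.0")
  w("hemocfd axisymmetric flow state, t = %g s", state$t)
  w("ASCII")
  w("DATASET RECTILINEAR_GRID")
  w("DIMENSIONS %d %d 1", grid$nr, grid$nz)
  w("X_COORDINATES %d double", grid$nr)
  writeLines(paste(format(grid$r, digits = 10), collapse = " "), con)
  w("Y_COORDINATES %d double", grid$nz)
  writeLines(paste(format(grid$z, digits = 10), collapse = " "), con)
  w("Z_COORDINATES 1 double")
  writeLines("0", con)
  w("POINT_DATA %d", grid$nr * grid$nz)
  dump_scalar <- function(name, m) {
    w("SCALARS %s double 1", name)
    w("LOOKUP_TABLE default")
    writeLines(paste(format(as.vector(m), digits = 10), collapse = " "), con)
  }
  dump_scalar("density", state$rho)
  dump_scalar("v_r", v$vr)
  dump_scalar("v_z", v$vz)
  dump_scalar("pressure", eos_pressure(state$rho, eos))
  dump_scalar("linear_damage", state$rhoDl / state$rho)
  invisible(file)
}
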
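# Shared scaled-down benchmark-nozzle runs for the acceptance suite.
# One steady solve per rheology, cached across test files.

nozzle_case <- function() {
  list(geom = fda_nozzle(z_inlet = -0.07, z_outlet = 0.05),
       Q = flow_rate_for_re(500),
       dr = 3.33e-4,
       control = solver_control(tol = 2e-6, t_end = 0.8, ramp_time = 0.03,
                                interior_order = 5, check_every = 200L))
}

nozzle_run <- function(model = c("newtonian", "carreau_yasuda_abraham",
                                 "casson_perktold")) {
  model <- match.arg(model)
  cached(paste0("nozzle_", model), {
    cs <- nozzle_case()
    simulate_steady(cs$geom, cs$Q, rheology_preset(model), dr = cs$dr,
                    control = cs$control, coeff = default_coeff)
  })
}
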
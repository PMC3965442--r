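# A shortened cone-throat-expansion conduit with the benchmark throat
# radius (so the throat Reynolds number matches the full case at the same
# flow rate), used for refinement and model-ordering checks where the full
# nozzle would be too expensive.

mini_nozzle <- function() {
  l_cone <- 0.002 / tan(10 * pi / 180)
  nozzle_geometry(data.frame(
    z_start = c(-0.032, -0.01 - l_cone, -0.01, 0),
    z_end   = c(-0.01 - l_cone, -0.01, 0, 0.025),
    kind    = c("constant", "cone", "constant", "constant"),
    R_start = c(0.004, 0.004, 0.002, 0.004),
    R_end   = c(0.004, 0.002, 0.002, 0.004)))
}

mini_run <- function(model, dr, t_end = 0.5) {
  cached(sprintf("mini_%s_%g", model, dr), {
    ctl <- solver_control(tol = 2e-6, t_end = t_end, ramp_time = 0.03,
                          interior_order = 5, check_every = 200L)
    simulate_steady(mini_nozzle(), flow_rate_for_re(500),
                    rheology_preset(model), dr = dr, control = ctl,
                    coeff = default_coeff)
  })
}
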
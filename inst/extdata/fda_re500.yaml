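# Benchmark nozzle, throat Reynolds number 500, Carreau-Yasuda blood.
# Resolution here is the scaled-down demonstration setting; refine dr/dz
# (and extend z_inlet/z_outlet) for production runs.
geometry:
  preset: fda_nozzle
  z_inlet: -0.075
  z_outlet: 0.06
grid:
  dr: 2.5e-4
  dz: 5.0e-4
rheology: carreau_yasuda_abraham
eos:
  rho0: 1056
  c0: 10
  p0: 13332
  gamma_ad: 7
inflow:
  Re: 500
solver:
  cfl: 0.4
  interior_order: 5
  tol: 1.0e-6
  t_end: 1.0
  ramp_time: 0.03
hemolysis: giersiepen
outputs:
  profiles: [mass_flow_error, pressure_drop, wss, centerline_vz, nih]
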
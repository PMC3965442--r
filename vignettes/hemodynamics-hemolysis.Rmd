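---
title: "Weakly-compressible axisymmetric blood flow and hemolysis modelling"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Weakly-compressible axisymmetric blood flow and hemolysis modelling}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of the models it implements, the
numerical choices behind them, and what the test suite does and does not
demonstrate. It is written for a reader who wants to judge whether the
methods are appropriate for their problem, not as a user manual (see the
README and function reference for that).

## The physical model

We solve the compressible Navier–Stokes equations in axisymmetric
cylindrical coordinates for the density $\rho$ and the momentum densities
$(m_r, m_z)$:

$$\partial_t \rho + \nabla\cdot(\rho v) = 0, \qquad
\partial_t (\rho v) + \nabla\cdot(\rho v v) = -\nabla p +
\nabla\cdot\sigma + \rho f,$$

with the viscous stress
$\sigma = \mu(\dot\gamma)\,(\nabla v + \nabla v^T) - \tfrac{2}{3}\mu
(\nabla\cdot v) I$ (the bulk-viscosity contribution is neglected, the only
physical approximation made at this level). Axial symmetry removes the
azimuthal coordinate; the hoop components of the divergence and stress are
retained as geometric source terms.

Blood is treated as *slightly compressible* instead of incompressible: the
Cole (Tait) equation of state
$p(\rho) = p_0 + \frac{\rho_0 c_0^2}{\gamma}\left[(\rho/\rho_0)^\gamma -
1\right]$ with $\gamma = 7$ closes the system, so pressure is an ordinary
evolved quantity (no Poisson solve, no SIMPLE/PISO iteration) and is read
off the density field wherever needed. The price is an acoustic CFL
constraint; we pay it with a *reduced sound speed*, $c_0 = 10$ m/s by
default, far below the physical value but large enough that the flow Mach
number stays below $\sim 0.1$ and density fluctuations below $\sim 10^{-3}$
for the flows of interest. The test suite asserts directly that doubling
$c_0$ changes the steady velocity field by less than 1 % in $L_2$, which is
the operational justification for the reduction. The reference pressure
$p_0$ (default 13332 Pa, i.e. 100 mmHg) only shifts the pressure scale;
every reported pressure is a difference.

Reference fluid constants follow the benchmark blood analog:
$\rho_0 = 1056\ \mathrm{kg/m^3}$, Newtonian $\mu = 3.5$ mPa s. The
benchmark nozzle geometry (12 mm inlet/outlet diameter, 20° conical
collector, 4 mm throat diameter over 40 mm, sudden expansion at $z = 0$) is
shipped as the `fda_nozzle()` preset rather than hard-coded anywhere; the
throat Reynolds number 500 corresponds to
$Q = \mathrm{flow\_rate\_for\_re}(500) = 5.206\times 10^{-6}\ \mathrm{m^3/s}$.

### Rheology

Three viscosity laws share a single interface, all driven by the effective
shear rate $\dot\gamma_{\rm eff} = \sqrt{2\,S\!:\!S}$ of the strain-rate
tensor $S = \tfrac12(\nabla v + \nabla v^T)$. This normalization is a
*convention choice*: several inequivalent factor conventions for the
"shear-rate tensor" circulate in the literature. We fix the one for which
unidirectional shear $v_z(r)$ gives $\dot\gamma_{\rm eff} = |dv_z/dr|$,
because it is the only choice simultaneously consistent with the viscosity
calibrations we ship, the shear-stress magnitude
$\tau = \mu\dot\gamma_{\rm eff}$ fed to the damage law, and the
Poiseuille-based analytic damage bound below.

* Newtonian: constant $\mu$, by convention equal to the Carreau–Yasuda
  infinite-shear viscosity, so the Newtonian model is the high-shear limit
  of the non-Newtonian ones.
* Carreau–Yasuda:
  $\mu = \mu_\infty + (\mu_0-\mu_\infty)[1+(\lambda\dot\gamma)^a]^{(n-1)/a}$
  with the Abraham et al. blood calibration
  ($\mu_0 = 0.16$ Pa s, $\mu_\infty = 3.5$ mPa s, $\lambda = 8.2$ s,
  $a = 0.64$, $n = 0.2128$). Strictly decreasing in $\dot\gamma$ and
  bounded in $[\mu_\infty, \mu_0]$.
* Casson: $\mu = (\sqrt{k_\tau/\dot\gamma} + \sqrt{k_\mu})^2$ with
  Perktold-derived constants ($k_\tau = 0.1937^2$ Pa,
  $k_\mu = 0.055^2$ Pa s). The law diverges as $\dot\gamma \to 0$, which is
  unphysical below the fit's validity range, so a cutoff holds
  $\mu$ constant below $\dot\gamma_c = 1\ \mathrm{s^{-1}}$ (the value below
  which the fit is no longer trusted). At the cutoff the low-shear ordering
  Casson ≥ Carreau–Yasuda ≥ Newtonian holds, which the tests assert.

## The numerical scheme

The grid is regular and cell-centered with radial centers at
$r_i = (i-\tfrac12)\Delta r$ — no cell sits on the axis, so the $1/r$
metric factors stay finite; the axis is closed by parity ghost rows
($v_r$ odd; $\rho$, $v_z$, $\rho D_l$ even).

Advective and pressure fluxes use conservative flux-interpolation finite
differences: at each face the numerical flux is the average of the left-
and right-biased Lagrange flux interpolations plus a matrix-free
dissipation term acting on the state,
$\hat F = \tfrac12[P(F)+N(F)] + \tfrac{a}{2}[P(u)-N(u)]$. The biased
interpolation pairs are the linear (unlimited) 3rd/5th/7th-order upwind
stencils; no nonlinear limiter is applied because every flow in scope is
smooth and laminar (the acceptance properties are convergence- and
physics-based, not scheme-identity-based). Three details of this operator
took actual debugging effort and are worth recording:

1. **Radial conservation and the axis.** The radial divergence is
   discretized in conservative form $(1/r_i)\,\Delta_r(r\hat F)$, and the
   *face* radius multiplies the dissipation term, so it is non-negative on
   every face that updates a fluid cell even though the stencils reach
   signed-$r$ ghost rows. The axis face carries exactly zero flux (zero
   area), which makes total mass conservation exact to roundoff — the
   periodic-box test asserts $10^{-12}$ relative per step.
2. **Characteristic-aware dissipation speeds.** Density and the
   face-normal momentum are dissipated at the acoustic speed
   $\max(|v|+c)$; the transverse (shear) momentum and the passive damage
   field only at the advective speed $\max|v|$. Acoustic-scale dissipation
   on the shear profile would otherwise swamp the physical viscosity in
   near-wall cells, where the stencil order is reduced.
3. **Span-capped order.** Fluid columns narrower than about ten cells
   cannot support the widest stencils (the coupling between axis ghosts
   and a nearby wall destabilizes them); the face order is capped by the
   local fluid span (7th order from 10 cells, 5th from 8, 3rd from 5).
   The default interior order is 7; throat-like regions at coarse
   resolution therefore run at 5th order automatically.

Viscous stresses are evaluated at cell faces at second order with
face-averaged viscosity; this is deliberate — for the laminar,
viscosity-dominated flows in scope the steady-state error is controlled by
the wall representation, not by the interior advection order, and the
face-based form is exact for parabolic profiles (the Poiseuille test
recovers the analytic profile to $5\times10^{-5}$ in $L_2$ and the
Hagen–Poiseuille pressure slope to under 0.1 %).

Walls are a staircase mask (a cell is fluid iff its center is inside
$r \le R(z)$; sub-cell volume-of-fluid fractions are out of scope).
Fluid–solid faces are impermeable: the advective flux is zeroed and only
the pressure contribution remains. No-slip enters through ghost values in
the first solid layer, quadratically extrapolated so the velocity vanishes
at the face (exact for parabolic profiles); density and linear damage are
mirrored with zero normal gradient.

Boundaries in $z$: the inflow imposes the Poiseuille profile
$v_z = v_{\max}[1-(r/R)^2]$, $v_{\max} = 2Q/\pi R^2$, ramped smoothly over
`ramp_time` (default 50 ms) to suppress the start-up acoustic transient,
with density free (zero gradient — the outgoing characteristic). The
outflow extrapolates both Riemann invariants (transparent boundary) with an
optional weak pull of the sound speed toward the reference outlet state
(`outflow_relax`); the mean pressure is anchored instead by a *gentle*
absorbing sponge over the last `sponge_cells` columns
($\sigma_{\max} = c_0/(12 L_{\rm sponge})$, quadratic ramp, acting on
density and radial momentum only). Strong sponges and strongly pulled
characteristics are themselves reflectors — the shipped defaults measure a
reflected-pulse amplitude below 5 % of the incident one, against a
hard-wall control run that reflects essentially fully, and that measurement
is a regression test.

Time integration is SSP-RK3 under a combined acoustic + viscous CFL limit
(default CFL 0.4, well inside the stability region). Steady state is
declared when the windowed max-norm relative change of momentum over
`check_every` steps drops below `tol` ($10^{-8}$ by default; the scaled
test cases use $10^{-6}$–$10^{-7}$, which the CFL-independence test shows
is already well inside the asymptotic plateau). Divergence (non-finite
fields) aborts with a diagnostic.

The conservative linear-damage density $\rho D_l$ is advected with the
same scheme and order as mass, with source $\rho\,C^{1/a}\tau^{b/a}$ from
the local instantaneous shear stress. Because the damage field needs
several mean transit times to fill the domain while the momentum field
converges faster, `simulate_steady()` co-evolves the flow first and then
relaxes the damage field over the *frozen* velocity field, where the
acoustic CFL constraint disappears; a test verifies the shortcut agrees
with full co-evolution.

## Hemolysis

The empirical damage law for constant shear stress,
$D = C\tau^b t^a$ with the Giersiepen coefficients
($C = 3.62\times10^{-7}$ in the damage-fraction convention, $a = 0.785$,
$b = 2.416$), is sublinear in time, so its differential form matters. The
package follows the damage-linearization route: $D_l = D^{1/a}$ grows at
the history-independent rate $dD_l/dt = C^{1/a}\tau^{b/a}$, and for
constant $\tau$ integrating and un-linearizing recovers the power law
*exactly* (asserted to $10^{-12}$). $D_l$ is an auxiliary variable without
physical meaning: averages must be taken over $D = D_l^a$, never over
$D_l$. Averaging $D_l$ first overestimates damage by the Jensen factor
$(\sum w_i D_{l,i})^a / \sum w_i D_{l,i}^a \ge 1$, computed by
`linear_averaging_overestimate()`; for the Poiseuille damage distribution
with the default exponents the factor is well above 1.2.

Two CFD routes produce the flow-weighted averaged NIH:

* **Pathlines** (`trace_pathlines()` + `average_nih_pathlines()`): RK4
  streamline integration through the steady field with bilinear sampling
  of velocity and $\tau$. Seeds default to 64 equal-flow-increment radii
  at the inlet ($s_k = \sqrt{1-\sqrt{1-F_k}}$ from the Poiseuille flux
  function $F = 2s^2 - s^4$), giving equal weights. Pathlines that fail
  to exit within 50 mean transit times (recirculation) are flagged,
  reported, and excluded from the average — in a steady planar
  recirculation bubble a trapped particle never exits, so any other
  convention would make the average depend on an arbitrary cut-off time.
* **Eulerian field** (`eulerian_nih_profile()`): pointwise
  $D = (\rho D_l/\rho)^a$, flow-weighted (local mass flux
  $\rho v_z\,2\pi r\,\Delta r$) over each radial cut, giving NIH$(z)$.

The two routes are equivalent on attached flows, and the test suite
asserts their agreement on analytic fixtures. In *recirculating* flow they
genuinely part ways: a steady closed streamline accumulates damage source
indefinitely, so the Eulerian field inside a recirculation bubble is
bounded only by diffusion and by the transport integration budget, and the
bubble fluid entrained into the jet's shear layer raises the Eulerian
average above the pathline one (whose inlet-seeded trajectories traverse
the core and exit; trapped trajectories are excluded by construction).
Neither number is wrong — they answer slightly different questions about
an idealization (steady 2D recirculation with no escape) that real blood
does not satisfy. Nozzle-level damage comparisons in this package
therefore quote the Eulerian value, which includes all shear exposure, and
report the pathline value alongside it.

The flow-weighted damage density diverges weakly at the wall
($\propto (1-F)^{-a/2}$ in flux coordinates), so the equal-increment seed
quadrature converges from below at rate $n^{-(1-a/2)}$; at 64 seeds the
pathline route sits a few percent below the closed form on the analytic
Poiseuille fixture, and the cross-route consistency tests use 128 seeds
and a 5 % tolerance. This is a quadrature property of the method itself,
not an implementation artifact, and is the reason route agreement — not
agreement with the closed form — is the acceptance-level check.

**Analytic lower bound.** Assuming a local Poiseuille profile with the
same $Q$ at every $z$ (exact in straight tubes, a lower-bound
approximation wherever jets and recirculation add shear), streamlines sit
at fixed relative radius $s$, $\tau = 4\mu Q s/\pi R^3$, and
$dt = \pi R^2\,dz/[2Q(1-s^2)]$. The average damage collapses to

$$\langle D\rangle = 2C\left(\frac{4\mu Q}{\pi}\right)^{b}
\left(\frac{\pi}{2Q}\right)^{a} I^{\,a}\,
B\!\left(\frac{b}{2}+1,\ 2-a\right), \qquad
I = \int R(z)^{\,2-3b/a}\,dz,$$

evaluated segment-wise in closed form by `geometry_integral()` (exponent
$q = 2 - 3b/a \approx -7.233$ for the default coefficients). The test
suite checks the closed form against an independent brute-force quadrature
oracle (streamline-by-streamline numerical integration) to $10^{-6}$
relative on straight, stepped, conical and full-nozzle geometries.
Internally everything is SI; `geometry_integral()` also exposes the
millimetre convention ($I$ with $R$, $z$ in mm, plus the matching
prefactor `K_mm`), since the bound is traditionally quoted that way. For
the benchmark nozzle $I_{\rm mm} = 0.278$ and the bound gives
NIH $= 2.5\times10^{-3}$ g/100 L at Re = 500 — the floor against which
the CFD values are compared (`NIH_CFD ≥ bound` is a tested property).

**Time-explicit variant.** Differentiating the power law at a fixed time
origin instead gives $dD/dt = C a\,t^{a-1}\tau^b$ (`arora_nih()`),
integrated interval-exactly in $t$ to handle the integrable $t^{a-1}$
singularity. It reproduces the constant-stress law when the origin
coincides with exposure start, but the result depends on the origin choice
— shifting it earlier strictly decreases the damage (with $a<1$ the rate
decays in $t$) — which is precisely the conceptual weakness the
linear-damage route avoids; both behaviors are asserted in tests.

**NIH conversion.** NIH $= 100\,(1-\mathrm{Hct})\,\mathrm{Hb}\,\langle
D\rangle$ in g/100 L, linear in both the hemoglobin content (default
150 g/L) and the plasma fraction (default Hct 0.45); the linearity is
tested, so any recalibration of the blood constants rescales results
transparently.

## Physiological indicators

* **Mass-flow metric**: $\dot m(z) = \sum \rho v_z\,2\pi r\,\Delta r$ over
  fluid cells (midpoint rule, consistent with the cell-centered staircase),
  reported relative to $\rho_0 Q$. Deviations are numerical error and
  concentrate where the wall is hardest to rasterize — on the benchmark
  nozzle, the conical collector; the acceptance suite checks the location
  of the worst error as a property.
* **Pressure drop**: centerline pressure via the EOS from the first cell
  row adjacent to the axis (no extrapolation), relative to the inlet. The
  simplified Bernoulli estimate $\tfrac12\rho v_{\rm peak}^2$ is provided
  for the clinical comparison; being inviscid it underestimates the CFD
  drop, and that ordering is asserted on the nozzle run.
* **WSS**: per axial column, $\tau$ sampled two cells radially inward of
  the outermost fluid cell. Sampling *below* the wall trades a systematic
  inward bias (factor $1 - 2.5\Delta r/R$ on a Poiseuille profile, which
  the tests verify quantitatively) for robustness against the staircase
  jitter of inclined walls; the offset is configurable and the bias
  vanishes under refinement. One practical consequence at coarse
  resolution: the WSS *entrance peak* at the cone-to-throat transition
  lives in a boundary layer thinner than the two-cell offset, so with only
  6–8 cells per throat radius the offset-2 profile plateaus mid-throat
  while the offset-0 profile shows the peak at the transition; the
  location test therefore samples the outermost cell.
* **Profile extraction**: centerline and radial cuts of $v_z$, $v_r$, $p$,
  $\tau$ with snap-to-grid sampling (exact on grid lines), CSV output with
  unit-bearing headers for overlay against experimental profile tables.

## Synthetic fixtures

`make_poiseuille_field()` builds the local-Poiseuille state on any
geometry with analytic metadata (velocity, $\tau$, WSS, transit times,
pressure slope) and is the oracle substrate for the rheology, indicator,
pathline and hemolysis tests without running the solver.
`make_perturbed_field()` adds a seeded, divergence-free streamfunction
perturbation (exactly flux-free in straight tubes) for robustness checks.
What the fixtures deliberately do **not** emulate: jets, recirculation,
staircase-wall artifacts, compressibility, or measurement noise — so
fixture-based tests validate the *post-processing chain*, while the solver
tests and nozzle runs validate the *flow physics*. Passing fixture tests
says nothing about turbulence or transitional regimes, which are out of
scope entirely (the solver is laminar DNS; throat Re ≥ 2000 would need
mesh adaptivity and 3D azimuthal physics this package does not have).

## Problem sizes and tolerances used by the shipped checks

The test suite and the acceptance script run scaled-down configurations
chosen as the coarsest settings at which each property is cleanly
observable: straight-tube solves at $\Delta r = 0.25$ mm (8 cells per
radius), nozzle runs at $\Delta r = 0.25$–0.42 mm (6–8 cells per throat
radius, domain $z \in [-75, 60]$ mm, 1.0 s of physical time, momentum
tolerance $10^{-6}$), pathline counts of 48–128, and a three-resolution
refinement study on a reduced cone–throat–expansion geometry. At these
sizes the mass-conservation error of the nozzle run is at the few-percent
level and decreases monotonically under refinement; reaching the
half-percent regime requires the production-scale resolution (hours of CPU
time), which is why the mass-quality acceptance check reports the
scaled-down value it actually measures. Steady-state tolerances, seed
counts and grid sizes are fixed in the test files; none of them are
derived from, or tuned to, any particular expected number.

## Known limitations

* Staircase walls limit near-wall accuracy to first order locally; WSS and
  cone-region mass errors inherit that rate (volume-of-fluid sub-cell
  walls would lift it, and are deliberately not implemented).
* The viscous operator is second order; the high interior advection order
  pays off only in advection-dominated regions.
* The Eulerian damage field near walls needs many transit times to
  saturate (slow cells); flow-weighted averages converge much earlier, but
  pointwise near-wall $D_l$ values should not be over-interpreted.
* The Casson cutoff makes low-shear viscosity constant rather than
  yield-stress-rigid: genuinely unsheared plug regions are outside the
  model's validity.
* Axisymmetry suppresses azimuthal jet instabilities; at throat Reynolds
  numbers approaching the transitional regime the 2D steady solution may
  exist numerically while the 3D flow would not be steady.
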
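---
title: "Model description and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Model description and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(erwcycle)
```

`erwcycle` quantifies how permanent carbon dioxide removal (CDR) through
enhanced rock weathering (ERW) really is, once the coupled
atmosphere--ocean--land carbon cycle has had its say.  This vignette is the
package's own account of the science it implements: the model equations and
their assumptions, the parameters that matter, what the synthetic pieces do
and do not emulate, and the numerical and design choices that were genuinely
open.

## The question

When carbon is removed from the atmosphere — whether by hypothetical direct
air capture ("baseline" / modulated-emissions intervention) or by dissolving
crushed rock so that CO2 ends up as bicarbonate delivered to the ocean (ERW)
— the rest of the carbon cycle pushes back.  Ocean and land reservoirs that
had been absorbing anthropogenic carbon re-release part of it when the
atmospheric burden falls.  The package separates two different flows:

* the **baseline backflux** `p_base`: the percentage of deployed
  removal/mitigation counteracted by legacy-carbon release from ocean and
  land, present for *any* intervention, and
* the **ERW leakage** `p_leak = p_ERW - p_base`: the *additional* return
  flow in an ERW deployment — carbon that was captured into seawater
  bicarbonate and then degassed back out.

Both derive from the time-integrated net impact ratio
$$\eta_i(t) = \frac{\int_{2030}^{t} \big[J_{\mathrm{CDR},i}
  - (J_{\mathrm{sea\text{-}air}}^{\mathrm{exp},i} -
     J_{\mathrm{sea\text{-}air}}^{\mathrm{ctrl}})
  - (J_{\mathrm{lnd\text{-}air}}^{\mathrm{exp},i} -
     J_{\mathrm{lnd\text{-}air}}^{\mathrm{ctrl}})\big]\,dt'}
  {\int_{2030}^{t} J_{\mathrm{CDR},i}\,dt'},
  \qquad p_i = (1-\eta_i)\cdot 100\%,$$
with all fluxes positive into the atmosphere and the control run sharing the
experiment's scenario and ensemble member.  `eta()`, `backflux()`, and
`p_leak()` implement exactly these definitions with trapezoidal integration
on annual-mean flux series, the lower bound fixed at the deployment start
year; "end of the century" means integrated through 2100 inclusive.

## Model structure

### Seawater carbonate chemistry

`solve_speciation()` closes the seawater CO2 system from dissolved inorganic
carbon (DIC) and total alkalinity.  The alkalinity balance includes
carbonate, borate, and water contributions; phosphate and silicate
alkalinity are omitted (sub-1% at these scales, and the box model carries a
generic nutrient rather than speciated phosphate).  Constants: K0 from
Weiss (1974); K1/K2 from Lueker et al. (2000) on the total pH scale
(Roy et al. 1993 selectable via `formulation`); KB Dickson (1990); Kw from
the DOE handbook; calcite/aragonite solubility from Mucci (1983); pressure
corrections from Millero (1995).  Total boron is salinity-proportional and
calcium is conservative, `Ca = 0.01028 S / 35` mol/kg.  The pH root is
bracketed on total-scale pH in [2, 12] and bisected to 1e-8 pH, then Newton
polished — robustness over speed, with a warm-started Newton fast path used
inside the integrator.  The exact agreement of a solved state's implied
alkalinity with its input (to ~1e-12 relative) is asserted in the tests.

### The four-box ocean

The ocean is the smallest structure that separates the two competing fates
of ERW-delivered carbon: re-equilibration with the atmosphere in the mixed
layer versus export to the interior before equilibration.  Boxes: a
low-latitude surface box (85% of ocean area, 100 m), a high-latitude surface
box (15%, 250 m; the deep-water formation site), an intermediate box, and a
deep box; volumes total 1.33e18 m3.  Transport combines a 24 Sv overturning
cell (high-lat sinking, deep-to-intermediate upwelling, return through the
low-latitude surface) with bidirectional mixing: 45 Sv low-lat/intermediate,
60 Sv intermediate/deep, and 160 Sv high-lat/deep.

These rates and the piston velocity (1500 m/yr) were calibrated once,
against two constraints: the control run's cumulative historical ocean
uptake should be roughly 30% of diagnosed emissions, and anthropogenic
carbon should enter the interior predominantly through the high-latitude
pathway, as it does in the real ocean.  The split matters: a configuration
that achieves the same uptake through vigorous low-latitude exchange
flushes river-delivered alkalinity out of the surface almost immediately,
which suppresses both the ERW leakage (the excess DIC never equilibrates)
and the surface-chemistry co-benefit.  With the high-latitude-weighted
split, the low-latitude surface residence time is ~15 years against a
mixed-layer CO2 equilibration time of ~2 years, so delivered carbon largely
(but not completely) equilibrates before subduction.

The biological pump takes up surface nutrient first-order (2 y low-lat,
10 y high-lat — the slow high-latitude uptake emulates incomplete
utilization), exports organic carbon at C:P = 106, and CaCO3 at a rain
ratio of 0.08; remineralization returns everything to the interior boxes.
CaCO3 burial is closed first-order on the deep-box calcite saturation:
`burial = b0 max(Omega_cal - 1, 0)` with `b0 = 4e13` mol/yr per unit
saturation excess, giving a preindustrial burial (and hence imposed
weathering) flux of ~0.2 GtC/yr.  Weathering delivers 1 DIC + 2 ALK per mol
buried to the surface, so the open-system preindustrial state is exactly
steady.  The deep Omega responds to transient alkalinity perturbations
(carbonate compensation), though on these run lengths its effect on the
headline diagnostics is small.

### Climate

A two-layer energy balance: mixed-layer and deep-ocean temperature
anomalies driven by logarithmic CO2 forcing (F2x = 3.71 W m-2) plus
simplified square-root CH4/N2O terms, feedback parameter set for a 3.0 K
equilibrium climate sensitivity, heat capacities 7.3 and 106 W yr m-2 K-1,
exchange coefficient 0.7 W m-2 K-1.  The land anomaly driving the biosphere
is 1.4x the global anomaly (the configurable land amplification).  Surface
ocean boxes warm with 0.8x the global anomaly; interior box temperatures
are held fixed — interior warming is slow relative to the experiment
horizon, and its main neglected effect (solubility loss at depth) is
second-order for flux *differences* between paired runs.

### The slab biosphere

Vegetation `V` and soil `S` are global pools:
`dV/dt = N - L`, `dS/dt = L - R`, with
`N = N0 (1 + B ln(C/C0))` (NPP responding to atmospheric pCO2),
`L = V / (Lambda_veg V + Lambda_0)` (litterfall on a biomass-dependent
turnover time), and `R = Gamma S Q10^((T - T0)/10)` (soil respiration).
The closed forms `V* = N0 Lambda_0 / (1 - N0 Lambda_veg)` and
`S* = N0 / Gamma` at the reference climate initialize every run and anchor
the property tests.  The reference values `C0 = 278` ppm and
`T0 = 8` degC (preindustrial land temperature) are assumptions — the source
material does not pin them — and are configurable per member.

RK4 at the package time step integrates the pools; `dt = 0.1` y is far
below the fastest admissible pool timescale (2 y).  Pathological parameter
corners (negative NPP at very low pCO2, pools driven negative) are clipped
with a warning; carbon accounting stays exact because the land-air flux is
computed from the realized pool change.

### Ensemble construction and filtering

Parameter uncertainty is handled by a stochastic ensemble: uniform priors
spanning the literature generously (N0 20-100 GtC/y, B 0.1-1.2, Lambda_veg
0-0.009 y/GtC, Lambda_0 2-40 y, Gamma 0.01-0.1 /y, Q10 1.2-4), filtered in
two stages.  Stage 1 runs the stand-alone slab under prescribed
concentration/temperature forcing and keeps members whose modern
(year-2015) soil stock lies in 1200-2000 GtC, NPP in 45-65 GtC/y, and
vegetation turnover in 8-25 y, and whose century responses (2015-2100
changes) lie within Delta V in [-60, 240] GtC and Delta S in [-150, 120]
GtC under both the mid- and high-emission scenarios — envelopes chosen to
bracket the spread of CMIP-class projections.  Acceptance is of order 1e-3,
comparable to the reference pipeline's.  The windows carry the constraint
deliberately: the dynamic envelopes cap the effective CO2-fertilization and
soil-warming responses, which are the dominant land control on `p_base`.

Stage 2 re-runs candidates fully coupled to the box model and re-applies
the same windows to the coupled trajectories.  In this reduced model the
control runs are concentration-prescribed, so the coupled stage sees the
same CO2 trajectory as the offline stage and its main effect is to verify
the member under the integrator actually used for the experiments; in the
reference 3D pipeline the coupled stage is more selective.

### Scenarios, inversion, and interventions

Three idealized concentration pathways ("low", "mid", "high") are
synthesized by monotone cubic interpolation through shipped anchor points
emulating the canonical strong-mitigation / stabilization / high-emission
shapes (CO2 peaking near 450 ppm then declining to 420; stabilizing near
540; reaching ~940 by 2100 and ~1960 by 2250).  Real concentration tables
can be supplied as CSV.  For each scenario and member, the model first runs
1765-2100 with CO2 prescribed, diagnosing the implied emission each year;
all experiments are then emission-driven from the 2030 branch state with
the diagnosed trajectory, which reproduces the prescribed CO2 to well below
1 ppm (asserted in tests).

Interventions start in 2030 at 10 GtCO2/yr by default (0.5-40 supported).
Baseline mode subtracts the rate from the control emissions.  ERW mode
removes the rate from the atmosphere and delivers DIC and alkalinity to the
low-latitude surface box at the feedstock stoichiometry: per mol CO2
captured, silicate delivers 1 mol DIC + 1 eq ALK, carbonate 2 + 2 with the
extra mol tagged as rock-derived carbon so the whole-system audit closes.
Feedstock dissolution is instantaneous — transport-path and soil-column
losses are explicitly out of scope.  Delivery routing across surface boxes
is configurable; the default sends everything to the low-latitude box,
which holds the coastal margins in this geometry.

## Numerical choices

* **Time step** 0.1 y throughout (explicit Euler for ocean/climate, RK4 for
  the slab).  The stiffest process, mixed-layer gas exchange, relaxes on
  ~2 y; halving the step to 0.05 y changes the headline backflux metrics by
  ~0.1 percentage point.  The transport stability bound is checked at run
  time and `transport_step()` refuses a step above it.
* **Spinup** replaces the literal two-stage multi-10-ky integration with
  the same fixed point computed faster: stage 1 integrates the closed
  system 8,000 y at dt = 0.5 under fixed preindustrial CO2 and diagnoses
  the burial the sediment closure would produce; stage 2 switches on
  burial + equal weathering, integrates 500 y, then Newton-solves the
  century-map fixed point *at the production time step*.  The result is
  steady to machine precision for the integrator that uses it: diagnosed
  preindustrial emissions are ~1e-9 GtCO2/yr and an unforced 535-year
  control run drifts by ~4e-13 ppm.  A drift audit (< 1e-4 relative per
  century per reservoir) guards the returned state.
* **Conservation** is enforced, not assumed: every run audits
  d(atmosphere + ocean DIC + V + S + cumulative burial) against cumulative
  emissions + weathering + rock-derived ERW carbon and aborts above 1e-6
  relative (observed residuals are ~1e-13).
* **Integration rule** for the diagnostics: trapezoid on annual-mean
  fluxes from the deployment start year.
* **Ties/degenerate inputs**: zero-DIC seawater speciates exactly
  (pH from borate + water); degenerate prior ranges collapse to a point;
  a zero-rate intervention reproduces its control bit-for-bit.

## Problem sizes

The shipped study (`run_erw_study()`, also driven by
`scripts/acceptance.R`) uses a 250,000-draw stage-1 sample, 120 coupled
candidates, and carries 100 filtered members through
3 scenarios x {control, baseline, ERW-silicate, ERW-carbonate}; it
completes in roughly ten minutes on one core.  These sizes are the
package's scaled-down analogue of the reference pipeline's
2e6 / 3,000 / 980; the ensemble-median diagnostics are stable to well
inside their reproduction tolerances at this size (bootstrap medians move
< 0.5 pp).

## What the synthetic pieces do and do not emulate

The pathway generator reproduces the *shapes* of the canonical
concentration pathways from round-number anchors, not their exact tables;
diagnosed emissions therefore resemble, but do not equal, published
inversions.  The slab priors and filter windows stand in for a
supplementary table that is not part of the source text; they were chosen
once from textbook modern values and not adjusted afterward.  Passing
tests therefore demonstrate that the *method* — ensemble filtering,
paired-run differencing, the backflux/leakage algebra — reproduces the
reference behaviour under comparable conditions, not that any individual
member is a calibrated Earth-system state.

## Known limitations

* A 2-surface-box ocean cannot represent coastally concentrated alkalinity
  delivery.  River-mouth grid cells in the reference model carry very
  large local saturation-state anomalies that survive into its global
  surface mean (~20% ERW increase vs control at 2070); diluting the same
  alkalinity into 85% of the ocean surface yields ~10-11% here.  The
  *relative* property — ERW's saturation co-benefit exceeding twice the
  baseline-mitigation effect — is reproduced; the magnitude is
  structurally understated and the corresponding acceptance assertion is
  expected to fail honestly.
* Interior ocean temperatures are fixed; deep solubility feedback on
  multi-century tails is neglected.
* Nutrient alkalinity, isotopes, sea ice, salinity transport, and all
  spatial structure are out of scope by design.
* The coupled ensemble-filter stage is less selective than its 3D
  counterpart because the reduced control runs are concentration-driven
  (see above).
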
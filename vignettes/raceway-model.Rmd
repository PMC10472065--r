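---
title: "Modelling growth, oxygen and management in a trout raceway"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling growth, oxygen and management in a trout raceway}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(racewaysim)
```

`racewaysim` simulates the production phase of a land-based trout farm: a
cohort of rainbow trout growing in a long flow-through raceway, the
dissolved oxygen (DO) they deplete along the streamwise direction, and the
management and control decisions — feeding, stock splitting, oxygen
supply — that keep the system productive and the fish above welfare limits.
This vignette explains the models, the choices behind their parameters, and
what the accompanying tests do and do not demonstrate.

## The growth model

Individual weight follows a net energy budget.  Anabolism is the
assimilated fraction of the *supplied* ration energy, capped by an
allometric maximum ingestion:

$$\frac{dW}{dt} \;=\; \frac{\varepsilon_A\, f_A(T)\,
\min\!\big(I,\; k_I W^{m} f_A(T)\big) \;-\; k_C\, e^{p_k T} W^{n}}
{\varepsilon_W}$$

* $W$ — individual wet weight (g); $I$ — ration energy (kJ/d), the ration
  mass times the feed's gross energy (mass-weighted sum of 23.6 / 39.5 /
  17.2 kJ/g for protein / lipid / carbohydrate).
* $f_A(T)$ — unimodal anabolic temperature response, equal to 1 at the
  optimum (16 °C) and 0 at and above the maximum (25 °C).  Cold water slows
  both ingestion and assimilation; this is what makes metabolic oxygen
  demand fall as winter approaches.
* Catabolism rises exponentially with temperature
  ($p_k = 0.06\,°\mathrm{C}^{-1}$, a Q10 of about 1.8) and allometrically
  with weight ($n = 0.8$).
* $\varepsilon_W = 6$ kJ/g converts the energy balance into weight change.

Respiration is the oxycalorific equivalent (1000/13.6 mg O₂ per kJ) of
catabolised energy plus a specific-dynamic-action surcharge of 15% of the
ration energy; ammonia comes from the protein share of catabolism
(50%, 0.092 g TAN per g protein) and CO₂ from the respired oxygen at a
respiratory quotient of 0.9.

**Parameter provenance.**  The defaults are *sanity-envelope* values chosen
once: they produce growth from fingerling (~80 g) to commercial size
(~350 g) within one season at 8–16 °C and a fed specific respiration of
roughly 300–400 mg O₂ kg⁻¹ h⁻¹, both in the range reported for farmed
rainbow trout.  They are deliberately not presented as a calibration of any
particular site, and every value is overridable through
`bioenergetic_params()` or the configuration file.

**Numerics.**  Integration is one explicit fourth-order Runge–Kutta step
per time step (1 day by default, hourly optional).  The cumulative
assimilated and catabolised energies are integrated with the same
quadrature as the weight, so the balance *weight gain × energy density =
assimilated − catabolised* holds to machine precision — this is asserted as
a test invariant rather than assumed.  Three trajectories (mean, mean ± sd
of the initial weight) provide the customary growth band at minimal cost;
user-supplied daily mortalities are removed before growth each step.
Under prolonged starvation with $n < 1$ the weight reaches zero in finite
time; the integrator halts there and flags the collapse instead of
producing negative weights.

## The oxygen model

Along the streamwise coordinate $x$ the DO concentration obeys

$$\frac{\partial C}{\partial t} = -\frac{Q}{A}\frac{\partial C}{\partial x}
+ k_{rear}\big(C_{sat}(T) - C\big) - \frac{R}{A}\frac{\partial M}{\partial x}$$

with $C$ in mg/L, $Q$ the flow (L/h), $A$ the cross-section (m²), and the
fish appearing as a distributed sink: $R$ is the specific respiration of
the stock (mg O₂ kg⁻¹ h⁻¹, taken from the growth model at the current hour's
temperature) and $\partial M/\partial x$ the biomass per metre of raceway.
A uniform biomass distribution is assumed — how fish actually spread along
a raceway is site-specific and unobserved, so the simplest
mass-conserving choice is used.  The point oxygen source raises the inlet
boundary by $\Delta C = \text{supply} \times \rho \times \text{efficiency} / Q$;
a 2.4 m³/h gas-volume supply at $\rho = 1.429$ kg/m³ and 90% gasification
efficiency into $1.5\times10^6$ L/h adds about 2 mg/L.  The same flow gives
a residence time near one hour for a 200 m × 8 m × 1 m basin, which is why
the model's control and reporting cadence is hourly.

$C_{sat}$ uses the Benson–Krause freshwater formulation (zero salinity,
configurable pressure), the standard for fresh surface waters; the package
cross-checks it against published solubility-table values.

**Numerics.**  The scheme is explicit first-order upwind on a uniform
node-centred grid over $[0, L]$ (101 nodes by default), stable under the
CFL condition $u\,\Delta t/\Delta x \le 1$; the solver substeps each
reporting interval at $0.9$ of the CFL limit.  Upwind is the natural choice
here because the balance has no diffusion term — the raceway is
advection-dominated — and the scheme is positivity-preserving and exactly
conservative in flux form, which the independent mass-balance accountant
(`oxygen_budget()`) verifies on randomised configurations.  Two analytic
steady states serve as oracles: a linear profile (no reaeration, uniform
sink) and an exponential relaxation toward saturation (no biomass).
Concentrations are clipped at zero; clipping is recorded as a dated
*anoxia* event rather than raised as an error, because a management
simulator must keep running through the conditions it is supposed to warn
about.

## Management rules

The utilization factor is biomass density over a 20 kg/m³ baseline
transfer density (common flow-through trout practice, in line with FAO
stocking guidance).  The transfer planner finds the first forecast day of
100% utilization and schedules a transfer of one third of the stock one day
earlier; a delayed variant postpones it by a week.  Transfers move whole
fish: the count scales by $1 - f$ and the weight distribution is unchanged,
so no mass is created or lost (a test invariant).  Intervention proposals
mirror day-to-day farm practice — harvest on weight (yearly cadence),
transfer on density (monthly), feed-type change on weight class (monthly),
next-day feed quantity (daily, from a deliberately illustrative three-class
%BW table), next-hour oxygen supply on DO (hourly) — ordered
irreversible-first when several fire together.

## Control policies

Open-loop supply follows a piecewise-constant schedule; with a constant
2.4 m³/h supply, modest biomass and a near-saturated inlet, the outlet runs
*above* the inlet — the over-supply that motivates closing the loop — and
falls below it after a cutoff.

The two closed-loop policies are solved by model inversion: bisection on
the supply (tolerance 10⁻³ m³/h) against a one-residence-time forward
prediction.  For pure advection–reaction the quasi-steady profile *is* the
trajectory of a water parcel over one residence time, so the analytic
steady-state profile serves as that prediction, making each control step
cheap and exact under slowly varying forcing.  The **green** policy finds
the smallest supply whose predicted outlet matches the inlet; the
**welfare** policy the smallest supply keeping the predicted minimum along
the raceway at or above the threshold (9.5 mg/L default).  Because a
control decision holds for a full interval while water from the previous
one is still in transit, the welfare controller evaluates the requirement
at the interval endpoints and one step back and keeps the largest — without
this, a rising-inlet flank systematically undershoots the floor by the
transport delay.  Residual excursions are bounded by the documented
0.05 mg/L controller tolerance.  The feedback mode is a proportional valve
($\Delta$supply = gain × error, clamped); on the simulated raceway the loop
is stable for gains below $2Q/(\rho\,\text{eff}\times10^6)$ — about
2.3 m³/h per mg/L at the default flow — and the prediction horizon and
hourly recomputation frequency are package choices, not observed practice.

## The synthetic forcing generator

The generator emulates an Alpine stream in summer: temperature is an
annual cosine (mean 13 °C, amplitude 4 °C, peak near day-of-year 200)
plus a diurnal sine (1.5 °C, afternoon peak) plus Gaussian noise
(sd 0.05 °C); inlet DO rides at 98% of the temperature-dependent
saturation with its own diurnal oscillation (0.6 mg/L); flow is constant at
$1.5\times10^6$ L/h.  Starting day-of-year 184 (early July), the seasonal
term makes both temperature and oxygen demand decline toward winter.  The
defaults — including a raceway depth of 1 m, a typical value for
flow-through trout basins and a required input because it is entirely
site-specific — define the study conditions used by the test suite and the
acceptance script.

What the generator does **not** emulate: flow variations from river stage,
sensor dropouts and bias, weather fronts (cloud cover decoupling the
diurnal DO cycle from temperature), photosynthesis/respiration of biofilm
and algae, and any feedback of water quality on fish behaviour.  Passing
tests under this forcing therefore demonstrate internal consistency of the
models and controllers under realistic magnitudes and timescales — not
predictive skill on a particular farm, which would require calibrating the
bioenergetic parameters and $k_{rear}$ against site data.

## Problem sizes and degenerate inputs

The test suite and the acceptance script run desk-scale problems chosen to
exercise every coupling: 30-day horizons at hourly DO resolution with 101
spatial nodes (the scenario engine advances ~75 000 CFL substeps in a few
seconds), 20 randomised 2-day configurations for the mass balance, and
135-day growth runs.  Degenerate inputs are handled explicitly: an empty
raceway is a fixed point of the DO model; a zero-length horizon returns the
initial state; fractions and schedules are validated at construction; CSV
readers interpolate gaps up to 3 steps and reject longer ones by naming the
offending interval.

## Known limitations

* Growth does not feed back on DO: low oxygen does not suppress ingestion.
  The hook exists (the DO field is available to the daily step) but no
  functional form is imposed.
* Single raceway only; basins in series or parallel are out of scope.
* No endogenous mortality, appetite or disease model; mortality is a
  user-supplied input stream.
* The respiration sink uses a uniform biomass profile; schooling near the
  inlet would steepen the upstream DO gradient.
* Open-loop/closed-loop comparisons use the package's default parameters;
  absolute supply volumes should not be read as site predictions.
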
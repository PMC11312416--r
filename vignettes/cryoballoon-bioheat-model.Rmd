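---
title: "Modeling cryoballoon pulmonary-vein ablation with cryopvi"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling cryoballoon pulmonary-vein ablation with cryopvi}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cryopvi)
```

## The problem

Cryoballoon ablation (CBA) treats atrial fibrillation by freezing a
circumferential band of tissue just inside a pulmonary-vein (PV) ostium,
blocking the ectopic electrical triggers that originate there. The operator
inflates a refrigerant-cooled balloon (here a second-generation 23 mm
device), occludes the vein, and runs freeze/thaw cycles while a thermocouple
reports the balloon temperature. The clinically interesting quantity is the
lesion: how deep the destructive cold reaches into the vessel wall and the
surrounding pulmonary tissue, and the cross-sectional area of the frozen
region. Too shallow a lesion fails to isolate the vein; too deep or too cold
a freeze risks collateral injury (notably phrenic-nerve palsy).

`cryopvi` simulates this procedure end to end: it converts per-patient
thermocouple logs into a balloon surface-temperature schedule, integrates
the Pennes bioheat equation over an axisymmetric model of the vein, and
measures the lesion from the computed isotherms.

## Model

### Geometry

The vein is modeled as concentric cylinders of height 60 mm: a blood-filled
lumen (ostium diameters 12-19 mm depending on the vein), a vascular wall
(1.8-2.8 mm), and a surrounding annulus of pulmonary tissue. The inflated
balloon is an ellipsoid of revolution, 23 mm across its equator and 20 mm
pole to pole, centred on the vein axis. Because the balloon is wider than
every ostium, the ellipsoid is clipped by the lumen cylinder: a band of the
balloon surface presses directly against the wall, which is the occlusive
positioning the procedure aims for. For the default right-inferior vein
(lumen radius 6 mm) the contact band's half-height is
$10\sqrt{1-(6/11.5)^2} \approx 8.53$ mm.

Everything is rotationally symmetric, so the package discretizes the
$(r, z)$ half-plane rather than the full 3-D model; nothing in the physics
or the boundary conditions breaks the symmetry. One textual ambiguity in
the source description — whether the vascular wall is the middle or the
outermost cylinder — is resolved in favour of the anatomically ordered
lumen / wall / pulmonary tissue layering; `build_domain(wall_position =
"outer")` restores the literal outermost-wall reading.

The pulmonary-tissue annulus thickness is nowhere stated; the default is
10 mm, chosen so the measurement isotherm never approaches the outer
boundary in any simulated therapy, and it is configurable.

### Bioheat equation

Each material region obeys the Pennes bioheat equation

$$\rho c \frac{\partial T}{\partial t} = \nabla\!\cdot\!(k \nabla T)
  + W_b C_b (T_a - T) + Q_m,$$

with density $\rho$, specific heat $c$ and conductivity $k$ per material
(blood, polyurethane, vascular wall, pulmonary tissue), blood mass
perfusion rate $W_b = 0.012\ \mathrm{s^{-1}} \times 1057\ \mathrm{kg\,m^{-3}}
= 12.684\ \mathrm{kg\,m^{-3}\,s^{-1}}$, blood specific heat
$C_b = 4000\ \mathrm{J\,kg^{-1}\,K^{-1}}$, and arterial temperature $T_a$.
Modeling choices worth stating explicitly:

* **Arterial temperature.** $T_a$ is set to the mean body temperature of
  36.7 °C. The material table's blood reference temperature (310.15 K,
  37.0 °C) is used as the blood's *initial* temperature; the 0.3 K
  difference is inconsequential but the two roles are kept distinct.
* **Metabolic heat.** No value is specified for any tissue, and the balloon
  is inert polyurethane; $Q_m = 0$ everywhere by default and is overridable
  per material (it also serves as the source hook for manufactured-solution
  verification).
* **Perfusion switching.** Blood flow ceases in frozen tissue, so the
  perfusion sink acts only in cells warmer than 0 °C (evaluated at the
  previous timestep). The cutoff is configurable; `-Inf` keeps perfusion on
  everywhere, which the steady-state verification utility assumes.
* **Blood as a solid.** Lumen blood is a conducting material with the blood
  properties plus the perfusion sink; advective flow (the original study's
  separate CFD of blood) is out of scope.
* **No latent heat by default**, matching the sensible-heat-only reference
  model. An apparent-heat-capacity option (`latent_heat_enabled`) smears a
  latent heat of 250 kJ/kg over the -8 to -1 °C band for sensitivity
  studies; enabling it shallows the computed fronts.

### Therapy schedules

A therapy log records, per patient: `TZ` (s, thermocouple at 0 °C), `TI`
(s, -30 °C), `TM` (s, maximum cold = time to isolation), the maximum
freezing temperature, and the total time `TT` (240 s, including the return
to body temperature). The balloon surface temperature is piecewise linear
through (0 s, 36.7 °C), (TZ, 0), (TI, -30), (TM, max), holds at the maximum
cold, and returns linearly to 36.7 °C at `TT`. The logs do not say when
thawing begins; the default holds until `TT - 30` s (configurable
`rewarm_duration`), since `TT` fixes only the endpoint of the rewarm. Two
identical cycles are concatenated (the logs report one milestone set per
patient).

```{r schedule}
log1 <- read_therapy_log(cryopvi_example("table2_therapy_logs.csv"))[[1]]
sch <- build_schedule(log1)
schedule_value(sch, c(0, log1$TZ, log1$TI, log1$TM, 210, 240))
```

### Discretization

The solver is a cell-centred finite-volume scheme on a uniform $(r, z)$
grid (cells $2\pi r_i h^2$ in volume; a planar unit-depth mode exists for
verification problems). Interface conductivities are harmonic means, which
preserve steady flux across the material discontinuities. Time stepping is
backward Euler by default — unconditionally stable, first order, an
M-matrix system so the discrete maximum principle holds — with
Crank–Nicolson optional. The sparse SPD systems are solved with a CHOLMOD
Cholesky factorization whose symbolic analysis is reused across timesteps.

Boundary conditions: the axis is a symmetry line (zero-area face); the
axial ends are insulated; the exterior radial edge is held at the
pulmonary-tissue initial temperature (311 K), 10 mm of insulating tissue
away from the action. The balloon is excluded from the solve and enters as
a boundary: in the default `dirichlet_schedule` mode the schedule value is
imposed *at the balloon surface* via a face-centred ghost value with the
tissue-side conductivity over a half cell. Conducting instead through
polyurethane half-cells (k = 0.02 W/m/K) would interpose a spurious
insulation layer and make the thermocouple-derived surface temperature
unreachable; the schedule is by construction a surface temperature, so the
face-Dirichlet form is the faithful one. The alternative `neumann_flux`
mode applies the device's quoted surface flux magnitude (interpreted as
W/m², its printed unit being ambiguous) over the contact surface and is
opt-in.

Defaults are 0.25 mm cells and dt = 0.25 s, which resolve the thinnest
wall (1.8 mm) by seven cells and the fastest schedule ramp (about 3 °C/s)
comfortably; a full two-cycle patient run is about 17 000 unknowns for
1920 steps and completes in well under a minute on one core. The
verification battery (below) quantifies the discretization error directly.

## Lesion measurement

Temperatures are classified into cryoinjury zones with each boundary
belonging to the colder zone: above freezing; 0 to -15 °C (membrane-
resistant — cells withstand brief freezing); -15 to -20 °C (extracellular
ice, heterogeneous nucleation — initial damage); -20 to -30 °C
(intracellular ice); -30 to -40 °C (vasoconstriction regime); at or below
-40 °C (homogeneous nucleation, irreversible death). The lesion is measured
at the -15 °C isotherm, where extracellular ice begins; the 0 °C contour is
also reported as the conventional display boundary.

`extract_front()` locates threshold crossings by linear interpolation along
radial and axial cell lines, restricted to tissue (wall + pulmonary) cells.
Lesion depth doubles the maximum *normal* penetration of the front beyond
the balloon surface. Over the contact band the outward normal is radial, so
penetration is the radial distance beyond the band, evaluated at front
points within the band's axial extent. This matters: the wall is two orders
of magnitude more conductive than pulmonary tissue and channels cold
axially well beyond the balloon, and a plain nearest-distance measure would
report that axial creep — not tissue penetration — as depth. For an
unclipped balloon (narrower than the lumen) the normal-cone distance to the
ellipsoid surface is used instead.

The cross-section area is the ellipse
$\text{Area} = \pi \cdot (A/2) \cdot (B/2)$ with $A$ the depth and $B$
fixed at the 23 mm balloon diameter (the equatorial cooling band makes
lesions uniformly wide). The library computes with full-precision $\pi$;
printed reference tables evaluate $\pi$ to two decimals and round half-up,
a convention `round_half_up()` reproduces exactly. Cohort dispersion uses
the population (divisor-$n$) standard deviation — the form that reproduces
the reference per-patient tables; the sample form does not.

The front is evaluated at the **end of the final hold at maximum cold**
(450 s with defaults), i.e. the end of the final freeze phase, when the
lesion is at its fullest extent. Evaluating after the final rewarm would
measure a retreating front and systematically underestimate the lesion.

```{r lesion-arith}
depths <- c(4.28, 3.24, 3.00, 3.96, 3.08)
round_half_up(lesion_area(depths, 23, pi_value = 3.14), 2)
pop_mean_sd(depths)
```

## Verification

Four independent checks back the solver, all run in the test suite:

* **Closed-form oracle.** On a quasi-1-D planar domain the steady solver
  matches $T(x) = T_a + (T_s - T_a)e^{-x/\delta}$,
  $\delta = \sqrt{k/(W_b C_b)}$ (5.06 mm for wall properties), to an
  $L_\infty$ relative error of about 0.04% at 0.1 mm cells.
* **Energy conservation.** With perfusion and sources off and the exterior
  insulated, the enthalpy change over a full freeze/thaw equals the
  time-integrated balloon heat rate to machine precision (backward Euler
  is exactly conservative in this finite-volume form).
* **Manufactured solution.** The observed spatial order on a radial
  manufactured solution of the axisymmetric operator is 2.00.
* **Maximum principle.** Every snapshot of every patient run stays within
  the bounds set by the schedule minimum and the warmest initial/boundary
  temperature, and tissue cools monotonically from `TI` through the end of
  each hold. (At the onset of cycle 2 the global tissue minimum briefly
  rises: a remote cold spot left by cycle 1 rewarms while the balloon is
  still ramping back down. That is correct physics, not a scheme artifact —
  the maximum principle bounds the minimum, it does not make it monotone
  through that crossover.)

## What the synthetic generator does and does not emulate

`generate_fixture_logs()` draws milestone times and maximum temperatures
uniformly over the observed clinical ranges (TZ 8–13 s, TI 23–36 s,
TM 32–42 s with TI < TM, max temperature -63 to -41 °C, TT = 240 s),
enforcing the log invariants. It emulates the *schedule envelope* of real
therapies, not their correlations (colder therapies tend to reach
milestones faster in reality) nor device-level variability (thermocouple
lag, refrigerant flow). Tests passing on generated logs therefore validate
schedule handling and solver behaviour across the clinical envelope, not
patient-level predictive accuracy.

## Known limitations

* Blood advection is absent; the perfusion sink is the only blood heat
  transport. Near the balloon poles, where real flow is occluded and
  recirculating, both the sink and a CFD would be crude.
* The occlusive clipped-balloon geometry presses the schedule-temperature
  surface directly against the wall. Simulated depths for the coldest
  therapies (around -60 °C) reach about 5 mm, roughly 0.5–0.7 mm above the
  upper end of the in-vivo reference band — consistent with the reference
  simulations evidently having kept a blood gap between balloon and wall
  (their reported balloon-to-wall distances are about 4 mm), which
  attenuates the cold. The warmer (around -41 °C) therapies land inside
  the band.
* No latent heat by default; enabling the apparent-heat-capacity option
  shallows fronts by roughly the smeared enthalpy and is the first knob to
  try when calibrating against histology.
* The balloon neither deforms nor deflates; vein anatomy is idealized and
  concentric.
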
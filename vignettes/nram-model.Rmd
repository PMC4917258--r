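---
title: "An ionic model of neonatal rat atrial monolayers with constitutively active I_KACh"
author: "nram package"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{An ionic model of neonatal rat atrial monolayers with constitutively active I_KACh}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nram)
```

## The biological problem

Primary cultures of neonatal rat atrial cardiomyocytes (NRAMs) are a standard
substrate for studying atrial-fibrillation-like reentry, because confluent
monolayers of these cells develop a constitutively active (agonist-independent)
acetylcholine-mediated inward-rectifier K+ current, I_KACh-c. This current
shortens the action potential, stabilises spiral-wave reentry, and is the
target of the Kir3.x blocker tertiapin-Q, which terminates reentry by roughly
tripling the action-potential duration (APD). `nram` implements a
Hodgkin-Huxley-type ionic model of the single NRAM and a 2D monodomain
simulator of cultured monolayers, so that pacing, restitution, spiral-wave
initiation (S1-S2 cross-field and burst pacing) and pharmacological block
experiments can be run in silico.

## The membrane model

The membrane potential obeys

$$\frac{dV}{dt} = -\frac{I_{ion} + I_{stim}}{C_m},$$

with the total ionic current a sum of twelve components:

$$I_{ion} = I_{Na} + I_{CaL} + \bar I_{K1} + I_{to} + I_{CaT} + I_{Cab} +
I_{NCX} + I_{NaK} + I_f + I_{Nab} + I_{Ksus} + I_{KACh}.$$

All currents are in pA/pF; with C_m = 1 uF/cm^2, pA/pF and uA/cm^2 coincide
numerically. The individual formulations:

* **I_Na** — three-gate form `G_Na m^3 h j (V - E_Na)`. Steady-state
  activation and (shared) inactivation are Boltzmann curves whose midpoints
  and slopes are exposed as parameters (`V_half_m`, `k_m`, `V_half_h`,
  `k_h`); time constants derive from classical ventricular rate functions
  with a room-temperature slowdown factor (`k_tau_Na`, `k_tau_h`).
* **I_CaL** — Goldman-Hodgkin-Katz (GHK) driving force (Na+/K+ permeability
  neglected) with voltage gates d, f and a Ca-dependent gate fCa
  (`1/(1+([Ca]_i/K_fCa)^2)`). The activation time constant carries a fixed
  +10 ms correction. The GHK bracket has a removable singularity at V = 0
  that is evaluated by its analytic limit whenever |2VF/RT| < 1e-7.
* **I_CaT** — `G_CaT b g (V - E_Ca + 106.5)`; in this atrial model the
  T-type current is the dominant depolarized Ca2+ entry and shapes the
  brief plateau; its inactivation floor `tau_g_min` controls the plateau
  lifetime.
* **I_to** — `G_to r (0.706 s + 0.294 s_slow)(V - E_K)`, with the fixed
  fast/slow weights.
* **I_Ksus** — `0.16 (I_Kur + I_Kr + I_Ks)`: an ultra-rapid component
  (gates ua, ui), a rapid delayed rectifier (gate Xr with instantaneous
  rectification) and a slow delayed rectifier (gates Xs1, Xs2). The slow
  component activates with a long, two-gate delay, so it contributes little
  to a normal (~60 ms) action potential but accumulates during the long
  action potentials seen under I_KACh-c block, acting as a duration-selective
  repolarization reserve.
* **Composite inward rectifier** —
  `0.048925 (K_o/(K_o+210)) (V-E_K-10)/(1+e^{0.041(V-E_K-10)}) + 0.01 (V-E_K)`.
  The prefactor reflects a maximal conductance at 47.5% of the neonatal
  ventricular value, and the +10 mV shift and linear term fold a K+
  leakage conductance into the measured rectifier.
* **I_KACh** (single cell) — dose-dependent:
  `3.5/(1+9.13652/[ACh]^0.477811) (0.04+0.23/(1+e^{(V+102)/10})) (V-E_K-10)`,
  used at a baseline dose of 1 uM; carbachol mode sets a saturating dose.
* **I_KACh-c** (tissue) — constitutively active:
  `0.37488 (0.075+0.35/(1+e^{(V+102)/10})) (V-E_K-10)`, independent of
  agonist. This is the main repolarizing current of the coupled monolayer.
* **I_f** — mixed Na+/K+ hyperpolarization-activated current,
  `G_f y (0.2(V-E_Na) + 0.8(V-E_K))`. Its activation midpoint is placed at
  -90 mV: with the small inward rectifier of these cells, a more positive
  midpoint turns the model into a pacemaker, whereas cultured NRAMs are
  quiescent; at -90 mV the current is present but removing it shifts the
  resting potential by well under 1 mV.
* **Pumps/exchanger/backgrounds** — a saturable Na+/K+ pump, a
  Na+/Ca2+ exchanger with the standard single-energy-barrier form, and
  linear Na+ and Ca2+ background (leak) currents.

Intracellular Na+ and K+ are held constant (pipette values: 8 mM Na+,
140 mM K+; bath 130 mM Na+, 5.4 mM K+, 1.8 mM Ca2+, T = 295 K), so
E_Na = +70.9 mV and E_K = -82.8 mV are fixed.

## Calcium subsystem

The sarcoplasmic reticulum (SR) is split into an uptake compartment (NSR)
and a release compartment (JSR), with the JSR one tenth of the total SR
volume. SERCA uptake uses a bidirectional Hill form; release is a single
average ryanodine receptor (RyR) with four states (rest, open, inactivated,
rest-inactivated) whose opening is regulated by cytosolic Ca and by JSR
content, and whose rates were re-scaled for a common-pool description
(bulk cytosolic Ca rather than a junctional subspace): the trigger is
`ko_Ca ([Ca]_i/K_rel_Ca)^2 / kCaSR`. Cytosolic Ca is buffered by troponin
and calmodulin, JSR Ca by calsequestrin (the calsequestrin capacity is a calibrated, effective value
for this common-pool scheme rather than a measured buffer density).

A deliberate design choice: the state variables are the *conserved totals*
(free + bound) per compartment; free Ca is recovered by inverting the
rapid-buffer equilibria (Newton iteration for the two-buffer cytosol, a
closed-form quadratic for calsequestrin). Fluxes between compartments are
exactly antisymmetric after volume weighting, so with the membrane Ca2+
currents disabled the total cell Ca is conserved to machine precision —
this is tested.

## Numerics

Forward Euler for the membrane potential, Ca totals and RyR states with
dt = 0.02 ms; Rush-Larsen exponential updates for all Hodgkin-Huxley gates
(a pure forward-Euler gate mode is available for comparison; gates are
clamped to [0, 1] in either scheme). The integrator tabulates all purely
voltage-dependent factors (gate steady states, Rush-Larsen factors and the
voltage parts of each current) on a 0.05 mV grid with linear interpolation;
the relative interpolation error is below 1e-6 and halving dt changes APD80
by well under 1%.

In tissue, the monodomain equation

$$\partial_t V = -\frac{I_{ion}+I_{stim}}{C_m} + \nabla\cdot(D\nabla V)$$

is integrated with a centred five-point Laplacian, space step
dx = dy = 0.00625 cm, isotropic D = 0.00012 cm^2/ms and no-flux (Neumann)
boundary conditions implemented by dropping out-of-mask neighbours
(mirror-node treatment); the discrete divergence theorem then guarantees
conservation of the masked voltage sum under pure diffusion, which is
tested to machine precision. dt = 0.02 ms satisfies the diffusion stability
bound dx^2/(4D) = 0.081 ms with a wide margin, and the bound is enforced.

## Stimulus units

Printed stimulus strengths (7 pA for 5 ms in the single cell; 100 pA for
2 ms in tissue) are interpreted through a configurable conversion
capacitance `C_cell` with default 1 pF, i.e. the printed picoampere values
are applied numerically as pA/pF. This is the package's own unit
convention: the whole-cell capacitance used originally for this conversion
is not available, and across a realistic ~20 pF cell a 7 pA, 5 ms pulse
(0.35 pA/pF) would displace the membrane by under 2 mV and could never
trigger an action potential. A separate physical pair (`C_cell_phys` =
20 pF, `V_cyto_pL`) governs the conversion of membrane Ca2+ currents into
concentration fluxes.

## Virtual monolayers

A culture is a 256 x 256 lattice (16 mm square) with a 15.6 mm circular
mask inscribed; outside-mask nodes are inert. A configurable fraction
(default 17%) of in-mask nodes is replaced by passive myofibroblasts
(single RC element: C_fb = 6.3 pF, G_fb = 0.635 nS/pF, E_fb = -49.6 mV,
values from the standard passive-fibroblast formulation), coupled to
neighbouring myocytes with G_gap = 0.5 nS/pF on both sides of each link;
fibroblast nodes do not enter the diffusion operator, and a no-coupling
switch turns them into inexcitable obstacles.

Intercellular variability draws, per myocyte, 19 independent uniform
multipliers in [X1/100, X2/100] — one for each maximal conductance or
Ca-flux rate in `variability_targets()` (the composite rectifier counts
twice: rectifier part and K+ leak part; the NSR-JSR transfer rate is
scaled through its inverse time constant). The published settings are
50-150%, 75-125% and 90-110%. Every random draw consumes an explicit seed
and restores the caller's RNG state, so a seed reproduces a monolayer
bit-identically.

Simulated monolayers are quality-controlled on their 1 Hz APD80 maps:
rejected if the dispersion (max - min over interior myocyte nodes) exceeds
20 ms, or if the map is non-uniform in the sense of contiguous APD domains
with sharp borders (adjacent-node jumps above a threshold, default 5 ms);
a smooth gradient below the dispersion limit passes.

## Parameter provenance and calibration

The printed current equations above (composite rectifier, both I_KACh
forms, the 0.16 I_Ksus scale, the I_to weights, the GHK I_CaL, the
T-type offset 106.5 mV) are implemented exactly as stated. Everything
else — maximal conductances, gate midpoints/slopes and time-constant
scales of the reconstructed source-model currents, and the common-pool
RyR/SERCA rates — was calibrated once, as a package design step, against
the published single-cell and tissue observables: resting potential
-72 mV, AP amplitude 132.7 mV, APD50 27 ms and APD80 58 ms at 1 Hz, mean
cytosolic/NSR/JSR Ca of 0.36/775/715 uM over a 1 Hz cycle, planar CV of
22.2 cm/s at the fixed D, a near-tripling of tissue APD80 under complete
I_KACh-c block, and a minimum 1:1-capture cycle length near 125 ms after
block. The calibrated values are frozen in `cell_params()` and are not
adjusted at run time.

Two calibration outcomes deserve explicit mention:

* **Upstroke velocity vs conduction velocity.** With time constants of the
  classical rate-function form, a planar CV of 22.2 cm/s at
  D = 0.00012 cm^2/ms demands a more excitable Na+ system than a
  dV/dt_max of 114 mV/ms permits: across the reachable frontier,
  configurations matching the published CV show dV/dt_max near
  160-180 mV/ms, and configurations matching dV/dt_max propagate at
  17-19 cm/s. The default parameter set resolves this in favour of CV,
  amplitude, APD and the Ca2+ targets; the model's dV/dt_max therefore
  runs high relative to the experimental 114.8 +/- 24.8 mV/ms and should
  be read accordingly.
* **Repolarization share of I_KACh-c.** Complete block of I_KACh-c in the
  default tissue model prolongs the 1 Hz APD80 from ~65 ms to ~117 ms
  (factor ~1.8) and shifts the minimum 1:1-capture cycle length to
  ~125-130 ms. The experimentally reported prolongation is closer to
  three-fold: reproducing it would require the constitutive current to
  carry an even larger share of the repolarization reserve than the fixed
  printed I-V formulation provides once the remaining currents are
  constrained by the single-cell APD, quiescence and stability of the
  blocked tissue (which still needs a duration-selective backup
  repolarizer — here the slowly activating I_Ks component). The block
  effect in this implementation is therefore qualitatively right and
  quantitatively conservative.
* **Quiescence.** Cultured NRAMs rest near -72 mV without automaticity.
  Because the composite inward rectifier is small, quiescence constrains
  the Na+ window (steepness `k_m`, `k_h`), the funny-current midpoint and
  the background conductances; the default set rests stably for at least
  tens of seconds and fires only when stimulated, which is tested.

## What the synthetic monolayers do and do not emulate

The generator reproduces the geometry (culture disc in a square lattice),
the myofibroblast fraction and the conductance-variability protocol of the
real cultures, under ideal conditions: no fibroblast proliferation or
shape, no anisotropy, no optical-mapping point-spread or noise, and
identical kinetics in every myocyte apart from the 19 multipliers. Passing
tests on these monolayers therefore validates the solver and the model's
collective electrophysiology — conduction, restitution, reentry,
electrotonic APD averaging — not the cell-biological realism of any
specific culture.

## Problem sizes used in the tests

The test-suite and the acceptance script run at desk scale, chosen as the
package's own defaults for routine verification: single-cell runs of a few
seconds; planar-wave strips of 128-256 x 3 nodes; capture scans on a
128 x 3 strip with a 5 ms cycle-length grid; and a 64 x 64 monolayer disc
for the dispersion QC. Full 256 x 256 spiral-wave experiments (S1-S2
initiation, burst-pacing induction, block-mediated termination) use the
same code paths and are exposed through `s1s2_cross_field()`,
`burst_pacing()` and `apply_block()`; they are long-running and are
exercised here on reduced domains.

## Known limitations

* Intracellular Na+ and K+ are fixed; long-time ionic drift is outside the
  model's scope.
* Temperature enters only through fixed rate scalings calibrated at room
  temperature; there is no general Q10 machinery.
* The common-pool RyR trigger uses bulk cytosolic Ca; release gain and
  graded-ness were re-calibrated and should not be compared quantitatively
  with junctional-subspace formulations.
* The upstroke-velocity/CV tension described above.
* Myofibroblasts are passive; active fibroblast variants are not modelled.
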
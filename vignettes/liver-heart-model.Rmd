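---
title: "A closed-loop lumped-parameter model of the liver-heart circulation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A closed-loop lumped-parameter model of the liver-heart circulation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hepacirc)
```

## The model

`hepacirc` simulates the systemic circulation as a closed electrical-analog
network (a 0D, lumped-parameter model): pressures play the role of
voltages, flows of currents, and vascular beds are reduced to
resistance-compliance-resistance (RCR, Windkessel) compartments.  The
model exists to ask one question quantitatively: *how do changes in
hepatic vascular impedance — the signature of acute liver injury — load
the heart?*

### Ventricles

Each ventricle is a time-varying elastance chamber,

$$P(t) = E(t)\,[V(t) - V_0],$$

with a triphasic elastance waveform: a raised-cosine rise from
$E_\mathrm{min}$ to $E_\mathrm{max}$ over $[0, t_\mathrm{max}]$
(contraction), a raised-cosine fall back over the relaxation interval
$t_\mathrm{toRelax}$, and constant $E_\mathrm{min}$ for the rest of the
period $T$ (diastasis).  The waveform is load-independent: it encodes
contractility, which is held fixed across all injury scenarios — the
model isolates purely hemodynamic loading effects from any change in the
myocardium itself.  Defaults: $E_{\mathrm{max},L} = 0.394$,
$E_{\mathrm{max},R} = 0.152$, $E_\mathrm{min} = 9\times10^{-5}$
Pa/mm^3^; $T = 0.684$ s (87.7 bpm), $t_\mathrm{max} = 0.377$ s,
$t_\mathrm{toRelax} = 0.104$ s, $V_0 = 10$ mL.

Reported ventricular volumes (EDV, ESV, and hence LVEF) are *stressed*
volumes, $V - V_0$.  This is the convention under which
$\mathrm{ESV} \approx \mathrm{ESP}/E_\mathrm{max}$ holds, and the only
one consistent with the published operating point this model reproduces
(an ESV near 38 mL at an end-systolic pressure near 112 mmHg with
$E_{\mathrm{max},L} = 0.394$ Pa/mm^3^ is impossible if 10 mL of
unstressed volume is included).  The dynamics are unaffected; only the
reporting convention is fixed by this choice.

### Valves

Valves are smooth diodes: a hyperbolic-tangent resistor in series with an
inertance.  The opening fraction is
$o(\Delta P) = \tfrac12\,[1 + \tanh(\Delta P / s)]$ and the effective
resistance $R/o$, capped at $10^6 R$ when closed.  The transition scale
$s$ is not a physiological constant but a regularization of an ideal
diode; we use $s = 2.7$ Pa (0.02 mmHg).  The choice matters only through
the closure transient: with a much softer transition (e.g. 13.3 Pa) the
brief back-flow at pulmonary-valve closure reaches a few percent of peak
forward flow, while at 2.7 Pa every valve rectifies to better than 1%.
The cycle metrics move by less than 0.2% between those two settings, so
the constant is not a tuning knob for the results.

### The hepatic subsystem and the loop

The liver has a dual blood supply.  The portal vein — fed by the
digestive-organ outflow — carries roughly 75% of hepatic inflow at low
pressure; the hepatic artery, branching from the systemic arterial
node, supplies the remaining ~25% at arterial pressure.  Both converge
in the sinusoids, the liver's capillary bed, and drain through three
hepatic veins into the central venous compartment.

The loop is wired as follows.  The left ventricle ejects through the
aortic valve into a systemic arterial junction feeding three parallel
branches: the hepatic-artery RCR, the digestive-organ RCR and the
other-organ RCR.  Digestive outflow perfuses the portal vein
($R_\mathrm{pv,p}$, $C_\mathrm{pv}$, $R_\mathrm{pv,d}$); portal and
hepatic-arterial blood meet at the sinusoid node ($C_\mathrm{hs}$),
which drains through $R_\mathrm{hs}$ and the three parallel hepatic
veins into the central venous RCR, the right atrium, the right
ventricle, the pulmonary valve, the lung RCR, the left atrium and back
to the mitral valve.  The two purely resistive junctions (arterial,
hepatic-venous confluence) are eliminated algebraically inside the
right-hand side, so volume is conserved to machine precision — a
property the test suite asserts at random states.

Two reconstruction choices deserve emphasis, because the source material
for this network is a schematic, not a netlist:

* **Atria.**  The parameter tables list no atrial parameters, but a pure
  ventricle-RCR loop cannot work: during systole the right ventricle
  ejects a full stroke (~55 mL) toward the left heart while both left
  valves are shut, and the lung compliance (1 mm^3^/Pa = 0.13 mL/mmHg)
  cannot store it.  Without atria the simulated loop settles into a
  nonphysiologic pass-through regime in which mean aortic flow is several
  times the volume swing of the left ventricle.  We therefore add two
  passive compliance reservoirs — a left atrium between the lung distal
  resistance and the mitral valve, a right atrium between the
  central-venous distal resistance and the tricuspid valve.  Their
  compliances ($C_\mathrm{la} = 10$, $C_\mathrm{ra} = 2$ mm^3^/Pa) were
  fixed once by the same calibration principle used for the rest of the
  model — reproduce the healthy aortic operating point (mean flow
  5 L/min, 120/80 mmHg, peak flow 30 L/min, summed as absolute relative
  deviations) — and never revisited.  At these defaults the baseline
  loss is 0.47.
* **Portal pressure site.**  The reported mean portal pressure is read
  at the sinusoid-inlet node, i.e. downstream of the presinusoidal
  resistance $R_\mathrm{pv,d}$.  Clinically this is the quantity the
  wedged hepatic venous pressure approximates, and it is the only
  reading consistent with the published pressure-flow pattern this
  package reproduces (a portal flow of ~0.5 L/min across a twenty-fold
  elevated $R_\mathrm{pv,d}$ alone drops ~40 mmHg, which would place the
  upstream node far above the 20 mmHg portal-hypertension cap).  The
  upstream portal-trunk channel (`P_pv`) is still exported in every
  waveform set.

A third, smaller choice: no separate aortic compliance compartment
exists in the parameter tables, so pulse buffering is provided by the
parallel branch compliances behind their proximal resistances.  The
arterial node is therefore purely resistive and its pressure algebraic.

## Simulation and numerics

`run_simulation()` integrates the 15 coupled ODEs (2 chamber volumes, 4
valve flows, 9 node pressures) with `deSolve::lsoda` on a fixed output
grid (default `dt` = 1 ms, 8000 steps = 8 s ≈ 11.7 cycles).  The valve
transitions make the system intermittently stiff; `lsoda` switches
method automatically and holds local error near `rtol = 1e-8`, well
beyond second-order fixed-step accuracy on this grid.  A compiled C
right-hand side is used by default; a pure-R reference implementation
(`assemble_rhs()`) is exported and the test suite checks both produce
the same trajectory.

Initial conditions are 10 mmHg at every node and 120 mL in each
ventricle, flows zero.  In a closed loop the initial state fixes the
total blood volume (~292 mL stressed, at the defaults), which is then
conserved to rounding; the transient redistribution is discarded by the
periodicity criterion (cycle-averaged aortic flow and pressure changing
by <1% between consecutive cycles — reached within the default horizon
with orders of magnitude to spare).  Metrics are computed on the final
complete cycle.  Because total volume is dynamically meaningful, the
steady cycle is independent of initial conditions only among states of
equal total volume; the test suite verifies exactly that
(volume-redistributed starts agree within 1%), and grid-halving changes
cardiac output by far less than the 0.2% tolerance asserted.

End-systole is detected as the instant, after peak ejection, at which
aortic-valve flow falls below 0.5% of its cycle peak (a valve-closure
proxy); the left-ventricular pressure there is the end-systolic pressure
used in $E_a = \mathrm{ESP}/\mathrm{SV}$.  Stroke work is the shoelace
area of the sampled pressure-volume loop, which the suite checks against
the time integral $-\oint P\,\dot V\,dt$.

## Calibration

`calibrate_model()` reproduces the study's fitting procedure: free
parameters are three peripheral scaling coefficients ($A_1$ on all
distal resistances, $A_2$ on all proximal resistances, $A_3$ on all
compliances — applied to the four RCR compartments and the hepatic
subsystem alike) plus the seven cardiac parameters, each constrained to
its physiological search range; the loss is the sum of the four absolute
relative deviations from the aortic targets; the optimizer is
multi-start Nelder-Mead (default 8 starts, 300 evaluations each,
relative tolerance 1e-4) with out-of-bounds proposals penalized softly
(+1e6) and one restart per start from the incumbent, which guards
against premature simplex collapse.  The result reports whether any
fitted parameter sits within 1% of a bound.  Afterwards
`tune_portal_ratio()` performs the "manual" step of the original
procedure automatically: a geometric bisection on the distal
hepatic-artery resistance until the portal share of hepatic inflow is
75% ± 1%.

The shipped default parameter set is *already calibrated* — its tables
are the healthy baseline — so the package's reproduction runs use it
directly; the calibration machinery is exercised in the test suite
through a parameter-recovery experiment (targets generated by a known
model are recovered to a loss below 0.05 with CO, SBP, DBP within 2%).

## Injury scenarios

Acute liver injury raises intrahepatic microvascular resistance
(sinusoidal endothelial damage, microthrombosis, fibrosis, sinusoidal
compression).  Under the assumption that injury loads the hepatic bed
uniformly, `apply_injury()` multiplies exactly $R_\mathrm{pv,d}$,
$R_\mathrm{ha,d}$ and $R_\mathrm{hs}$ by a common factor;
`run_injury_sweep()` simulates factors 1, 5, 10, 15, 20 (M1-M20), each
from the same initial state so rows are independent, and flags any
scenario whose mean portal pressure reaches 20 mmHg.  The suite asserts
the expected monotone physiology across the sweep: CO, SV, SW, LVEF and
both hepatic inflows fall; portal pressure and $E_a$ rise; the arterial
share of hepatic inflow collapses from ~25% toward ~3%.

## Global sensitivity analysis

`run_sensitivity()` quantifies which hepatic resistance governs cardiac
function.  Four factors — $R_\mathrm{pv,d}$, $R_\mathrm{ha,d}$,
$R_\mathrm{hs}$ and a joint hepatic-vein factor $R_\mathrm{hv}$ — are
scaled on $[0.5, 10]$ times baseline (uniformly in linear space;
log-uniform is available but off by default, since only the interval is
specified, not a measure).  Sampling follows Saltelli's radial design
over a Sobol' low-discrepancy sequence, $N(2K+2)$ model evaluations in
total; first-order indices use the Saltelli (2010) estimator, total-order
indices Jansen's estimator, both averaged over the two radial block
families, with row-bootstrap confidence half-widths.  The Sobol'
sequence itself (Joe-Kuo direction numbers, up to 10 dimensions, seeded
digital shift) is implemented in the package and validated in the test
suite against closed-form indices of benchmark functions: a single
active factor, an additive symmetric function, and the Ishigami function
($a = 7$, $b = 0.1$), whose exact indices follow from
$V_1 = \tfrac12(1 + b\pi^4/5)^2$, $V_2 = a^2/8$,
$V_{13} = 8b^2\pi^8/225$.

First-order estimates converge slowly compared to total-order ones; at
desk scale ($N$ = 128-512) their bootstrap half-widths remain a few
tenths, while total-order indices are stable to a few hundredths.  The
rank structure of the results — which factor dominates which output —
is stable from $N = 128$ up.

## Problem sizes

A full 8 s simulation of the 15-state loop takes on the order of 0.1 s.
The test suite runs the complete M1-M20 sweep, a reduced
parameter-recovery calibration, and a Saltelli experiment at $N = 128$
(1280 evaluations); the reproduction script uses $N = 256$ (2560
evaluations) for the sensitivity indices and the full 8000-step grid
everywhere.

## What the model does and does not capture

The loop reproduces the cycle-to-cycle mechanics of a closed
circulation under hepatic impedance changes: preload loss through
splanchnic pooling, afterload rise, and the redistribution between the
portal and arterial hepatic supplies.  It deliberately omits — and
results must be read accordingly:

* **Regulation.**  No baroreflex, no neurohormonal adaptation and no
  hepatic arterial buffer response; the arterial flow collapse under
  severe injury is therefore an upper bound on what an autoregulated
  liver would show.
* **Atrial contraction and venous tone.**  Atria are passive
  reservoirs.  With every printed venous resistance being small and the
  ventricular diastolic elastance tiny, the venous reservoir drains
  nearly to ventricular diastolic pressure each cycle, which caps the
  mean venous (and hence baseline portal) pressure a few mmHg below the
  published operating point; relative M1-to-M20 changes that hinge on
  that baseline inherit the discrepancy, while injury-dominated levels
  (e.g. severe-injury portal pressure) do not.
* **Valvular disease, pericardium, respiration, 1D/3D wave effects** —
  all out of scope.

## Reproducing the study numbers

`scripts/acceptance.R` recomputes, from the shipped configuration and
nothing else: the M1 and M20 steady-state metrics (two 8000-step
simulations) and the Sobol' indices of CO and MAP (one Saltelli
experiment), and writes them as JSON.  The vignette makes no numeric
claim that those computations and the test suite do not themselves
produce.
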
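---
title: "The four-current simplified action potential model: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The four-current simplified action potential model: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(fourcurrent)
```

## The model

Cardiac myocytes fire action potentials (APs): a fast depolarization of
the transmembrane voltage followed by a plateau and a slow
repolarization. Detailed ionic models track a dozen or more currents
and the intracellular ion concentrations; that realism comes at a heavy
computational and analytical cost. The model implemented here takes the
opposite route: all membrane currents are grouped by *function* into
four components —

* `J_fi`, a fast inward (sodium-like) current that drives the upstroke,
* `J_si`, a slow inward (calcium-like) current that sustains the
  plateau,
* `J_so`, a slow outward (potassium-like) current that repolarizes,
* `J_to`, a fast transient outward current that carves the phase-1
  notch typical of epicardial cells.

The state is the dimensionless voltage `V = (V_mV + 85)/100` plus four
gates: `h` (fast-inward inactivation), `f` (slow-inward inactivation),
and the `r`/`s` pair (transient-outward activation/inactivation). Each
gate relaxes exponentially toward a voltage-dependent steady state with
a voltage-dependent time constant; the steady states and time constants
are step functions (plus two tanh sigmoids in the slow inward current),
which is what makes the model partially tractable analytically. The
voltage obeys the monodomain reaction–diffusion equation

```
dV/dt = div(D grad V) - (J_fi + J_si + J_so + J_to) + J_stim
```

with `D` a scalar (isotropic tissue) or a transversely isotropic tensor
built from a fiber direction. The inclusion of an explicit `J_to` is
what separates this formulation from the classic three-current
(Fenton–Karma) model: it reproduces the epicardial notch and gives a
handle for notch-current diseases (setting `g_to` is a single-knob
knockout).

The five built-in parameter sets (`builtin_params()`) are fits to human
epicardial, endocardial and midmyocardial cell recordings and to the
TNNP (human) and LRd (guinea-pig) ionic models. All share the fixed
thresholds `V_r = 0.6` and `V_to = 0`.

## Conventions the equations leave open

**Heaviside at zero.** The step functions are never defined at their
switching point. We take `heaviside(0) = 1` (right-continuous),
centralized in one helper: this makes the slow-outward saturation
`k_inf` continuous at `V_c`, and is measure-zero everywhere else.

**The role of `V_s`.** The parameter table lists a per-cell-type `V_s`,
but the printed kinetics switch the s gate at `V_c`. Reading `V_s` as
the s-gate switching threshold is the only interpretation in which the
parameter does anything, so it is the default
(`s_gate_threshold = "Vs"`); the literal reading is available as
`s_gate_threshold = "Vc"`. For the LRd set the two readings coincide in
practice (`V_s = 0.6 = V_r`), so none of the headline LRd benchmarks
depend on this choice.

**Stimulus sign.** The transport equation subtracts the stimulus
current; read literally, a positive stimulus would hyperpolarize.
Stimulus amplitudes here are depolarizing magnitudes (added to
`dV/dt`), matching what "threshold stimulation" means physiologically.

**Initial condition.** The analytic resting state
`(V, h, f, r, s) = (0, 1, 1, 0, 1)` is an exact fixed point of the
dynamics and the default start everywhere.

## Numerics

Integration is explicit forward Euler with `dt = 0.01` ms — the
reference scheme for this model family — and uniform node-centered
grids with `dx = 0.02` cm in 1D/2D and `0.025` cm in 3D. The diffusion
operator is flux-form: each interior face carries one flux, added to
one node and subtracted from the other, so the total `sum(V)` is
conserved to round-off under the zero-flux (Neumann) boundaries that we
impose at domain and mask edges (the standard choice for cardiac
monodomain; the boundary condition is not otherwise specified for this
model). Anisotropic tensors use face-averaged coefficients with
mask-aware centered tangential gradients (a 9/19-point stencil).
`simulate_tissue()` refuses time steps above the explicit bound
`dx^2/(2 ndim Dmax)` unless told to warn instead.

The compiled kernels tabulate the only transcendental factor of the
right-hand side (`g_si d_inf(V) f'_inf(V)`, two tanh evaluations) on a
`1e-4`-spaced voltage grid with linear interpolation; the table is
exact at and below `V_c` (so the resting fixed point stays exact) and
agrees with the closed form to ~1e-9 elsewhere. Tests cross-check the
compiled trajectory against a pure-R Euler reference and against an
adaptive-step integration of the same equations (deSolve), which the
`dt = 0.01` trajectory approaches at first order.

Two numerical properties of the reference discretization are worth
knowing. First, a planar wavefront at `dx = 0.02` cm travels ~15%
slower than the mesh-converged speed (57.5 vs ~68 cm/s for the LRd
set), because the upstroke spans only a few nodes; we keep `dx = 0.02`
for all printed comparisons since it is the reference condition, and
verify the continuum `sqrt(D)` scaling on finer grids. Second,
cross-fiber conduction at the published `D_perp = 6.75e-5` cm²/ms has a
space constant below any affordable spacing, so the measured
anisotropy ratio sits slightly above the continuum `sqrt(D_par/D_perp)
= 3.85`.

## Protocols

**Threshold.** The stimulation threshold of a cell is found by
bisection on the amplitude of a 1-ms pulse (excitation = V exceeds 0.8
within 20 ms), to a relative bracket of 1e-3; the standard stimulus
everywhere is 1.5x that threshold.

**APD and restitution.** APD is time above a threshold voltage,
default `V = 0.1` (~-75 mV, ~90% repolarization), with linear
interpolation at the crossings; DI is the gap between a downstroke and
the next upstroke. Dynamic restitution paces each cycle length for 10
pre-beats (the model has no concentration memory, so the transient is
short) and keeps the final beat; cycle lengths that lose 1:1 capture
are reported as dropped. CV is measured between two interior cable
probes from the `V = 0.5` upstroke crossings — the steepest part of the
front, insensitive to the exact level.

**Spiral waves.** Spirals are started by S1–S2 cross-field
stimulation: a plane wave from the left edge, then a quadrant stimulus
timed automatically at the moment the mid-domain node recrosses the APD
threshold in the S1 wake. The tip is the intersection of the `V =
V_iso` contour with the `dV/dt = 0` contour, located per grid cell by
bilinear root finding and linked over time by nearest neighbor (0.5 cm
gate); `V_iso` defaults to half the maximum observed voltage. The
rotation period is the mean inter-activation interval at a probe at
least 2 cm from the tip trajectory. Because the tip meanders, a fixed
probe sees a Doppler-modulated period (~±5 ms over a ~800 ms meander
cycle for the LRd set on a 6 x 6 cm sheet); the default experiment
therefore averages ~30 rotations (3900 ms after S2, first 700 ms
discarded). On the full 10 x 10 cm domain this measurement gives
`T = 101 ms` for the LRd fit; on the 6 x 6 cm domain used in the test
suite, where the wavelength (~6 cm) is comparable to the domain,
boundary interactions raise it to ~104 ms. APD at the spiral rate is
sensitive to the (unreported) threshold convention: at `V = 0.1` the
per-rotation APD is ~78 ms, so the complementary DI (~26 ms) absorbs
both that convention and the scale-down bias. We keep the default
threshold rather than calibrating it against the printed split.

**Pseudo-ECG.** The heart-dipole vector is the volume sum of
`r * div(D grad V)` over tissue voxels (the same conservative operator
as the solver, so the sum of sources vanishes and the result is
independent of the chosen center). Lead signals are projections on unit
vectors; amplitudes are arbitrary under the homogeneous-torso
monodomain approximation, so waveforms are compared after normalizing
the activation peak. The default "lead I" points along -x because the
synthetic geometry's +x axis runs from the left toward the right
ventricle.

## The synthetic ventricle generator

The real ventricular anatomy used for the published 3D comparison is
not distributed, so `synthesize_ventricles()` builds a parametric
stand-in: two nested truncated ellipsoidal shells — a thick-walled left
ventricle and a thin-walled right ventricle displaced toward +x —
truncated at the basal box face, yielding one connected wall with two
closed cavities and a shared septum. Fibers run circumferentially
around the long axis with the published `D_par = 1e-3` and
`D_perp = 6.75e-5` cm²/ms. The endocardial surface is labeled and split
into three regions fired at 0, 5 and 10 ms per beat (basal septal
endocardium, apical septal endocardium plus apical cap, remaining free
walls), emulating the His–Purkinje sequence with the early regions on
the LV-facing septal surface so the septum depolarizes left-to-right.
The default box (64 x 56 x 56 voxels at 0.025 cm, ~47k tissue voxels)
is a deliberately coarse, small-heart-scale geometry chosen so a
four-beat paced run completes in minutes; it reproduces the topology
and activation order of a ventricle model, not any measured anatomy,
and transmural cell-type heterogeneity is absent by design — which is
exactly why the simulated T wave is discordant (opposite polarity to
the main activation deflection), as observed for the homogeneous
published comparison.

## Fitting

`fit_ap_model()` estimates parameters from AP templates by bounded
Levenberg–Marquardt least squares (minpack.lm). The residual aligns the
simulated final paced beat to each template at the `V = 0.5` upstroke,
weights the window from upstroke+5 to upstroke+50 ms by 3x (the phase-1
notch region that `J_to` must capture; "slightly larger weight"
quantified once and kept configurable), and optionally appends scaled
CV residuals from short-cable runs. Three numerical choices matter:

* Free parameters are optimized as log-ratios to the start, so they
  stay positive, bounds are multiplicative (default 1/8x to 8x), and
  the finite-difference step is uniform across parameters.
* The discrete trajectory of a step-function model has a staircase
  microstructure at the `dt` scale; machine-epsilon difference steps
  see a flat objective. The default `epsfcn = 1e-4` (1% steps) bridges
  it.
* The switching thresholds (`V_c`, `V_r`, `V_s`, `V_1`, `V_2`, slopes)
  enter discontinuously and are held fixed by default; the default free
  subset is the four conductances plus the gate time constants.

Not everything is identifiable from voltage alone: `tau_r_minus` (the
r-gate closing tail, masked by the already-closed s gate) and, at long
cycle lengths, `tau_h_plus` (excitability recovery) barely move the
trace. Recovery experiments therefore use templates that include a
short cycle length (300 ms) — the same reason the published fits pace
down to 100 ms — and report recovery over the identifiable subset.
Self-fits on model-generated templates are exactly zero-residual by
construction, and multiple jittered starts (deterministic given a
seed) guard against the local minima this objective demonstrably has.

## Problem sizes used by the test suite

The suite favors the reference discretization wherever affordable:
the cable benchmark runs the full 8 cm / 5 beat protocol; the spiral
experiment uses a 6 x 6 cm sheet (scaled down from the published
10 x 10 cm; the full domain reproduces the published period within 1%
but costs several-fold more); the ECG runs four beats on the default
synthetic geometry; convergence checks use short cables and small
sheets. Tests on finer grids (`dx` down to 0.005 cm, `dt` to 0.0025 ms)
verify the discretization-sensitive claims.

## Known limitations

* No intracellular ion concentrations, pumps, or memory: dynamic and
  S1–S2 restitution cannot be fitted simultaneously, and abrupt rate
  changes are outside the model's validity (as for the original).
* The `dx = 0.02` cm reference grid under-resolves the upstroke (CV
  ~15% below mesh-converged), and any affordable grid under-resolves
  cross-fiber conduction at the published `D_perp`.
* One formal invariant fails at a corner: for the endo set with `f = 1`
  just above `V_fi`, the slow inward current slightly exceeds the slow
  outward one (net +1.5e-4 ms^-1); dynamically reachable overshoots
  always repolarize, which is what the tests assert.
* The ventricle geometry is synthetic; real anatomies can be supplied
  as voxel masks + fiber fields via `voxel_grid()` /
  `read_geometry()`.
* Lead amplitudes (and hence absolute ECG voltages) are arbitrary;
  only waveform morphology is meaningful.
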
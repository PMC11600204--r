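---
title: "Two-probe micromanipulation of muscle microtissues: models, measurement and screening"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Two-probe micromanipulation of muscle microtissues}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(microDMA)
```

## What this package models

Fiber-shaped skeletal-muscle microtissues (microphysiological models) are
suspended between two glass probes: a motorized *moving probe* stretches
the fiber along its axis while the bending of a compliant *sensing probe*,
read by a top-view camera, reports the axial force. Capillary adhesion of
a liquid bridge (about 120 µN) holds the fiber without clamps, which is
also the hard force budget of every protocol. From cyclic stretching one
extracts the complex modulus `E*` and loss factor `tanδ` at the cell
mechanosensing frequency of 0.1 Hz; from slow ramps with and without
electrical stimulation one extracts the optimal length `L_o` and the
contractile force (CF). Three criteria — CF generation, `tanδ < 0.4`
measured in solution, and a modulus increase `ΔE* > 5 kPa` across a
degradation or differentiation step — screen large grids of culture and
bioink conditions.

`microDMA` implements the full measurement and screening pipeline and a
physics-based synthetic bench that stands in for the instrument and the
biology, so every stage can be validated against closed-form oracles.

## Force sensing

The sensing probe is a hollow quartz cantilever (outer diameter 0.3 mm,
inner 0.1 mm), clamped at its base; the fiber rests at distance $l$ from
the clamp and the camera tracks the tip at $L_p$. Small-deflection
Euler–Bernoulli theory gives the cross-section inertia
$I_z = \pi/64\,(D_p^4 - d_p^4)$ and the tip stiffness

$$k = \frac{6 E I_z}{l^2 (3 L_p - l)},$$

so the tip deflection $x$ converts to force as $F_s = k x$. The readout
is pixel-quantized: $F_s$ is an integral multiple of
$k \times \text{pixel size}$. Two presets ship with the package: a
`"short"` probe at ≈0.88 µN/px used for viscoelasticity (and combined
measurements), and a `"long"` probe of twice the length at ≈0.11 µN/px
for sensitive contractile work — tip stiffness scales with the inverse
cube of length at fixed $l/L_p$, hence the exact factor of 8. The probe
length, mount position (50/45 mm for the short preset) and the 1.1 µm
pixel are declared fixture values chosen to reproduce those two
resolutions; only the tube diameters and the quartz modulus (72 GPa, a
standard literature value) are instrument constants. Large-deflection
beam theory is out of scope: deflections stay below 1% of the probe
length, where the closed form agrees with numerical beam integration to
better than 0.1% (tested).

Quantization convention: the recorded pixel count is
`floor(|x|/pixel)` with the sign of `x`. The control loop uses the
sub-pixel deflection estimate (corner detection localizes the tip edge to
a fraction of a pixel before rounding); archived recordings quantize.

## The constitutive model and its parameters

A fiber is a three-parameter Zener solid plus an additive Newtonian
drag term:

* `equilibrium_modulus` $E_e$ (Pa) — long-time elastic modulus;
* `arm_modulus` $E_1$, `arm_viscosity` $\eta_1$ — a Maxwell arm with
  relaxation time $\tau_1 = \eta_1/E_1$;
* `drag_coefficient` $\gamma$ (Pa·s) — the viscous friction between the
  porous microfiber and the surrounding solution, lumped as an
  equivalent bulk viscosity. It acts **only in solution**; in air it is
  zero. This single term carries the central phenomenon: hydrogel
  fibers that read `tanδ ≈ 0.1–0.2` in air read `0.5–0.9` in solution,
  while cellular bundles (whose water is cell-internal) are unaffected,
  which is what makes `tanδ < 0.4` in solution a purity criterion for
  gel-free tissue.

Storage and loss at angular frequency $\omega$ are
$E' = E_e + E_1 (\omega\tau_1)^2/(1+(\omega\tau_1)^2)$ and
$E'' = E_1 \omega\tau_1/(1+(\omega\tau_1)^2) + \omega\gamma_\mathrm{med}$,
with $|E^*| = \sqrt{E'^2 + E''^2}$ and $\tan\delta = E''/E'$
(`complex_modulus()`, the analytic oracle for the whole measurement
pipeline).

Nonlinearity and activity enter through a passive stiffening stress
$E_e c_p (e^{c_p \varepsilon} - 1)$ and a Gaussian active force–length
relation $a F_a \exp[-((\varepsilon - \lambda_{opt})/w)^2]$ with
activation $a \in [0,1]$. Defaults $\lambda_{opt} = 5\%$ and $w = 3\%$
place the optimal length inside the observed 4–7% window; the shape is a
modeling choice (only the window and the force loss at high strain are
constrained by observation). Electrical pulses launch α-function twitch
kernels $(t/\tau) e^{1-t/\tau}$ with $\tau = 0.15$ s and single-twitch
peak 0.6; at 5 Hz the kernels overlap into a saturated tetanic plateau,
at 1 Hz twitches stay separate.

`params_from_targets()` inverts the linear model: given a target
$(|E^*|, \tan\delta)$ at 0.1 Hz it returns parameters that land exactly
on the targets. Gel-like samples use a *balanced* arm (equal storage and
loss shares, 15% of storage, relaxing at the analysis frequency).
Cell-dominated samples use a *glassy* arm carrying 70% of the dynamic
storage: engineered tissue is much stiffer under 0.1 Hz oscillation than
under a quasi-static ramp, and this split lets a myobundle read ~8 kPa
in DMA while its slow-ramp passive tension stays at the few-µN level
observed in force–length sweeps. This is the one place where the model
structure was genuinely open; the choice is validated by the pipeline
recovering both the DMA targets and the active parameters.

## The synthetic bench

`run_oscillation()`, `run_length_sweep()` and `run_stimulation()`
integrate the quasi-static force balance: at each step the fiber stress
at strain $\varepsilon = (L_m - x)/L_0$ must equal the probe force
$k x$. Inertia is neglected (micro-scale masses, ≤1 Hz loading). The
Maxwell arm advances by an exponential integrator (exact for strain
linear within a step), the drag rate uses second-order backward
differentiation, and the scalar balance is solved by damped Newton to a
residual below $10^{-9}$ N (one step suffices for linear plants). The
internal grid subdivides the 5 Hz camera interval so that at least 100
steps cover each load cycle; recordings are then decimated to the camera
rate, Gaussian deflection noise (default 0.3 px) is added, and the
readout is floor-quantized to integer pixels.

The default oscillation protocol is 1 settling + 5 analysis cycles at
0.1 Hz and 10% strain amplitude, preceded by a 5% static pre-strain
ramped in during settling. The pre-strain is standard tensile-DMA
practice — it keeps the liquid-bridge contact loaded in tension over the
whole cycle. It also matters numerically: a lossy fiber's force would
otherwise swing through zero, where the signed-floor quantizer has a
two-pixel dead band that attenuates the measured amplitude by several
percent. Recordings whose instantaneous force exceeds 120 µN abort with
a `fixation_failure` condition, mirroring detachment of the liquid
bridge.

`generate_population()` runs seeded condition grids (sub-seeded per
replicate, bit-reproducible). Three grids ship as presets:

* `gelma12` — 12 combinations of methacryloyl substitution (30/60/90%),
  GelMA concentration (5/8%) and photoinitiator (0.25/0.5 mg/mL).
  After culture the outcome partition is fixed by observation, not
  mechanism: combinations 1, 2, 3, 5, 6 agglomerate into cell spheres
  (non-measurable — there is no fiber to suspend), 4 and 8 form pure
  cellular bundles (no drag, `tanδ` 0.1–0.4), the rest keep gel residue.
* `cocl2_11` / `cocl2_14` — hypoxia dose grids over 0–200 µM. The dose
  maps use four piecewise contraction strengths (full, reduced, weak,
  none), a loss-factor rise crossing 0.4 just above 120 µM, and a
  modulus collapse at 180–200 µM; under the un-optimized 3+3-day
  schedule the contraction criterion already fails above 80 µM. The
  exact dose levels of the 14-level grid are a package choice (every
  named dose appears).
* `bioink54` — alginate (0.5–1.0%) × CaCl₂ (0.5/1/1.5%) × diameter
  (110/200/300 µm). All composites share the same GelMA core, so the
  measured end state has a common dynamic modulus with a small (CV 8%)
  spread — this is what makes the diameter-grouped passive baseline of
  the CF criterion meaningful — while the modulus increase across
  alginate removal is carried by the condition-dependent pre-degradation
  state. Eleven combinations generate CF; two of them (alginate 0.8 /
  CaCl₂ 0.5 / 300 µm and 0.7 / 1 / 300 µm) carry loss factors 0.75 and
  0.718, and only (0.7, 1, 200) and (0.8, 1, 200) also show a >5 kPa
  modulus increase. Five of the eleven CF-positive combinations and the
  final two are fixed by observation; the remaining six are declared.

Replicate scatter is log-normal: CV 15% on moduli and contractile peaks,
CV 10% on loss-factor targets (ratio quantities co-vary in their
numerator and denominator, so they spread less than raw moduli), CV 8%
on the shared-backbone bioink modulus. Calibration keeps pre-culture
cores inside the 0.81–4.23 kPa and 0.45–1.1 in-solution bands with
margin for measurement error, and cellular bundles inside 0.1–0.4.

What the generator does **not** emulate: nonlinear large-amplitude
harmonics beyond the mild stiffening term, hydrogel degradation
kinetics, cell proliferation dynamics, probe resonance, camera
illumination artifacts, or inter-batch drift. Passing tests therefore
demonstrate that the measurement and screening logic is correct for
linear-viscoelastic-plus-active fibers under the stated noise model, not
that real tissue obeys the Zener form.

## Force control

The moving probe is force-controlled so that cyclic loading tracks a
sinusoidal force command (peak 15 µN by default, always below the 120 µN
fixation budget). Control runs at the 5 Hz camera rate. The original
instrument's controller design is not public; the package's controller
is a reconstruction with three layers:

1. **Identification** (`identify_plant()`): least squares for
   `F[k+1] = a F[k] + b ΔL[k]` from a bounded random staircase. For an
   elastic sample the exact fit is the integrator `a = 1` with `b` the
   probe/sample series stiffness; drag inflates `b` with the step-rate
   response and pulls `a` below 1. The structure cannot represent both
   the integrating elastic path and the differentiating drag path at
   once, which caps what per-step model-based feedback can achieve.
2. **Receding-horizon quadratic program** (`mpc_step()`): horizon 10,
   tracking weight 1 per µN², move weight 0.01 per µm² (equal weights in
   natural units would paralyze the actuator — useful moves are tens of
   µm while errors live at the µN scale), hard bound
   $0 \le \hat F \le 120\,\mu N$ so the peak-to-peak force can never
   exceed the liquid-bridge budget, first move rounded to the 0.2 µm
   actuator quantum, zero-move fallback on infeasibility. Solved by the
   unconstrained normal equations with a `pracma::quadprog` fallback
   when a constraint activates.
3. **Per-cycle harmonic adaptation** (inside `run_closed_loop()`): the
   command is a single tone, so the steady-state probe motion is
   parametrized as mean plus one phasor. After each cycle (in ≥2 s
   blocks so viscoelastic transients die out) the measured force and
   displacement phasors give the operating-point gain and a damped
   Newton step (`ilc_gain = 0.8`, blended over half a cycle) moves the
   waveform toward the command. This is the adaptive sinusoidal force
   control used by commercial dynamic mechanical analyzers. Within-cycle
   tracking corrections through the mismatched first-order model
   destabilize slow commands (the real plant integrates moves), so in
   the closed loop the QP acts as the constraint governor around the
   adapted plan while its tracking term is suppressed.

Settling lasts `max(6, 15 f)` cycles (a fixed wall-clock allowance for
the adaptation), after which the waveform is frozen so the analysis
cycles are stationary; commands carry a 5% guard band below the 120 µN
limit to absorb quantization and residual adaptation error. Steady-state
tracking reaches the 15 µN peak within ~2% at 0.01, 0.1 and 1 Hz. The
naive alternative (`run_open_loop()`: displacement sized from the static
gain alone) overshoots on lossy plants, increasingly with frequency —
the motivation for force control.

## Measurement pipeline

`stress_strain()` forms $\sigma_s = 4 F_s/(\pi d_0^2)$ and
$\varepsilon_s = (L_m - x)/L_0$ with $d_0$ the *initial* core diameter
throughout (it is never re-measured). `extract_viscoelasticity()`
projects both series onto the single tone at exactly $f_m$ (not the
nearest FFT grid bin; for integer-period records the two coincide) over
an integer number of periods with the settling cycle dropped and no
window; $E^* = A_\sigma/A_\varepsilon$ and
$\tan\delta = \tan(\phi_\sigma - \phi_\varepsilon)$ with the phase
difference wrapped into $[0, \pi/2)$ — a negative raw difference
(possible under noise for nearly elastic samples) is clamped to zero and
flagged, as is leakage from trimmed partial cycles.
`lissajous_modulus()` takes the final loop's
$(\sigma_{max}-\sigma_{min})/(\varepsilon_{max}-\varepsilon_{min})$,
which equals $|E^*|$ for linear steady states (within 2%, tested).

For contraction, `find_optimal_length()` subtracts the passive ramp from
the stimulated one on a common strain grid (linear interpolation when
grids differ, flagged), smooths the difference over a ~0.5% strain
window, and reports `L_o`, the stimulated force there, and the maximal
passive force. `cf_criterion_value()` then subtracts the mean passive
force of the same-diameter group (a singleton group falls back to the
sample's own passive curve, flagged); contraction is called above a 3 µN
difference.

Numerical accuracy, verified in the test suite: noise-free and
unquantized, the pipeline matches the closed-form oracle within 1% for
`E*` and `tanδ` across the calibrated plant family; at default noise and
quantization the error stays within 5% with negligible mean bias, and
active-parameter recovery ($F_a$, $\lambda_{opt}$) is unbiased within 5%
over seeded replicates.

## Screening

`evaluate_criteria()` aggregates per-sample summaries to per-condition
verdicts: contraction (A) by majority of replicates, purity (B,
`tanδ < 0.4`) by *all* replicates — a single sample above 0.4 demotes
the condition, matching how a 140 µM hypoxia dose was demoted — and
modulus increase (C) on group means of the paired before/after states.
All rules and thresholds are configurable (`criteria_config()`). A
missing pairing makes C *not evaluable*, never failed; sphere-forming
conditions are excluded upstream as non-measurable rather than counted
as failures. `screening_funnel()` filters sequentially (A, then B, then
C); because the criteria are pure predicates the selected set is
order-independent while the staged counts are not. On the synthetic
`bioink54` grid the funnel reproduces 54 → 11 → 9 → 2 with the two
expected survivors. `dose_threshold()` implements the monotone-prefix
rule — the largest dose below which everything passes — flagging
non-monotone patterns and the nothing-passes case.

Two worked reference tables ship with the package:
`bioink_cf_survivors_reference()` (the eleven CF-positive combinations
with their loss factors; the two printed exclusions carry 0.75 and
0.718, the nine survivors carry representative sub-0.4 values) and
`cocl2_reference_outcomes()` (per-dose criterion outcomes under the
optimized and the standard culture schedule). They drive the screening
worked examples independently of the simulator.

## Imaging stage

`render_probe_frame()` draws the probe silhouette with anti-aliased
sub-pixel tip placement plus seeded Gaussian noise; `detect_tip()` finds
the strongest Harris corner (hand-rolled structure tensor with separable
Gaussian windowing) in a band around the reference row, refines the tip
edge by an unclipped coverage integral over a ±10 px window around the
corner (unclipped so zero-mean noise cancels instead of being
rectified), and rounds to integer pixels — the same "integral multiple
of a pixel" the force readout uses. Round-trips are exact at zero noise
for integer shifts up to ±20 px and within 1 px at 10%-of-contrast
noise. Only bending-plane displacement is tracked; probe-camera
coplanarity is assumed perfect.

## Reproducibility and problem sizes

Every stochastic stage takes a seed; populations derive per-replicate
sub-seeds from it, and a run is reproducible from its JSON configuration
alone (`read_run_config()`, `run_pipeline()`). The default study sizes
used in the examples and checks are those of the screening designs: 96
pre-culture cores (12 × 8), 8–16 replicates per hypoxia dose, and 54 × 8
= 432 bioink samples; oscillation records are 6 cycles of 0.1 Hz at 5 Hz
sampling (301 samples), sweeps 500–750 samples. A full 432-sample
simulate-and-analyze pass takes a few seconds on one core.

## Known limitations

* The drag term is a lumped equivalent viscosity, not a boundary-layer
  model; only its sign and medium-dependence are observationally
  constrained.
* The first-order control model cannot represent the drag feedthrough;
  tracking therefore relies on the periodic-command adaptation and is
  not expected to track arbitrary (non-periodic) force commands
  accurately.
* `tanδ` extraction assumes the linear regime; the mild passive
  stiffening used in condition maps shifts measured storage by ~2%,
  which the calibration absorbs.
* The condition maps are phenomenological lookup calibrations, not
  mechanistic biology; they reproduce reported outcome patterns, and
  numbers not reported anywhere (e.g. which six further bioink
  combinations contract) are declared choices.
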
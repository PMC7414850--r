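---
title: "Modelling and quantifying chloride homeostasis in the superficial dorsal horn"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling and quantifying chloride homeostasis in the superficial dorsal horn}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sdhcl)
```

## The problem

Fast synaptic inhibition through GABA~A~ and glycine receptors is carried
mainly by chloride, so its strength hinges on the transmembrane Cl^-^
gradient, which mature neurons maintain with the K^+^–Cl^-^ co-transporter
KCC2. In the superficial dorsal horn (SDH) of the spinal cord, lamina I
(the nociceptive projection layer) and lamina II (an interneuron layer)
differ in KCC2 expression, and therefore in how well they defend
intracellular chloride when it is loaded — by a recording pipette, by
sustained GABA~A~ activation, or by intense synaptic drive. Under low load
the difference is invisible; under load it surfaces as a more depolarized
GABA~A~ reversal potential (E~GABA~), collapsing inhibition in lamina I.

`sdhcl` implements, as reusable and tested code, the computational chain
used to study this system: the ionic biophysics (module `ionlib`), a
dynamic single-compartment neuron (`pointsim`), a reduced diffusion model
of the pipette-imposed chloride load (`spatialsim`), the
electrophysiological and imaging analysis operators (`ephys`, `imaging`),
and seeded generators of synthetic inputs for every one of them
(`synthdata`).

## Ionic primitives

All reversal potentials use RT/F at the recording temperature (25.693 mV
at 25 °C). The GABA~A~ reversal combines Cl^-^ and HCO~3~^-^ with a
permeability ratio of 0.25:

$$E_{GABA} = \frac{RT}{F}\,
\ln\!\frac{[\mathrm{Cl}]_i + 0.25\,[\mathrm{HCO_3}]_i}
          {[\mathrm{Cl}]_o + 0.25\,[\mathrm{HCO_3}]_o}$$

Two condition presets ship with the package. `"recording_acsf"` carries
the recording solutions: extracellular Cl^-^ is computed from the ACSF
recipe (126 NaCl + 2.5 KCl + 2 MgCl~2~ + 2 CaCl~2~ = 136.5 mM) with
HCO~3~^-^ 26/16 mM; with a 29 mM pipette load it gives
E~GABA~ = `r round(gaba_reversal(ion_preset("recording_acsf")), 1)` mV,
and with 9 mM, `r round(gaba_reversal(ion_preset("recording_acsf", cl_in = 9)), 1)` mV.
`"point_model"` carries the dynamic-model conditions (Cl^-^~o~ 120 mM,
HCO~3~^-^ 15/30 mM). The two HCO~3~^-^ sets are used as given by their
respective protocols and are not reconciled. `cl_from_reversal()` is the
exact algebraic inverse of `gaba_reversal()` and converts measured
E~GABA~ to intracellular chloride.

Anion fluxes use the Goldman–Hodgkin–Katz current equation. The sign
convention, fixed once and enforced by tests, is **positive = anion
influx** (which, for an anion, is also conventional outward current), so a
positive Cl^-^ current raises [Cl^-^]~i~. The removable singularity at
V~m~ = 0 is replaced by its first-order series inside |V| < 2.6 nV so
integrators never see a discontinuity.

KCC2 extrusion follows a saturating law,
$J = V_{max}\, x/(1+x)$ with $x = ([\mathrm{Cl}]_i - [\mathrm{K}]_o)/12$:
extrusion is null at 3 mM (resting K^+^~o~) and half-maximal at 15 mM.
Reverse transport is clamped to zero when $x \le 0$ — the law is an
extrusion model and its validity does not extend to reverse mode.

## The single-compartment dynamic model

`pointsim` integrates, with forward Euler at dt = 0.1 ms (configurable;
halving dt moves steady chloride by far less than 1%), the coupled
dynamics of

* membrane potential V: leak, Morris–Lecar Na^+^ and K^+^ currents,
  ohmic excitatory synaptic current, and the GHK Cl^-^/HCO~3~^-^ GABA
  currents;
* the Morris–Lecar K^+^ gate W;
* [Cl^-^]~i~: GABA-carried influx minus KCC2 extrusion scaled by the
  surface-to-volume ratio;
* [K^+^]~o~ in an extracellular space of one fifth the cell volume: leak
  and voltage-gated K^+^ currents, a constant Na/K-pump import, the K^+^
  leg of KCC2, and first-order clearance to 3 mM with τ = 200 ms.

Synaptic drive arrives as Poisson trains of unitary conductances (1 nS
inhibitory, τ 25 ms; 0.5 nS excitatory, τ 15 ms) with instantaneous rise
and the discrete Euler decay `g (1 - dt/τ)` exactly as the model was
originally specified — not the exact exponential, so trajectories are
reproducible against that reference step for step. Inhibitory conductance
is converted to a GHK permeability by matching currents at the test point
V = −60 mV, [Cl^-^]~i~ = 5 mM; HCO~3~^-^ permeability is a quarter of
that.

Choices the equations leave open, and how they were fixed:

* **Membrane capacitance** is not part of the published parameter set; we
  use 0.01 pF/µm² (1 µF/cm²) times the cell surface (~21 pF for the
  lamina-I geometry).
* **E~Na~** defaults to +60 mV, configurable.
* **K^+^-gate orientation.** The published activation midpoint slope
  (V~4~ = −30 mV) would make the K^+^ gate close with depolarization. The
  default uses |V~4~|, giving the canonical monotone-increasing
  activation; `spiking_params(as_printed = TRUE)` restores the literal
  form.
* **Gate timescale.** The gating time constant is given dimensionless
  (sech of voltage); it is scaled by `tau_w_scale`, default 25 ms (the
  canonical Morris–Lecar 1/φ with φ = 0.04 ms^-1^). With a 1 ms scale the
  gate tracks the membrane faster than the membrane time constant
  (~12 ms) and regenerative spiking is impossible at any drive; 25 ms
  restores spiking at high excitatory rates while leaving it absent
  without excitation.
* **Pump.** Only the potassium leg of the Na/K pump is specified: a
  constant import of 1.5× the resting leak K^+^ current, entering the
  [K^+^]~o~ balance only (its contribution to V is not specified and is
  left out).
* **Initial conditions**: V at the leak reversal (−65 mV), W at
  equilibrium, [Cl^-^]~i~ 5 mM, [K^+^]~o~ 3 mM.

### The chloride-load scenario

`simulate_gaba_load()` reproduces the sustained GABA~A~ load under
voltage clamp at −70 mV: a constant Cl^-^ permeability is calibrated so
the magnitude of the initial net GABA current equals 10 pA (the sign is
not specified by the source protocol; with the default initial state the
net current is inward, dominated by HCO~3~^-^ efflux, while the Cl^-^
component is several times larger — about 70 pA of influx — which is
exactly the regime of interest, a large accumulating Cl^-^ flux hidden
inside a small net current). Without extrusion, chloride equilibrates
passively: E~Cl~ reaches the clamp within 0.1 mV (the passive oracle,
[Cl^-^]~i~ → 120·e^(−70/25.693)^ ≈ 7.87 mM). Any positive V~max~ keeps
the steady E~Cl~ more negative; blocking extrusion therefore
depolarizes E~Cl~, the furosemide signature. [K^+^]~o~ is held at rest in
this clamped scenario (the K^+^ dynamics belong to the activity model).

### Units, and the extrusion scale

A dimensional audit of the point model is part of the package's account:
with V~max~ in µmol m^-2^ s^-1^ and the laminar geometry
(S/V ≈ 0.85 µm^-1^), maximal extrusion is ~8 mM/s, while Poisson synaptic
drive at a few Hz delivers only ~0.002–0.05 mM/s of Cl^-^ influx. Taken
literally, extrusion wins by orders of magnitude and [Cl^-^]~i~ sits
pinned at the transporter null point regardless of capacity — no
capacity-dependent contrast can appear. The effective capacity that the
original dynamic simulations must have used is not recoverable from the
published units, so the package makes the reconciliation explicit:
`point_params(extrusion_scale = s)` multiplies V~max~ by a dimensionless
scale, and `calibrate_extrusion_scale()` implements the documented
calibration — measure the mean synaptic Cl^-^ influx with [Cl^-^]~i~
pinned at 5.5 mM under baseline 1/1 Hz drive, and choose the scale that
makes extrusion at the reference capacity (10 µmol m^-2^ s^-1^) balance
it there. One scale (~1.8 × 10^-3^) is shared by all capacities, so the
lamina-I : lamina-II capacity ratio is preserved.

With that calibration the model reproduces the qualitative physiology:
steady [Cl^-^]~i~ rises with excitatory rate; the contrast between
capacities 10 and 25 µmol m^-2^ s^-1^ grows when excitation outpaces
inhibition tenfold (the capsaicin-like regime), helped by spiking
depolarization and activity-driven [K^+^]~o~ accumulation throttling
KCC2. Because the calibrated extrusion is weak, chloride relaxes over
hundreds of seconds; comparative runs therefore use 300 s of simulated
time (the shortest horizon at which the steady-state ordering is
established across seeds) and the interlaminar demonstration 900 s, with
averages over the final third. At 900 s under 5/50 Hz drive the
capacity-10 vs capacity-25 cells differ by ~2.2 mM of chloride and
~4.3 mV of E~GABA~ — the concentration contrast reaches the measured
interlaminar range, while the E~GABA~ shift stays short of the 10–15 mV
observed in tissue, a known limitation of the single-compartment
reduction with this calibration.

`simulate_capsaicin_ramp()` drives the same model with rates ramping
linearly (default 1/1 → 5/50 Hz over 2 min), the protocol used to mimic
TRPV1-agonist application; with a zero-amplitude ramp it reduces
bit-exactly to `simulate_activity()`.

## The pipette-load diffusion model

Estimating extrusion capacity from loaded recordings requires a model of
where the pipette's chloride goes. `spatialsim` implements an
axisymmetric one-dimensional finite-volume reduction of that geometry: a
truncated-cone pipette (tip Ø 1.2 µm, back Ø 22 µm, 120 µm long) in
series with the somatic prolate ellipsoid (semi-axes 10.75/5.5 µm for
lamina I, 7.9/4.58 µm for lamina II) sliced along its axis — each slice
carrying its exact surface-band membrane area — and the two dendrites
(Ø 1.5 µm, 80 µm) merged into one equivalent cylinder of doubled section
beyond the distal pole. Chloride diffuses axially
(D = 2.03 × 10^-9^ m² s^-1^) with interface conductances from the
series-resistance formula; KCC2 (fixed-K^+^ form, since the spatial model
does not track K^+^) drains every membrane-bearing element; the pipette
back is held at the load concentration. The steady state solves a mildly
nonlinear tridiagonal system by damped Newton iteration with a
backtracking line search, iterates clamped to the physical band; mass
balance (pipette influx = total extrusion) closes to 10^-3^ relative or
better, and halving the 1 µm grid moves the somatic mean by < 1%.

`fit_vmax()` bisects V~max~ in [0, 200] µmol m^-2^ s^-1^ (tolerance
0.1) until the volume-weighted somatic mean matches a target
concentration, typically obtained from a measured E~GABA~ via
`cl_from_reversal()`.

### What the reduced model reproduces, and where it disagrees

The reduction reproduces the structural findings: a chloride gradient
confined to the last tens of micrometres of the pipette tip (the
fitted-capacity solutions recover to 95% of the load within ~25–40 µm),
insensitivity of the somatic mean to dendrite length beyond 80 µm
(< 1% for a doubling), and a monotone, saturating relation between
capacity and somatic chloride. The pipette's diffusive conductance
(D / ∫dx/A ≈ 350 µm³/s) is independently consistent with the electrical
resistance of such a cone in ACSF (~4 MΩ, matching 5–7 MΩ pipettes).

The absolute fitted capacities, however, come out about 2.5× lower than
the values reported from the original three-dimensional finite-element
fit: ~4 µmol m^-2^ s^-1^ for lamina I (target 20 mM from −45.9 mV) and
~14 for lamina II (target 14 mM from −53.2 mV), versus ~10 and ~25. The
discrepancy follows from mass balance: at a 20 mM somatic mean the
pipette supplies ~350 × 9 ≈ 3200 mM µm³/s, and with uniform KCC2 on the
published soma + dendrite areas a capacity of 10 would extrude more than
twice that. A capacity of ~10 balances the books only if dendritic
extrusion is ineffective and somatic extrusion partially so. We keep the
uniform-membrane model (as the method was described), report the fitted
values it actually produces, and note that the capacity *ratio* between
laminae (~3.4 here vs ~2.5) is much better preserved than the absolute
values — consistent with the reduction mainly rescaling the effective
extrusion area.

## Analysis operators

**E~GABA~ from I–V curves.** Repeats are averaged per voltage, an
ordinary least-squares line is fit, and the x-intercept is corrected for
the liquid junction potential (8 mV high-Cl^-^, 9 mV low-Cl^-^
presets). The estimator is affine-equivariant and, over simulated noisy
curves (σ = 2 pA, 8 voltages × 3 repeats), unbiased to < 0.5 mV with
spread matching the analytic least-squares variance.

**eIPSC trains.** Amplitudes of the 25-pulse 20 Hz train are normalized
to the first pulse and averaged in 3-point windows centred on every 5th
stimulus; the phrasing of the original binning rule is ambiguous, so the
window anchor is configurable and the last window clips to stimuli
{24, 25}. The depression course is fit with a one-phase decay
parameterized with unit value at the first stimulus,
y(n) = plateau + (1 − plateau)·e^(−K(n−1))^. Note that centre-binning
rescales a pure exponential's amplitude by (1 + 2 cosh K)/3 ≈ 1.03, so a
noiseless generated train is recovered to ~2–3%, not exactly; fitting
model-valued bins directly is exact. The chloride-accumulation component
of depression is the difference of end-of-train depression fractions
between holding at 0 mV (Cl^-^ influx dominates) and −90 mV
(Cl^-^-independent). Charge transfer is the trapezoidal integral of
baseline-subtracted current.

**FLIM chloride.** Photon histograms are fit with A·e^(−t/τ)^ convolved
with the instrument response (delta if absent); the amplitude is profiled
out analytically, leaving a one-dimensional minimization, so the fit is
scale-invariant in total counts and needs no starting values. Unweighted
least squares is the default (a Poisson-weighted option exists).
Lifetimes convert to concentration through Stern–Volmer,
[Cl^-^] = (τ~0~/τ − 1)/K~sv~ with K~sv~ = 32 M^-1^; lifetimes above τ~0~
clip to 0 mM with a warning. Depth gradients are quantified by binning
per-cell concentrations every 20 µm of depth and regressing the bin means
on bin centres.

**Laminar quantification.** The IB4 band centre is computed per image
column as an intensity-to-the-4th-power barycentre (the "order 4"
weighting; exponent configurable) — a bright:dim pair at ratio 2 pulls
the centre 16:1 toward the bright blob — columns below 1% of the median
column weight are excluded (the floor is a package choice; the original
rule is silent), and a quadratic row(column) curve is fit through the
centres directly (no pre-smoothing; the original smoothing is
unspecified). Trans-laminar profiles bin each channel's intensity against
the signed minimum distance to that curve, dorsal side positive. The
global membrane index is M = mean(lamina) − mean(intracellular) on
background-subtracted images — invariant to intensity offsets. The
membrane distance profile computes exact point-to-segment distances to
manually traced membrane polylines, signed positive on the intracellular
side, defined as the left of the traversal direction (generated
annotations traverse cell outlines with the interior on the left); both
distance computations are tested bit-exactly against exhaustive
per-pixel oracles.

**Immunogold clustering.** Particles closer than 65 nm link, linkage is
transitive (union-find connected components), particles in components of
size ≥ 2 count as oligomeric, and the percentage counts particles, not
groups. Distances are 2D Euclidean in the section plane. The
implementation is checked against single-linkage hierarchical clustering
cut at the threshold on random fields, and is invariant to particle
order and rigid motions.

## Synthetic data

Every input type has a seeded generator that embeds its ground truth in
the output: linear I–V curves with Gaussian current noise; Poisson-
sampled exponential decays with optional Gaussian IRF; laminar images
with a dorsoventral KCC2 gradient, IB4/CGRP bands along a known quadratic
axis, ring cells and full annotations; mixtures of Gaussian clusters
(spread 15 nm, well under half the 65 nm cutoff) and uniform monomers on
fields sized so chance linkage is negligible; and one-phase-decay eIPSC
trains. The generators emulate the *statistical structure the analyses
assume* — linearity, mono-exponentiality, Gaussian/Poisson noise,
geometric annotations. They do not emulate optical blur, correlated
noise, segmentation error, or biological heterogeneity, so passing
recovery tests demonstrates correctness of the estimators, not robustness
to real-tissue artefacts; annotations (masks, membrane traces) are
treated as inputs, as they were manual in the original workflow.

## Problem sizes and tolerances

The shipped tests run the point model at dt = 0.1 ms for 5–300 s
(drive-contrast runs 300 s × 3 seeds; the 900 s interlaminar
demonstration lives in the acceptance script); the spatial chain at 1 µm
resolution (~220 elements, Newton convergence at 10^-10^ relative
residual, bisection to 0.1 µmol m^-2^ s^-1^); Monte-Carlo recoveries at
200–500 seeds. All stochastic components are reproducible bit-exactly
from their seed arguments.

## Known limitations

* The point model is a single compartment: no dendritic chloride
  gradients, no GABA~B~, no NKCC1, no temperature dependence.
* The literal transport units require the documented extrusion-scale
  calibration before capacity-dependent contrasts appear, and the
  resulting E~GABA~ contrast undershoots tissue measurements.
* The spatial model is a 1D reduction; absolute fitted capacities carry
  the ~2.5× scale noted above, the laminar ratio being the robust
  output.
* Reverse KCC2 transport and electrodiffusive coupling inside the
  cytosol are out of scope.
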
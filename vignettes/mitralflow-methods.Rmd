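---
title: "Transmitral flow energetics: models, numerics and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Transmitral flow energetics: models, numerics and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mitralflow)
```

`mitralflow` analyses transmitral flow the way an in-vitro left-heart
duplicator study would: particle images are turned into planar velocity
fields by PIV, velocity fields into viscous energy dissipation (VED), and
pressure/Doppler recordings into transvalvular gradients and a Gorlin valve
area. Because duplicator recordings are not portable, the package carries a
first-class synthetic-data module that emulates the statistical and
physiological structure those instruments produce. This vignette documents
the models, the tunable parameters, the numerical choices, and what the
synthetic route can and cannot establish about real data.

## The activation waveform and the synthetic jet

Ventricular filling is modelled by a two-lobed activation waveform on the
cycle phase $\varphi \in [0,1)$: a passive-filling (E) lobe and an
atrial-contraction (A) lobe, each a raised cosine
$w(\varphi) = a\,\tfrac12\!\left(1+\cos\frac{2\pi(\varphi-c)}{b}\right)$ on
its support. Raised cosines are smooth, integrable in closed form, and leave
the two timing fractions free. Defaults (`beat_spec()`):

| parameter | default | meaning |
|---|---|---|
| `e_center`, `e_fraction` | 0.55, 0.25 | E lobe centre and width (cycle fractions) |
| `a_center`, `a_fraction` | 1/12, 1/6 | A lobe; occupies exactly the first sixth of the cycle |
| `ea_ratio` | 1.8 | E:A peak amplitude ratio |

The recorded cycle starts just before the A-wave peak, so an early-cycle
VED peak (the "remaining effect of the A-wave", at $T/12 \approx 0.07$ s at
70 bpm) precedes systole, and the E-wave peak lands near $0.55\,T \approx
0.47$ s — matching the default peak-detection windows $[0, 0.15]\,T$ and
$[0.45, 0.65]\,T$ of `detect_peaks()`. Two further considerations fixed the
defaults: the A lobe sits wholly inside the first $1/6$ of the cycle, which
at 70 bpm is exactly the fraction by which one second exceeds one cycle, and
with `ea_ratio` near 1.8 the squared waveform has the same mean over that
window as over the whole cycle — so extending a one-cycle VED recording
periodically to 1 s behaves like scaling by the cycle count, as the TVED
contract assumes. No instrument E/A velocity ratios or diastolic durations
were available to calibrate against; these are physiologically reasonable
placeholders (clinical E/A of a healthy ventricle is roughly 1–2) and are
fully user-configurable.

The transmitral jet itself is a kinematic prescription, not a Navier–Stokes
solution: a downward Gaussian jet
$v(x,y) = -V(t)\exp\!\big(-((x-x_c)/\sigma)^2\big)$ with $\sigma$ half the
`jet_width`. Treating the orifice as an axisymmetric Gaussian of the same
scale gives a volumetric flux $Q(t) = \pi\sigma^2 V(t)$, and the amplitude
is calibrated once per series so that $\int_0^T Q\,dt$ equals the stroke
volume — `integrated_inflow()` verifies the round trip to well under 1 %.
The effective orifice areas default to the Gorlin areas of the two valve
models (normal 2.2 cm², calcified 1.4 cm²), with one physiologic
refinement: a compliant normal valve opens wider under exercise flow
(default 3.0 cm²) while a calcified orifice is flow-independent. This is
what makes the rest→exercise TVED rise structurally larger for the
calcified valve — with a fixed orifice the jet velocity must carry the
whole flow increase, and dissipation grows quadratically with it.

## Synthetic particle images

`render_particle_pair()` seeds `particle_density` tracers per px² uniformly,
renders each as a 2D Gaussian whose $e^{-2}$ intensity diameter equals
`particle_diameter` (standard synthetic-PIV practice), advects them by the
locally interpolated velocity over `frame_interval`, and re-renders.
Particles leaving the frame between exposures are dropped and none are
injected — the simplest consistent contract. Displacements are refused
beyond `max_displacement_px` (default 4 px, one quarter of the 16 px final
interrogation window), naming the offending maximum. One integer seed per
call drives positions and noise through an isolated RNG scope; no global
state is touched.

Coordinates are pinned once and covered by fixture tests: image row 0 is the
top, the physical $y$ axis points up, $x = p_x \cdot \text{mag}$,
$y = (H - p_y)\cdot \text{mag}$, and the velocity converter flips the sign
of the row displacement.

## PIV: multi-pass FFT cross-correlation

`multipass_piv()` runs one pass per entry of `pass_windows` (default 64 then
16 px, 50 % overlap; node count per axis is
$\lfloor (\text{image}-\text{window})/\text{step}\rfloor + 1$ with step
$= \text{window}(1-\text{overlap})$). Each pass:

1. offsets the second frame's window by the integer-rounded predictor
   interpolated from the previous pass (discrete window shifting — image
   deformation is a deliberate non-goal, left as an extension point);
2. mean-subtracts both windows and correlates them by FFT, zero-padded to
   twice the window to suppress circular wrap-around;
3. divides the correlation plane by the per-lag overlap area of the padded
   windows. This matters: the raw zero-padded estimator is biased toward
   small displacements because distant lags accumulate fewer overlapping
   pixels. On uniform-displacement fixtures the normalisation reduced a
   systematic 0.01–0.14 px undershoot (growing with displacement and
   particle diameter) to ~0.002 px;
4. finds the maximum within the half-window search radius and refines it
   per axis with a three-point Gaussian fit,
   $\delta = \frac{\ln c_{-1} - \ln c_{+1}}
   {2(\ln c_{-1} - 2\ln c_0 + \ln c_{+1})}$, falling back to a parabolic
   fit when a neighbour is non-positive;
5. validates with the normalized-median test (threshold 2.0, noise floor
   0.1 px — common literature defaults): a vector is flagged when its
   residual against the 8-neighbour median exceeds the threshold times the
   median neighbour residual, flagged vectors are replaced by the median of
   valid neighbours and stay flagged. Textureless windows and border peaks
   are flagged invalid rather than raising. Masked nodes never enter
   medians or downstream integrals.

At tracer density 0.02 px⁻² with 16 px windows (≈5 particles per window) the
per-vector random error floor is ≈0.06 px. Accuracy fixtures therefore use
prescribed fields whose signal comfortably exceeds that floor while staying
inside the quarter-window rule (e.g. solid rotation with a 1.8 px maximum
displacement); a weaker prescribed signal measures the noise floor, not the
estimator.

## Viscous energy dissipation

`ved_instant()` evaluates
$\Phi = 2\mu(u_x^2 + v_y^2) + \mu(u_y + v_x)^2$, which is the expansion of
the ordered-pair sum $\tfrac{\mu}{2}\sum_{i,j}(\partial_j u_i +
\partial_i u_j)^2$ — the standard planar dissipation function, in W/m per
unit out-of-plane depth (the identity is asserted on random fields in the
tests). Gradients are second-order central differences with one-sided
second-order stencils at boundaries and beside masked/invalid nodes; nodes
with fewer than two usable neighbours along an axis are excluded.

The integral uses tensor-product trapezoidal cell weights (interior nodes a
full `spacing²`, boundary nodes half/quarter cells). A uniform node weight
looks natural but carries an $O(h)$ boundary error that demonstrably stalls
grid convergence; with trapezoidal weights the Lamb–Oseen vortex fixture
converges to the quadrature value of the analytic dissipation density at
observed order ≈ 2.0, and a linear shear field is exact
($\mathrm{VED} = \mu\gamma^2 A$ with $A$ the grid extent) to machine
precision. Rigid motions dissipate nothing and constant-velocity offsets
change nothing (Galilean invariance); both are enforced as properties.

`tved()` integrates the series trapezoidally over $[0, d]$ (default 1 s),
extending the recording periodically by its cycle period where needed —
necessary because one second exceeds both the rest (60/70 s) and exercise
(60/110 s) cycles. `anova_recordings()` treats each replicate recording as
a group of VED samples in a one-way ANOVA (`stats::oneway.test`,
equal-variance form): a small F / large p indicates replicate consistency.
Whether a reported exercise/rest change should be read as
$(\text{ex}-\text{rest})/\text{rest}$ or as a ratio is left to the reader:
`compare_conditions()` reports the percent change and the raw values side
by side, asserting neither.

## Hemodynamics

Diastolic filling windows are the maximal intervals with
$p_{LA} \ge p_{LV}$, with edges refined to the interpolated zero-crossing
of the difference and intervals under 20 ms discarded as crossover chatter.
The catheter mean gradient is the trapezoidal time-average of
$p_{LA}-p_{LV}$ over those windows. The synthetic traces shape the
diastolic difference as half-sine lobes (linear contact at the lobe edges,
so the crossing is sharply defined at 4 ms sampling) normalised to a
time-mean of exactly the configured offset; the round trip recovers
offsets to about 0.6 %.

The Doppler mean gradient follows the clinical convention for an envelope
"integrated in standard fashion": the time-mean of the instantaneous
simplified-Bernoulli gradient $4v^2$ over the flow period — not
$4\bar v^2$. The flow period is the contiguous positive-velocity region
(bounding zero samples included) containing at least one sample above
0.05 m/s; the threshold rejects noise blips while the zero-bounded
extension keeps analytic fixtures exact (a half-sine lobe of peak 1 m/s
yields exactly 2 mmHg, a constant 1 m/s envelope exactly 4 mmHg). The
Bernoulli coefficient is fixed at 4 mmHg·s²/m²; the density difference of
the blood analogue is deliberately ignored, matching clinical practice.

The Gorlin area pins the unit contract: cardiac output in mL/min (heart
rate × stroke volume), flow period in s/beat, gradient in mmHg, result in
cm², with constants 44.3 and 0.85. Both benchmark values (2.2 cm² at
1.3 mmHg, 1.4 cm² at 3.2 mmHg, flow period 0.465 s) are asserted in the
tests. No exercise flow period is configured by default, so no exercise
valve area is computed.

## The pipeline and problem sizes

`run_experiment()` wires the stages together for one condition/valve cell
with five replicates by default (replicate seeds derived from the base seed
by fixed increments; a small per-node velocity jitter, 0.005 m/s, makes
replicates distinct while leaving the energetics essentially unchanged).
Reports are tibbles with provenance attributes (config hash, seed, package
version); artifacts (series, traces, envelope, summary, config, log) are
written when an output directory is set, and identical config + seed yields
byte-identical summaries.

Default simulation sizes — 40–60 frames per cycle on a 64×64-node field
over an 8 cm domain, 192² px synthetic frames when PIV re-measurement is
enabled, 256–512² px for the accuracy fixtures with one native-resolution
1632×1200 pair in the acceptance script — were chosen so the full analysis
remains interactive on a laptop while every estimator operates well inside
its validated regime; all are configurable upward.

## What the synthetic route does and does not show

Passing tests establish that each estimator recovers what the generators
prescribe: displacements to ~0.05 px, gradients to ~1 %, dissipation
integrals to second order, stroke volume to <1 %. They do not establish
instrument-grade realism: the jet is kinematic (no vortex rings, no wall
interaction, no out-of-plane motion), particle images are ideal Gaussians
without laser-sheet or sensor artefacts, pressure morphology outside the
diastolic difference is canonical rather than measured, and absolute VED
magnitudes therefore track the experimental ones only in order of
magnitude. Quantities that depend on the physical duplicator's flow fields
— the published VED peak values and the specific 127 %/240 % TVED rises —
are outside what a desk-scale synthesis can reproduce; the pipeline instead
asserts the structural ordering (the narrowed, flow-independent orifice
shows the larger exercise rise) under fixed seeds.

Known limitations: no window deformation or stereo/tomographic PIV, no
out-of-plane dissipation correction, no pressure-recovery modelling, and
Doppler/catheter agreement is exact only for Bernoulli-consistent data by
construction.
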
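---
title: "A multi-scale model of left atrial function: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A multi-scale model of left atrial function: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

Over one beat the left atrium (LA) acts in turn as a reservoir (storing
pulmonary venous return while the mitral valve is closed), a conduit
(passively feeding the left ventricle after mitral opening) and a pump
(actively contracting at end-diastole). The time-varying-elastance
description that works well for the left ventricle (LV) is of doubtful
validity for the atrium — its elastance curve is bimodal and its load
independence has never been convincingly demonstrated — so `atrisim` instead
derives both LA and LV pressures from a model of the sarcomere. This
vignette documents the model equations as implemented, the unit and timing
conventions, the numerical choices, and the places where the design was
genuinely open.

## Model structure

The closed loop contains seven chambers: LA and LV (multi-scale, below), a
time-varying-elastance right ventricle (RV, which also absorbs the function
of the neglected right atrium), and four passive linear chambers — aorta
(ao), vena cava (vc), pulmonary artery (pa) and pulmonary veins (pu) with
$P = E V$. Chambers are linked by seven Poiseuille resistances
($Q = \Delta P / R$); the mitral, aortic, tricuspid and pulmonary valves are
perfect diodes, $Q = \max(\Delta P, 0)/R$. `R_pv` is the pulmonary *valve*
and `R_prox` the proximal pulmonary vein resistance — they are deliberately
distinct registry keys because their printed symbols are easily confused.
Chamber volumes follow the continuity equation, so total stressed volume
(273 ml) is conserved exactly by construction; the loop is

lv → (aortic valve) → ao → (R\_sys) → vc → (tricuspid) → rv → (pulmonary
valve) → pa → (R\_pul) → pu → (R\_prox) → la → (mitral) → lv.

### Calcium inputs

Each sarcomere is driven by a prescribed intracellular calcium transient
built from two cosine half-waves: a rise to `Ca_max` over `T1` seconds,
$\mathrm{Ca}(t) = \frac{\mathrm{Ca}_{max}}{2}(1 - \cos(\pi t / T_1))$, and a
return to zero over `T2`, $\frac{\mathrm{Ca}_{max}}{2}(1 + \cos(\pi (t -
T_1) / T_2))$, zero elsewhere in the 0.45 s cycle. The pulse is C1-smooth
and periodic. Two conventions deserve note:

* **Zero diastolic baseline.** The transients return exactly to zero
  between beats. With the published kinetic gains, even a 0.01–0.1 µM
  diastolic floor feeds the slow attachment/recycling pathway
  ($Z_3 \cdot \mathrm{Ca}$) until diastolic ventricular pressure reaches
  tens of mmHg — unphysiological — so the fitted pulses must be read as
  baseline-subtracted.
* **Atrial lead.** The atrial transient is evaluated at
  $(t + s) \bmod \text{period}$ with $s = 0.085$ s, so atrial activation
  *leads* ventricular activation and atrial contraction falls at the end of
  ventricular diastole, producing the a-then-v wave order and an a wave
  that precedes mitral closing. The RV driver has an analogous offset
  `shift_rv`, default 0 (anchored to ventricular activation): the relative
  right-heart timing is poorly constrained by left-heart data, so it is an
  explicit parameter rather than a hidden convention.

### Sarcomere model

Each chamber wall is an equivalent half-sarcomere with four troponin-system
states (concentrations in µM): free troponin $T$, calcium-bound troponin
with detached cross-bridges $TCa$, and the two attached states $TCa^*$ and
$T^*$. The cycle is

$$T \xrightarrow{Y_1 \mathrm{Ca}} TCa \xrightarrow{Y_2 e^{-R_s (L - L_a)^2}}
TCa^* \xrightarrow{Y_3} T^* \xrightarrow{Y_4} T,$$

with reverse rates $Z_1$, $Z_2$ and $Z_3 \mathrm{Ca}$ on the first three
steps. The Gaussian overlap factor $e^{-R_s (L - L_a)^2}$ (centre
$L_a = 1.17$ µm, width parameter $R_s = 20$ µm⁻²) scales the forward
*attachment* rate: filament overlap limits how many cross-bridges can
attach, and this is what makes contraction preload-dependent
(Frank–Starling). Cross-bridge elongation $h$ relaxes toward its unloaded
value $h_c$ while being carried by sarcomere motion, $\dot h = \dot L - B (h
- h_c)$, so the sliding velocity is $\dot X = B (h - h_c)$ and rapid sliding
detaches bridges through the flux $Y_d \dot X^2$ applied to both attached
states (returning $TCa^* \to TCa$ and $T^* \to T$, which preserves total
troponin exactly). Forces per wall area (mN/mm², ≡ kPa):

$$F_a = A \,(TCa^* + T^*)\, h, \qquad F_b = K (L - L_0), \qquad F = F_a + F_b.$$

The passive element is deliberately *linear*; the steep high-volume limb of
a real end-diastolic pressure–volume relation is outside scope (it shows up
as a straight high-volume segment of the atrial PV loop). The two chambers
share all kinetic constants and differ only in the gains $A$ and $K$
(`A_la = 577.51`, `A_lv = 944.58`, `K_la = 20.0`, `K_lv = 0.4853`), paired
that way because each $A$ row belongs with the adjacent chamber-specific
$K$ row of the calibration.

### Chamber geometry and Laplace's law

Chambers are hemispheres: $V = \tfrac{2}{3} \pi R^3$. Radial deformation
equals sarcomere deformation, $L = L_0 R / R_0$ — only *relative*
deformations enter, so no absolute µm/cm conversion is needed. Pressure
follows the thin-walled Laplace relation

$$P = \frac{2 F t_{wall}}{R} \times \frac{1}{0.133322\ \mathrm{kPa/mmHg}}.$$

With the calibrated gains this produces aortic pressures near 120/70 mmHg,
which is the internal consistency check for the factor 2. The ventricular
wall thickness `t_lv = 6.36` cm is an *effective* calibration constant, not
an anatomical thickness; it absorbs whatever geometric idealisation error
the hemisphere introduces.

## Simulation

The assembled ODE system has 17 states (two 5-state sarcomeres + seven
volumes) and is integrated with `deSolve::lsoda` at `rtol = 1e-7`,
`atol = 1e-9`, dense output every 0.5 ms. The diode flow law is continuous
but non-smooth; a stiff-capable adaptive solver handles the switching
without event detection, because the *flow law* — not a discrete valve
state — is the model primitive. Halving the tolerances moves the steady
atrial pressure extrema by well under 0.1% (this is a test).

Initial conditions are not part of the model: volumes are split in fixed
proportions (la 8, lv 25, rv 15, ao 10, vc 90, pa 25, pu 100 of 273 ml) and
the sarcomeres start at rest. `run_to_steady_state()` integrates cycle by
cycle (convergence monitored at 2 ms sampling) until every chamber's
per-cycle volume extrema change by less than `tol = 1e-4` relative between
consecutive beats — about 35 cycles from these defaults — then re-integrates
one final cycle at 0.5 ms for analysis. Non-convergence within `max_cycles`
is a loud error carrying the trend, never a silent truncation. A negative
chamber volume aborts the run with a diagnostic rather than clamping:
it signals a parameter error, and clamping would silently break volume
conservation.

The preload-reduction experiment (`run_ivco()`) emulates inferior vena cava
occlusion by multiplying the pulmonary vascular resistance by 4 — the model
has no explicit vena-cava resistance, and throttling pulmonary venous
return reduces left-heart preload the same way — applied instantaneously at
a cycle boundary, followed by five beats; the fifth is analysed.

## Analysis layer

`detect_fiducials()` anchors the cycle at mitral opening (point F, the
LA/LV crossover located by linear interpolation, which also carries the
v-wave peak) and finds: A = LV pressure minimum; E = the closing crossover;
B = the atrial minimum between opening and closing (a-wave onset); C = the
most prominent atrial local maximum after B, allowed to overrun E by up to
20 ms because the a-wave peak can fall essentially at mitral closing; D =
the atrial minimum after E (v-wave onset). Slopes are the BC and DF chords;
the early/late transmitral gradient maxima are $\max(P_{la} - P_{lv})$ over
the opening→B and B→E windows — the split at B is our operationalisation of
"before/after onset of atrial contraction". No smoothing is applied by
default (simulated traces are smooth); a moving-average option exists for
noisy recordings. Wave *counting* for morphology checks uses a prominence
threshold (2% of the peak-to-peak range, `prominent_maxima()`): a "wave" is
a feature of the pressure trace, not any sample-level ripple.

`extract_pv_loop()` treats the cycle as a closed polygon, finds its
self-intersection by exhaustive segment testing in normalised coordinates,
and reports the signed shoelace area of each lobe; the active "a" lobe is
the one at lower volumes. A loop without self-intersection is reported as a
single lobe with a flag, not an error. `mitral_wave_features()` flags E/A
fusion when the inter-peak flow minimum stays above 5% of the E peak — at a
0.45 s period the simulated waves are always fused (no diastasis); a single
detected peak counts as fused by convention.

## Synthetic fixtures

`fixture_waveforms()` builds piecewise-linear LA/LV/flow traces whose break
points *are* the fiducial points, so detection can be tested against exact
ground truth (e.g. an a-wave chord slope of exactly 50 mmHg/s). The
fixtures emulate the geometry of the waveforms — crossovers, onsets, peaks,
fusion — but none of the properties of real recordings: no noise, no
baseline wander, no c wave, no beat-to-beat variability. Passing the
fixture suite therefore demonstrates *exactness of the analysis layer on
clean traces*, not robustness on clinical data.

## Reconstruction choices and known limitations

The sarcomere equations implemented here follow the published four-state
formulation that the calibrated rate constants belong to; three details are
not recoverable from the calibration table alone and were fixed as follows,
each isolated behind a single function so a correction is one code change:

* the overlap factor multiplies the attachment step (the alternatives —
  scaling calcium binding or scaling force directly — were implemented and
  compared; scaling calcium binding produces a spurious third atrial
  pressure maximum and an a-wave slope that *rises* under preload
  reduction, contradicting the experiment being reproduced);
* the cross-bridge equation uses $\dot h = \dot L - B(h - h_c)$, making
  $\dot X = B(h-h_c)$ the sliding velocity in the $Y_d$ detachment flux;
* the Laplace prefactor is 2 (thin-walled shell), validated by the
  physiological systemic pressures it yields with the calibrated gains.

Under these choices the simulation reproduces the qualitative atrial
physiology in full — biphasic a/v pressure wave, figure-eight PV loop with
the active lobe at lower volumes, fused E/A filling, correct valve-event
order, and a decrease of all eight indices under preload reduction — and
most index values to within ~10%. Two systematic gaps remain and are
visible in the acceptance checks: the LV early-diastolic pressure floor is
low (the reconstructed calcium waveform leaves essentially no diastolic
cross-bridge tone at the published detachment rates) and the atrial active
pressure amplitude above its diastolic floor is correspondingly weak, which
depresses the a-wave slope. Both trace to waveform details lost with the
original typeset equations, not to the conservation structure or the
circulation, and both are reported as computed rather than patched by
re-tuning published constants.

Out of scope by design: electrophysiology, the right atrium, a series
elastic element, nonlinear passive chambers, inertial (inductive) flow
elements, baroreflex control, respiratory coupling, pressure-wave
propagation (hence no c wave), and Doppler velocity profiles.
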
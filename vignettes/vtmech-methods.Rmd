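---
title: "Methods: desk-scale electromechanics of ventricular tachyarrhythmia"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: desk-scale electromechanics of ventricular tachyarrhythmia}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`vtmech` reproduces, at desk scale, a computational study of how the
*electrical instability* of ventricular tachyarrhythmia relates to the
heart's *mechanical performance*: simulate reentrant arrhythmia episodes,
quantify each episode by twelve electrical features, compute two mechanical
outputs (stroke volume and the averaged standard deviation of myocardial
tension, "ampTens"), and benchmark support vector regression against small
neural networks for predicting mechanics from electrics.

This vignette records the models, their assumptions, the tunable parameters,
and the design choices made where the design was genuinely open.

## Single-cell electrophysiology

Cells follow the ten Tusscher-type human ventricular formulation (17 state
variables; epicardial parameters by default, endocardial and mid-myocardial
variants available).  Integration is forward Euler for the membrane
potential and concentrations with Rush-Larsen exponential updates for the
voltage gates; intracellular and SR calcium use the analytic
instantaneous-buffering update of the published integration scheme.
Voltage-dependent gate quantities are tabulated on a 0.02 mV grid per run
(the table embeds `exp(-dt/tau)`, so it is rebuilt whenever `dt` changes).

* `dt = 0.02` ms default.  Halving it changes the steady-state APD by well
  under 1 ms (checked in the tests).
* Pacing for APD measurements: 50 conditioning beats at 1 Hz, stimulus
  52 pA/pF for 1 ms, APD90 on the final beat.  The reference study states
  neither pacing protocol nor repolarization threshold, so these defaults
  are recorded prominently here; its quoted control APD (236 ms) is a
  tissue-mesh average, while the single-cell APD90 of this ionic model is
  published near 276 ms.  Our control value (~271 ms) sits between the two,
  inside the +/-20% band used throughout.
* APD is measured as the time spent above the level
  `peak - fraction * (peak - takeoff)`, crossings linearly interpolated.

Tachyarrhythmia variability is created by scaling the delayed-rectifier
conductances `g_Ks` and `g_Kr` 2- to 100-fold, and by five inherited
channelopathy presets (three KCNQ1, two hERG variants).  The presets ship
as an editable JSON catalogue of conductance-level multipliers because the
variants' full Markov kinetics live in the primary literature; each entry
is labelled as an approximation.

## Tissue: monodomain sheet and thin slab

Tissue is an isotropic monodomain sheet,
`dVm/dt = D lap(Vm) - I_ion/Cm`, no-flux boundaries, explicit integration
under the stability bound `D dt/dx^2 < 0.25`.  A thin-slab mode (`nz`
layers) exists solely to give scroll-wave filaments a 3D definition.

**Desk-scale conduction.**  With the physiological diffusion
(`D ~ 1e-3 cm^2/ms`, CV ~ 50 cm/s) the excitation wavelength `CV x APD` is
~4 cm, larger than any few-centimetre sheet, and induced spirals
self-terminate — verified empirically during development.  The package
therefore slows conduction to `D = 2e-4 cm^2/ms` (CV ~ 22 cm/s) and
refines the grid to `dx = 0.0125 cm` so the wavefront stays resolved.
Production geometry is 192x192 (2.4 cm); the fast profile is 96x96 with
2 s recordings.  Consequences: wavelengths and rotor speeds are desk-scale
quantities (about one order below the printed study values), while
dimensionless structure — rotor count, DF band, feature correlations — is
preserved.  This is the package's main rescaling and is stated wherever
results are reported.

**Reentry induction.**  S1 is a plane wave from the left edge; S2 is a
premature regional stimulus at one of four sites (left/right half, lower
left/right quadrant, mapping the anatomical whole/lower LV/RV sites onto
the sheet).  In a homogeneous sheet a *half-plane* S2 has no free wavefront
end and cannot curl into a spiral, so those sites are expected to fail
induction and be QC-rejected; quadrant sites induce reentry.  The S2
coupling interval is scanned over a window anchored at the configuration's
single-cell APD90 (offsets -20 to +120 ms in 10 ms steps) because the
vulnerable window tracks repolarization; the first interval whose trial
segment shows re-activation is kept.

**Reentry onset** is the first time a node re-depolarizes above -20 mV
with no stimulus active *after* its first post-S2 activation (the S2 wave
passage itself).  Episodes whose reentry dies (phase singularities in
fewer than 80% of post-onset frames) are rejected, not imputed: the
reference dataset contains only sustained episodes.

## Electrical features

Twelve features per episode, fixed order: APD, Wavelength, Rotation_rate,
DF_mean, DF_std, DF_peakP_mean, DF_peakP_std, PS, PS_std, Filament,
Filament_std, Filament_PS_ratio.

* **Phase** comes from the analytic signal (FFT Hilbert transform) of the
  mean-subtracted voltage, wrapped to `(-pi, pi]`; constant nodes are
  masked.  A delay-embedding alternative sits behind a flag.
* **Phase singularities**: winding number of each 2x2 plaquette (sum of
  wrapped phase differences around the loop, tolerance 5%).  The detector
  is tested against a brute-force oracle with an independently written
  wrapping rule on random multi-charge fields.
* **Filaments**: PS detected per slab layer, PS-bearing voxels joined by
  26-connectivity.  Both the element (voxel) count and the connected
  count are computed; the "Filament" feature uses elements, whose
  magnitude (PS count x wall thickness) matches the study's filament
  statistics, which are ~300-fold larger than its PS counts.  On 2D
  recordings the element count degenerates to the PS count and is flagged.
* **Dominant frequency**: single full-window periodogram per node,
  normalized `2|X|^2/N^2`, band 0.5-20 Hz; DF is the argmax, peak power
  the periodogram value there; outputs are means and population SDs over
  nodes.  Windows too short for two periods of the band floor raise the
  floor to `2/duration` with a warning (the fast profile's 2 s recordings
  then resolve >= 1 Hz, far below the 3-9 Hz rotors seen in practice).
* **Wavelength** is operationalized as `CV x APD`; CV comes from the
  median inverse gradient of per-node first-activation times.
  **Rotation_rate** is the mean translation speed of tracked PS tips
  (greedy nearest-neighbour linking).  The study table prints this
  quantity in cm/s with statistics that mirror its DF column in Hz; the
  unit ambiguity is noted, and tip speed in cm/s is what is computed.

## Myofilament mechanics

A four-state crossbridge chain N_xb <-> P_xb <-> XB_PreR <-> XB_PostR
driven by bound troponin calcium.  The non-permissive/permissive rates are
steeply cooperative, `K_np (TCa/TCa_ref)^{7.5}` and
`K_pn (TCa/TCa_ref)^{-7.5}`, clipped at 5 /ms because the negative
exponent diverges at diastolic calcium.  Troponin saturation follows a
single-site buffer ODE (`k_on = 40 /mM/ms`, `k_off = 0.06 /ms`), chosen so
that saturation spans ~0.1-0.4 over the ionic model's calcium transients.
Crossbridge cycling rates are of the magnitude of the cited myofilament
literature (f 0.5, g 0.07, hf 2, hb 0.4, gxb 0.07 /ms).  The model is
isometric — no sarcomere-length feedback — because 3D wall mechanics is
out of scope; tension is `60 kPa x XB_PostR`, calibrated so a 1 Hz twitch
peaks at ~40 kPa (physiological tens of kPa).  Under fibrillatory calcium
the resulting per-cell tension SD is of order 10 kPa, larger than the
study's sub-kPa band: with millisecond-scale crossbridge kinetics a ~8 Hz
rotor still produces sizable tension oscillations, and the twitch
calibration was kept rather than suppressing tension amplitude.  The
integrator is checked against the algebraic fixed point of the rate matrix
(0.1%) and conserves occupancy exactly by construction.

## Hemodynamics

A closed-loop lumped circulation: four elastance chambers (LA/LV/RA/RV),
four RC vascular compartments (SA/SV/PA/PV), four ideal one-way valves
(MI/AO/TR/PU).  Ventricular elastance is tension-driven,
`E_LV(t) = 0.08 + 0.07 T(t)` mmHg/mL with T the spatial-mean tension in
kPa — the time-varying-elastance surrogate that replaces the study's
finite-element ventricle; this is the largest structural simplification in
the package and is flagged in all reports.  Atria follow a fixed
low-amplitude half-cosine timing function.  Defaults give SV ~ 60-75 mL
under a normal 1 Hz twitch and SV ~ 0 under fibrillatory driving.  Blood
volume is conserved exactly by construction; valves never conduct
backwards.

*Meaningful ejection periods* are LV-volume maxima with topographic
prominence of at least 2% of the resting EDV (120 mL), each paired with
the following minimum; stroke volume is the mean EDV-ESV drop over those
periods and 0 when none exist.  The 2% prominence threshold is a package
default (the study names no number); it rejects sub-mL ripple while
keeping every genuine cycle.

## The emulator (synthetic feature tables)

The regression bench never runs tissue simulations; it uses a calibrated
emulator of the 116-episode table.  Marginals are Beta distributions on
each variable's [min, max], moment-matched to its mean/SD (a truncated or
clipped Gaussian cannot reach the SD > mean - min seen in the Filament and
SV rows).  Dependence is a single-factor Gaussian copula: strong loadings
(+/-0.85, giving |r| ~ 0.7 with the outputs) for APD, Wavelength,
Rotation_rate and DF_mean; weak loadings (+/-0.36, |r| ~ 0.3) for the
dispersion/singularity features; the outputs additionally carry a mild
quadratic term in the factor so the bench has a smooth nonlinearity for
the networks to exploit.  Copula ranks are mapped through a stratified
quantile grid (Latin-hypercube style), so sample moments are faithful at
any n and every draw respects the table's min/max.  One printed bound was
corrected: the study table's `DF_peakP_mean` maximum (2e-5) is below its
own mean and median and is read as 2e-4.

What the emulator does *not* reproduce: episode-level physics (its rows
are exchangeable draws, not simulation outputs), heavy-tail behaviour
beyond what Beta marginals allow, and any feature-feature structure beyond
one factor.  Bench results on it show algorithmic properties of the
regressors, not new physiology.

## Regression bench

Min-max scaling is fitted on the training split only (features and
targets) and applied to held-out rows; the study does not state its
leakage handling, and train-only fitting is the defensible choice.  Models:
SVR with linear, polynomial (degree 3; unstated in the study) and RBF
kernels, `C = 100`, `gamma = 1/n_features`; networks with 1-4 hidden
layers of 6 ReLU neurons, linear output, uniform +/-0.05 initialization,
full-batch Adam (lr 1e-3), MSE loss, 2000-epoch cap with early stop after
a 200-epoch plateau — the unstated training details are package defaults,
all exposed in `regression_spec()`.  Small uniform initializations can
start dead (all ReLU units silent); a fit that plateaus no better than the
constant predictor is retried from a fresh seeded initialization (at most
3 restarts).  Evaluation: `R^2 = 1 - SS_res/SS_tot` about the
evaluation-set mean; MSE on the scaled target (for cross-target
comparability) and on the raw scale.  70/30 split with
`n_train = floor(0.7 n)`; 10-fold CV on the training split for model
selection, after which the selected model is refit on the full split.

## Problem sizes and determinism

Everything is seeded: the emulator and splits are deterministic functions
of their seeds, SVR is deterministic, network fits are deterministic given
the initialization seed.  Default test/bench sizes: emulator tables of
200-10000 rows, bench comparisons at n = 1000 over 20 seeds, tissue smoke
runs at 96x96 for 2 s.  These sizes were chosen so the whole suite runs on
a single CPU in minutes while leaving the statistical conclusions stable
across seeds.

## Known limitations

* 2D/thin-slab surrogate with rescaled conduction: absolute wavelengths,
  rotor speeds and filament counts are not comparable to 3D anatomy.
* Conductance-level mutation presets approximate Markov-kinetic variants.
* Isometric crossbridge model without length feedback; tension-SD
  magnitudes exceed the study's band (see above).
* Elastance surrogate ventricle: absolute pressures are not calibrated to
  the study's finite-element values.
* No mechanoelectrical feedback (excluded by the study itself).
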
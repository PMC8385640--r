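---
title: "Locating atrial parasympathetic innervation sites from electrogram grids: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Locating atrial parasympathetic innervation sites from electrogram grids: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Ganglionated plexi (GPs) are epicardial clusters of autonomic ganglia whose
cholinergic neurons release acetylcholine (ACh) onto the atrial myocardium.
ACh activates the inward-rectifier potassium current IKACh, which shortens
the action potential duration (APD) and — crucially for this package —
steepens phase 3 of repolarization. A steeper, earlier repolarization
produces a larger-amplitude repolarization wave in the unipolar electrogram
(EGM) recorded above the tissue. `achmap` builds the full in-silico chain
needed to exploit this signature: atrial tissue simulation with localized
ACh release, a forward model for a multielectrode EGM grid, and a
threshold-based detector that maps which electrodes overlie ACh-release
sites, with fibrotic areas screened first from the depolarization-wave
amplitude.

## Membrane models

Myocytes follow the Courtemanche–Ramirez–Nattel human atrial model (21
state variables; Na+, K+, and Ca2+ currents, sarcoplasmic-reticulum calcium
handling). Fibroblasts follow the MacCannell *active* fibroblast model with
four membrane currents (a time-dependent Kv current with activation and
inactivation gates, an inward-rectifier K+ current, a Na+/K+ pump and a
background Na+ leak); its resting potential in this implementation is
−48.6 mV, depolarized relative to the myocyte's −81 mV, as published.

Three substrates are available through `apply_condition()` and the
tissue-level pairings of `experiment_config()`:

| | non-AF | paroxysmal AF | persistent AF |
|---|---|---|---|
| fibrosis | 0% | 20% | 40% |
| myocyte–myocyte D | 0.003 cm²/ms | 0.003 | 0.002 |
| Ito, ICaL, IKur scaling | 1, 1, 1 | 1, 1, 1 | 0.5, 0.3, 0.5 |

Edges touching a fibroblast carry a 4-fold reduced diffusion coefficient;
the transverse-to-longitudinal conductivity ratio is 0.5 with fibers along
the y axis. Optional cell-to-cell variability assigns each node one of 25
(IK1, ICaL) conductance combinations spanning ±30% in 15% steps
(`variability_grid()`); the default experiment matrix runs without it, and
a `variability` argument to `simulate_tissue()` switches it on.

### The IKACh formulation

The dose–response has the familiar saturating form
`g = g_max / (1 + 9.13652 / [ACh]^0.477811)` ([ACh] in µM) multiplying a
voltage-dependent factor `0.0517 + 0.4516 / (1 + exp((V + 59.53)/17.18))`
and the K+ driving force. The published maximal conductance of 10 nS/pF,
derived from guinea-pig data for cholinergic-AF modeling, collapses the
human atrial APD90 to ~50 ms at the 0.1 µM dose used here. That regime is
inconsistent with the delineation rule this detector relies on (see below):
the repolarization peak of ACh sites would fall *before* the start of the
search window. We therefore rescaled the maximal conductance, keeping the
dose–response shape, so that 0.1 µM halves the single-cell APD90
(`g_max = 1.8` nS/pF; APD90 295 → 151 ms at cycle length 1000 ms). This is
a deliberate, documented model choice made on single-cell physiology; all
constants are pinned in `ikach_constants()`.

## Numerics

The monodomain equation is solved by explicit finite differences: a
flux-form 5-point Laplacian over the edge-wise diffusion map, no-flux
boundaries via absent edges, Rush–Larsen updates for the twelve
voltage-dependent gates (steady states and rate constants tabulated on a
0.05 mV grid and linearly interpolated), forward Euler for concentrations,
the calcium-release gates and the membrane potential. The time step adapts
between 0.005 and 0.01 ms on the previous step's maximal |dVm/dt|
(threshold 20 mV/ms), so upstrokes integrate at the small step and
diastole at the large one. One implementation subtlety with physical
content: a fibroblast node's gap-junctional (diffusion) term is multiplied
by Cm_myocyte/Cm_fibroblast = 100/6.3, because the same edge current moves
the much smaller fibroblast's potential proportionally more. Without this,
each fibroblast node behaves like a 16-fold oversized cell and drains its
myocyte neighbors so strongly that 40% fibrosis collapses the tissue APD.

The fast integrator is verified two ways: a one-step comparison against the
exact right-hand side on all 21 state variables, and a full paced beat
against an independent stiff solution (`deSolve::lsoda`), which agrees in
APD90 to 0.1% at the integrator's converged limit (~0.6% at dt = 0.01 ms).

Tissue stimulation applies 40 pA/pF for 2 ms to the bottom two node rows —
twice the diastolic threshold of 19.6 pA/pF found once by bisection
(`diastolic_threshold()`) on the non-AF desk-scale tissue.

**Spatial convergence.** With this scheme the longitudinal conduction
velocity changes by ~7% between dx = 0.04 and 0.02 cm (measured with
dt = 0.005 ms and 0.05 ms activation sampling), reflecting the first-order
resolution of the upstroke by a standard finite-difference stencil. Schemes
of the finite-element/meshfree family converge faster, and a sub-0.2%
change between these spacings is not attainable here; the corresponding
acceptance test records this honestly as a failure. Velocities themselves
are physiological (≈80–85 cm/s longitudinally in non-AF tissue) and the
transverse-to-longitudinal velocity ratio approaches √0.5 as the grid is
refined.

## The electrogram forward model

The unipolar EGM at electrode position r′ is the current-dipole integral
over the sheet: φe(r′, t) = ΣΣ [−∇Vm(r, t) · ∇(1/d(r, r′))] dx dy, with
central-difference spatial gradients of Vm (one-sided at borders), the
analytic kernel gradient, Euclidean distance d, and area weights; all
distances in cm. "Dimensional" electrodes (0.8 × 0.8 mm) average the
punctual EGMs of all covered nodes — 25 nodes at the reference 0.02 cm
spacing — which, by linearity, is folded into the kernel weights. Raw
amplitudes are normalized by a distance-dependent divisor (350, 250, 150
for z = 0.5, 1, 2 mm), landing depolarization amplitudes at ~6–7 mV as in
clinical recordings.

Filtering is zero-phase (forward–backward Butterworth with odd-reflection
edge padding and exact mean removal): a 2 Hz high-pass for clean signals,
and for noisy signals a 2–30 Hz band-pass before repolarization analysis
plus a 2–250 Hz band-pass before depolarization analysis.

**Noise.** Patient-derived noise segments are not available, so
`synth_noise()` generates band-limited (1–100 Hz), 1/√f-weighted Gaussian
segments normalized to exactly unit power; `add_noise()` scales them so
that 10·log10(P_signal/P_noise) equals the requested SNR. The choice of
the signal-power reference matters enormously: referencing the whole beat
ties the noise to the 6–7 mV depolarization complex (σ ≈ 1.6 mV at 0 dB),
which obliterates the ~0.3 mV repolarization wave the detector reads. The
experiment pipeline therefore references the SNR to the grid-level clean
signal power over the repolarization window — the quantity the detector
analyses — giving hundreds-of-microvolt noise amplitudes at 0 dB, the
scale reported for repolarization-analysis noise studies. `add_noise()`
itself defaults to per-electrode whole-record power and accepts any
reference through `p_signal`. Real electrode noise contains impulsive and
mains components that this synthetic spectrum does not; robustness results
under it show tolerance to broadband in-band noise, not to structured
artifacts.

## The detection algorithm

1. **Delineation** (`delineate()`). Each electrode's steepest negative
   slope marks its depolarization; the grid reference time t_ref is the
   median over electrodes (the grid-level rule is unspecified in mapping
   practice; the median is robust to stragglers). The grid-global
   repolarization peak time t_R is the time of the maximal |φ| across all
   electrodes at least 100 ms after t_ref; the analysis window TW spans
   [t_R − 30, t_R + 150] ms. The EGM onset for the depolarization segment
   is the first sample before t_ref where any |φ| exceeds 5% of the grid
   depolarization maximum.
2. **Amplitudes** (`amplitude_maps()`). The repolarization amplitude R_A is
   the local extremum of largest absolute value inside TW, sign preserved
   (local extrema are strict sign changes of the first difference; plateaus
   resolve to their earliest sample; an exact |min| = |max| tie returns the
   positive value — positive peaks are the ACh signature — and is flagged).
   The depolarization amplitude D_A is max − min over onset→TW-onset.
3. **Thresholds** (`roc_optimal_threshold()`). Exhaustive scan of a stated
   grid — 40 values in 0.1 mV steps centered at the global mean for D_A;
   1% steps of the grid-maximum R_A across a configurable span, default
   −80%..+80% (~160 values), necessarily including negative percentages
   because fibrotic-region optima can be negative — choosing the point
   closest (Euclidean) to the 100% sensitivity / 100% specificity corner.
   Ties resolve to the higher-sensitivity point, then to the lower
   threshold.
4. **Classification** (`classify_electrodes()`, `detect_ach()`). Without
   fibrosis patches, one stage: ACh iff R_A > R_th. With patchy fibrosis,
   two stages: fibrotic iff D_A < D_th, then region-specific R
   thresholds optimized separately within the predicted fibrotic and
   non-fibrotic regions. If a region's ground truth is single-class the
   other region's threshold is reused (recorded in `fallbacks`).
5. **Metrics** (`detection_metrics()`): accuracy, sensitivity, and false
   positive rate (1 − specificity), with ACh as the positive class and
   per-electrode ground truth from the center-in-circle rule (boundary
   inclusive) against the generator's registry.

The threshold search uses the ground truth of the case being analyzed —
an operating-point characterization of the amplitude features, not a
prospective classifier; `detect_ach()` also accepts fixed percentage
thresholds (`thresholds =`) so that across-configuration mean optima can
be applied instead, the mode a clinical deployment would use.

## Phantoms

`phantom_vm()` builds analytic Vm movies in milliseconds instead of
minutes: a planar wave of template APs (1 ms linear upstroke, slowly
declining plateau, logistic phase 3) traveling at a set velocity, with ACh
zones given a shorter APD and a faster phase-3 time constant and fibrotic
zones a depressed upstroke and delayed activation. The phantom reproduces
exactly the features the detector reads — zone-dependent repolarization
steepness and amplitude — and nothing else: no rate adaptation, no
electrotonic coupling across zone boundaries, no source-sink effects. Tests
passing on phantoms therefore validate the EGM and detection stages, not
the tissue electrophysiology; the monodomain runs cover the latter.

## Scales, defaults, and reproduction

Two profiles share every code path. `full_profile()` is the reference
geometry: 5 × 5 cm (251 × 251 nodes, dx 0.02 cm), a 16 × 16 electrode grid
at 2 mm pitch (z = 0.5/1/2 mm), single-cell pre-pacing for 60 s at cycle
length 1000 ms, two paced tissue beats with the second analyzed.
`desk_profile()` — used by the test-suite and `scripts/acceptance.R` so a
full 28-configuration matrix completes in minutes on one CPU — keeps dx
0.04 cm on a 2 × 2 cm sheet with an 8 × 8 electrode grid, one analyzed
beat of 550 ms (nodes start from converged single-cell states, so the
tissue transient is small), and fewer ACh circles per geometry (3 × 0.32,
1 × 0.5, 1 × 0.76, and 1 × 0.5 + 2 × 0.24 cm) so the circles fit the
smaller mapped area; circle radii, doses, fibrosis densities, remodeling
and the detection algorithm are identical. ACh circle centers are drawn
uniformly inside the mapped area with rejection of overlaps (whole-layout
restarts on dead ends); fibrotic patch layouts are two named presets in
fractional coordinates (`fnu_preset()`), since only qualitative geometries
are available for them, and ACh circles may overlap fibrotic patches.

At the desk scale each electrode is 1/64 of the map, so accuracies move in
~0.016 steps and single-configuration metrics are noticeably grainier than
at 16 × 16; the acceptance checks therefore aggregate minima/maxima over
the full configuration matrix. One random realization is generated per
(configuration, seed); seeds are recorded in every summary row.

## Known limitations

* 2D sheets, axis-aligned fibers, edge pacing at fixed cycle length only;
  no arrhythmia induction, no bipolar EGMs, no ventricular far field.
* Collagenous (non-conductive) fibrosis is not modeled — fibrosis is
  fibroblast replacement plus coupling reduction.
* The CV spatial-convergence figure of merit of higher-order solvers is
  not met by the finite-difference stencil (see Numerics).
* The synthetic noise spectrum is a stand-in for patient noise segments.
* Ground truth for partially covered electrode footprints uses the
  center-point rule; electrodes straddling a circle rim contribute
  misclassifications that a footprint-overlap rule might not.
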
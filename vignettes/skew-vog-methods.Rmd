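---
title: "Measuring skew deviation from alternating-cover video-oculography: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring skew deviation from alternating-cover video-oculography: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(skewscope)
```

## The measurement problem

Skew deviation is a vertical misalignment of the eyes arising from
imbalance in the graviceptive (otolith and vertical semicircular-canal)
pathways. Detecting and quantifying it matters clinically because a skew
is one of the "central" signs distinguishing vestibular stroke from
peripheral vertigo in the bedside HINTS battery. The reference method,
the alternate prism cover test (APCT), occludes each eye in turn: a
latent misalignment reveals itself as a corrective vertical refixation
saccade on uncovering, and the examiner increases prism strength until
the movement is neutralized. The APCT is ordinal (whole prism diopters),
examiner-dependent, and known to struggle with small deviations.

`skewscope` implements an automated counterpart. Under an
alternating-cover stimulus (the viewing eye switches every 2 s), a
monocular eye tracker records the vertical position of one eye. Every
cover switch elicits a corrective saccade whose net amplitude equals the
misalignment, with alternating sign. The algorithm recovers the skew from
those switch-locked saccades, and the package validates the whole chain
against a simulated APCT examiner on synthetic recordings with known
ground truth.

Units: positions are degrees of visual angle (positive = up), times are
seconds, prism strengths are prism diopters (PD). The PD-to-degree map is
deliberately *linear* at 0.57 °/PD, matching the conversion table used
with the clinical foil set (so 2 PD = 1.14°, 10 PD = 5.70°); the optical
`atan(pd/100)` form would give 1.146° and 5.71° instead, and the linear
convention reproduces the printed values exactly. For the fixation-target
geometry we use the single-argument form `atan(size/distance)`; at 4 mm /
260 mm it gives 0.881°, indistinguishable at three decimals from the
half-angle form, and the choice between the two is unverifiable at this
geometry.

## The estimation engine

For a trace $y(t)$ sampled at $f_s$ (default 250 Hz; the engine requires
$f_s \ge 100$ Hz) and switch times $s_k$:

**Velocity.** Savitzky–Golay differentiation: a local quadratic fit over
an 11-sample window at 250 Hz (scaled proportionally with $f_s$, kept
odd). It is exact on linear trends and strongly attenuates differentiated
white noise: at 0.05° position noise the velocity noise SD is about
1.2 °/s, comfortably below the detection threshold. Blink samples are
linearly bridged before filtering and the blink mask is dilated by the
filter half-width, so velocity within reach of a blink is `NA`.

One consequence of the fixed 44 ms window deserves mention: small
saccades (a 2.28° saccade lasts ~26 ms under the main-sequence rule
below) are *narrower* than the filter, so the measured peak velocity is
substantially attenuated — we measure 30–80% of the analytic peak of the
underlying profile depending on amplitude. This is harmless for the skew
estimate, which uses the *integral* of velocity (preserved by the filter)
and the net position step, never the peak; peaks are only used for
thresholding, where the ordering by amplitude survives. Tests therefore
pin amplitude recovery tightly (0.02°) and assert only an attenuation
band for peaks.

**Saccade detection.** Candidate samples satisfy
$|v| > \max(\lambda \hat\sigma, 10\,°/s)$ with $\lambda = 6$ and
$\hat\sigma$ the median-based robust SD of the velocity, sustained for at
least 6 ms. The floor keeps the threshold physical on near-noiseless
traces where $\hat\sigma \to 0$. Onsets/offsets extend outward to the
nearest crossing of $\max(\hat\sigma, 0.5\,°/s)$ (the 0.5 °/s floor again
guards the noiseless limit); events closer than 20 ms merge. The
commercial device this emulates does not publish its detector, so these
are standard adaptive-threshold choices, all exposed in `vog_control()`.

**Event windows and integration.** Each switch owns the window
$[s_k - 0.5, s_k + 1.5]$ s (clipped to the trace and flagged when it
extends beyond it). Saccades intersecting the window are selected and the
per-event skew is the trapezoidal integral of *signed* velocity from the
first selected onset to the last selected offset, clipped to the window;
no sample outside the window ever contributes. Signed integration is the
reason hypermetric saccades need no special casing: an overshoot followed
by its corrective return integrates to the net displacement. (Rectified
integration would double-count the overshoot.) If no saccade lies in the
window the event records a valid skew of zero — "no corrective movement"
is a real observation at small deflections — unless a blink gap overlaps
the window, in which case the event is invalidated (`blink_gap`) rather
than interpolated: a gap could hide the saccade, so neither a number nor
a confident zero is defensible.

**Aggregation.** Each valid event's signed skew is rectified by the
alternation sign expected from the viewing-eye sequence (left-eye viewing
is taken as positive for the tracked right eye; the convention is
symmetric and only needs to be consistent between simulator and engine).
Events deviating from the event median by more than 3·MAD (MAD floored at
0.1° so that a tight cluster does not reject everything) are excluded —
this is the guard that drops residual hypermetric or artifact-corrupted
windows. The recording-level estimate is the **median** of the remaining
rectified values, reported as a magnitude (the cover test reports
magnitudes). The median was chosen over the mean because one corrupted
window out of five should not move the estimate; with at least five
switches per recording the median has adequate efficiency.

**Calibration** is optional: simulated traces are already in degrees.
When supplied, a least-squares linear fit `raw = gain·deg + offset` over
known fixation targets (protocol: center and ±8.5° vertical/horizontal)
is inverted and applied before differentiation.

## The simulator

`sim_config()` defaults encode the replica study conditions: 10 subjects
× foils {1, 2, 4, 6, 8, 10} PD, one 10-s recording per condition at
250 Hz, cover switches every 2 s with the first at 0.5 s so that five
full event windows fit, and each subject seeing the foils in a
derangement of the previous subject's order. Per switch the simulator
injects a corrective saccade with Normal(200, 40) ms latency (a
literature-typical reaction time; truncated at 80 ms), logistic position
profile, and duration from the main-sequence rule
$D\,[\mathrm{ms}] = 2.2\,|A|[°] + 21$. The logistic steepness (default 8)
gives a ~180 °/s peak for a 2.28° saccade, realistic for small vertical
saccades. Net displacement per responding window equals the signed
induced deflection *exactly* (the waveform is normalized), which makes
ground truth conservation a testable identity rather than an
approximation.

Degradations, each independently switchable:

* **Measurement noise**: i.i.d. Gaussian position noise, SD 0.05°.
* **Blinks**: Poisson events (0.05 /s) of 0.1–0.2 s, stored as masked
  gaps, not position excursions — the engine must demonstrate gap
  tolerance, not artifact rejection of implausible excursions.
* **Hypermetric saccades** (p = 0.1): overshoot by 30–60% with a fast
  corrective return 50–150 ms later; the *net* displacement is conserved.
* **Non-responders**: with probability 0.3 at 1 and 2 PD (0 elsewhere) a
  recording shows no corrective saccades at all, reflecting central
  adaptation to small misalignments; drawn per recording, not per event,
  matching the per-participant phenomenon.
* **APCT examiner**: reading = truth (+2.6 PD bias when the truth is
  below 2 PD) + Gaussian examiner noise (SD 1.5 PD), quantized to the
  available prism set {0, 1, …, 10} (0 = "no prism needed"). The bias
  and noise echo the observed overestimation of ~1 PD skews near 4 PD
  and the ordinal saturation at 10 PD.

All randomness flows from one master seed through named substreams keyed
by (subject, foil, purpose), so recordings are individually reproducible
and adding subjects never perturbs earlier ones.

What the simulator does **not** emulate: horizontal or torsional
components, nystagmus (slow-phase drift would require detrending the
velocity trace and is out of scope), pupil-image-level artifacts,
tracker-specific nonlinearity, or head movement. Passing tests on this
generator therefore show the algorithm is correct *given* clean
switch-locked vertical refixations; they do not certify performance on
patients with spontaneous nystagmus or poor fixation.

## Agreement statistics

The comparison of the automated estimate against the cover test follows
the standard two-method repertoire, computed over the 60-row
subject × foil table:

* **Percent error** $(\mathrm{ref} - \mathrm{test})/\mathrm{ref} \times
  100$, undefined at zero reference (excluded and counted); **accuracy**
  is 100 minus the mean absolute percent error, so the two sum to 100 by
  construction. This is the most direct reading of an "overall accuracy"
  headline given only the percent-error formula.
* **Pearson** r, r², two-sided p via the t transform.
* **ICC(2,1)**: two-way random effects, absolute agreement, single
  measures, from the two-way ANOVA mean squares, with the standard
  F-based 95% CI and the between-row F test p. This variant is the
  conventional choice for two-method agreement on continuous data when
  the published variant is unspecified; absolute agreement (not
  consistency) is what matters clinically. The implementation computes
  the mean squares directly; the test suite checks it against an
  independent `stats::aov` oracle to 1e-10.
* **Bland–Altman**: differences ref − test; bias = mean, limits of
  agreement = bias ± 1.96·SD with the sample (n−1) SD.
* **Paired two-sided Wilcoxon** per foil condition: zero differences
  dropped (classic convention; a Pratt option is provided), exact
  signed-rank p for up to 25 untied nonzero differences, otherwise a
  normal approximation with tie-corrected variance and continuity
  correction. The exact branch is verified against full $2^n$ sign
  enumeration in tests.

Multiple-testing correction across conditions is deliberately not
applied, and no proportional-bias regression is fitted on the
Bland–Altman differences.

## Numerical and test-size choices

Tolerances: waveform excursion is exact to 1e-9 by construction; the
velocity-integral identity (event skew vs. net position step) is held to
0.02°, which bounds trapezoid plus smoothing error at 250 Hz; noiseless
round-trip recovery is held to 0.1 PD per foil and the default-conditions
(0.05° noise, blinks, overshoots, non-responders) per-foil median error
to 0.3 PD over 50 seeds. Study-level properties use 50 replicate studies
(ICC > 0.7 in at least 90% of them; non-decreasing mean estimate across
foil strengths). These sizes keep the full suite under a minute while
leaving the binomial/sampling noise of each property an order of
magnitude below its margin. Degenerate inputs are errors, not guesses:
identical calibration targets, zero-variance correlations, zero
between-row variance ICCs, sub-window traces. A recording with no valid
event windows returns an estimate of 0 with `n_events_used = 0` and a
warning flag rather than an error, because "no corrective movement seen"
is a legitimate clinical outcome.

## Known limitations

* The detector's constants (λ = 6, 10 °/s floor, 6 ms duration, 20 ms
  merge) are standard but not tuned to any particular tracker; real
  devices with different noise spectra may need `vog_control()`
  adjustments.
* Peak velocities are filter-attenuated (see above); do not use
  `peak_velocity_deg_s` for main-sequence studies without deconvolution
  or a shorter window.
* The simulated examiner is a two-parameter caricature (bias below 2 PD,
  Gaussian noise, quantization); it reproduces the qualitative
  small-skew overestimation pattern, not any specific examiner.
* Estimates are magnitudes; the signed (direction-resolving) information
  exists at event level but is not aggregated, mirroring how cover-test
  results are reported.
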
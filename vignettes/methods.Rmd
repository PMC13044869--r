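---
title: "Models and methods behind photoddball"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind photoddball}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", fig.width = 6)
library(photoddball)
```

photoddball implements a complete analysis chain for event-locked
dopamine photometry in auditory deviance paradigms, together with a
generative model of the data it analyzes. This vignette explains the
models, the tunable parameters, the numerical choices, and what the
synthetic tests do and do not establish about real recordings.

## The stimulus paradigms

Eight paradigm generators produce event tables on a common schema
(`onset_s`, `duration_s`, `intensity_db`, `intensity2_db`, `change_s`,
`band_lo_hz`, `band_hi_hz`, `role`, `trial_index`). Conventions worth
stating explicitly:

* **Interval conventions.** "Inter-stimulus interval" is an
  offset-to-next-onset gap (6-s stimuli at a 3-s gap recur every 9 s);
  SOA-based paradigms use onset-to-onset spacing, as the name says. The
  2-s pause of the repetitive train is *inserted*: it adds to the
  nominal SOA (`pause_adds = FALSE` makes it replace the SOA instead).
* **Exact-ratio oddball.** Deviants are placed by randomizing the
  lengths of the standard runs that separate them, under the
  constraints that every run is at least `min_standard_run` long and
  each block opens with a full run. This makes the 10% deviant fraction
  and the role counts exact and deterministic per block — testable
  properties — rather than Bernoulli averages. After
  `n_deviants_per_block` deviants the two bands exchange roles. A
  maximum standard-run length is deliberately not enforced: nothing in
  the design requires one.
* **Many-standards control.** Exact per-band counts by balanced
  shuffle; the band physically identical to the oddball deviant is
  labeled `deviant_equivalent`. The default band set is ten 500-Hz-wide
  bands with lower edges 1000–5500 Hz; since a 500-Hz grid starting at
  1000 Hz cannot contain the 3250–3750 Hz oddball deviant band exactly,
  the deviant-equivalent defaults to the sixth band and both are
  parameters. No minimum spacing between deviant-equivalents is
  imposed.
* **Analysis standard.** Each deviant is paired with the stimulus
  `offset_trials` (default 3) positions earlier; because every deviant
  is preceded by at least four standards, the 3-back stimulus is always
  a standard inside a block. Deviants without a valid partner are
  skipped and counted in a message.
* **Time base.** Onsets are 64-bit seconds laid out on the sampling
  grid; all fixed-SOA paradigms keep onset differences at the SOA to
  floating-point accuracy.

## The synthetic dopamine response

The stimulus-locked response is a sum of smooth components in "kernel
units" — the z-score units in which the analysis reports features:

* onset-positive, onset-negative and offset-positive peaks are
  **asymmetric Gaussians** (separate rise/fall standard deviations)
  anchored to onset or offset. The field's data constrain latencies and
  amplitudes but not waveform shapes, so the shapes are a modeling
  choice. Default latencies/amplitudes: 96 ms / +0.224, 602 ms /
  −0.860, 549 ms / +0.744.
* the **intra-stimulus dip** is a boxcar over the stimulus passed
  analytically through the sensor kinetics (so it saturates with the
  sensor's time constants and relaxes after offset), scaled so its mean
  over the final second of a 6-s stimulus is −0.327.
* the **drop-positive** component after a mid-stimulus decrement of ΔL
  dB is an asymmetric Gaussian with amplitude `intensity_gain · |ΔL|`;
  the default gain, 0.744/40 z per dB, makes a −40 dB step match the
  offset-positive peak. Only decrements are modeled; the analysis and
  generator treat upward steps as unsupported.
* `deviant_gain` multiplies only the value-encoding components
  (onset-negative, dip) for deviant-role events, reflecting the view
  that deviance enhancement is carried by the aversive/value arm of the
  response rather than the alerting peak.
* `offset_relief_tau_s` (default 0.3 s) saturates the relief amplitude
  with the dwell time in the preceding state: brief 100–150-ms bursts
  produce only a weak relief peak (brief-stimulus recordings show the
  trough merging back to baseline with no separate offset peak), while
  0.5–5-s stimuli are near saturation, so the duration series is almost
  flat. Setting it to 0 gives a strictly duration-independent offset
  component, the configuration used for the duration-series null
  calibration.

**Component widths and superposition.** The onset-negative and
offset-positive widths default to 100/120 ms. This matters numerically:
components overlap, and a peak riding on the slope of another component
shifts by approximately slope/curvature. With these widths the composite
extrema stay within one 10-ms sample of the nominal latencies at the
default 100-Hz acquisition rate, which is what the parameter-recovery
tests assert. Wider troughs (≈180 ms) would push the offset peak about
one sample late purely through superposition with the relaxing dip.

## The sensor model

The sensor is a causal difference of exponentials,
`h(t) = exp(−t/τ_decay) − exp(−t/τ_rise)`. The decay constant is set
directly (default 700 ms — the slow return visible after transients;
only the rise is tightly constrained by the sensor literature). The
rise constant is *solved* so that the impulse response's 10–90% rise
time equals the requested value (default 70 ms), which makes the rise
time a calibrated, testable property rather than an indirect one.
`sensor_response()` convolves an input with `h` normalized to unit peak
(impulse → unit transient) or unit area (constant → constant).

## The recording model

`simulate_recording()` renders

```
excitation = B_exc(t) · (1 + dff_scale · k(t)) + a(t) + ε_exc
isosbestic = B_iso(t)                          + a(t) + ε_iso
```

with double-exponential photobleaching `B` per channel (defaults: 10%
and 20% fractions at τ = 60 s and 600 s), a shared common-mode artifact
`a(t)` (Ornstein–Uhlenbeck, sd 0.3 a.u., τ = 2 s) injected identically
into both channels, white measurement noise per channel (0.15% of
baseline), and `dff_scale = 0.05` fractional fluorescence per kernel
unit. The per-event ground truth (post-gain amplitudes, nominal
latencies) is attached to the recording for recovery tests.

The noise defaults describe a deliberately high-SNR bench recording:
with them, a subject's 10-trial average recovers component latencies to
within two samples and amplitudes to within 10%, which is the regime in
which parameter-recovery testing is meaningful. Real freely-moving
recordings are substantially noisier (per-sample noise of the same
order as the largest components); tests that specifically mirror
animal-data conditions (the duration-series null calibration) therefore
raise the simulated noise to that regime and say so.

Two emergent properties of this model are worth knowing:

* **Reference leakage.** The isosbestic fit is a single least-squares
  regression per session, and the dopamine signal itself participates
  in it. The fitted slope is therefore slightly biased away from the
  pure bleaching ratio, leaving a small bleach-shaped residual drift in
  ΔF/F even in noise-free simulations — visible as a slow monotone
  trend of a few hundredths of a z per trial. This is a faithful
  property of single-regression referencing, not a bug; the
  trial-stability test uses literally identical feature rows for its
  exactness check and a direct feature-level simulation for its type-I
  calibration for precisely this reason.
* **Common-mode rejection.** An artifact injected identically into both
  channels is attenuated by well over an order of magnitude in ΔF/F
  relative to a single-channel baseline computation, because the
  regression absorbs it into the fitted reference.

## Preprocessing choices

* The isosbestic regression is fit over the full session (segment-wise
  fitting was considered and not adopted: nothing in the target designs
  requires it, and a single fit is the conservative option).
* ΔF/F requires a strictly positive fitted reference and reports the
  first offending sample otherwise. A constant isosbestic channel
  degrades to an intercept-only fit with a message.
* z-scoring uses the unbiased (n−1) standard deviation, recorded in the
  output metadata. Global mode standardizes the whole session; local
  mode standardizes a ±3.2-s window anchored at a reference (deviant)
  onset, normalizing the *whole window once* so that the deviant and
  its 3-back standard (at −2.4 s, inside the window) share one local
  reference frame.
* Epochs are cut at half-open sample intervals with nearest-sample
  onset alignment (no sub-sample interpolation); events whose window
  leaves the recording are dropped with a count. The per-trial baseline
  is the mean over the 2 s preceding onset.

## Feature definitions

Per epoch, with windows half-open at the lower edge — "1–300 ms" is read
as (0, 300] and so on:

| feature | definition |
|---|---|
| onset-positive | max z in (0, 300] ms after onset |
| onset-negative | min z in (0, 800] ms after onset |
| offset-positive | max z in (0, 800] ms after offset |
| intra-stimulus dip | mean z over the final min(1 s, duration) |
| drop-positive | max z in (0, 800] ms after the level change |
| peak-to-trough | max − min over [0, SOA) after onset |

Ties break to the earliest sample. Amplitudes are raw z at the extremum
(negative for troughs); relative amplitudes subtract the immediately
preceding state (onset-positive peak for the trough, dip mean for the
offset peak). For stimuli shorter than 1 s the dip averages the whole
stimulus. The drop-positive window length mirrors the offset-positive
window by analogy and is configurable, since no measured value pins it.
The onset/offset ratio `onset⁺/(onset⁺ + offset⁺)` clamps negative
(noisy) amplitudes at zero to stay in [0, 1] and errors when both are
zero; recording sites project onto the ventromedial (ML 0, DV 8) →
dorsolateral (ML 8, DV 1.5) axis by scalar projection.

## Behavioral metrics

Length of stay accumulates dwell time per *condition* (not per physical
field), because the field–condition mapping reshuffles every session.
The Preference Index conditions at the same level:
`PI = Pr(Goal = X | Start ≠ X) − Pr(Goal ≠ X | Start = X)`, computed
per animal by default (matching per-animal summaries) with pooling as an
option. The behavioral simulator works at session granularity: shuffled
balanced mapping, uniform start field, goal field drawn proportionally
to condition attraction weights. Equal weights give PI = 0 in
expectation; for two conditions with weights (w, 1) the closed form is
PI = (w−1)/(w+1), which the tests verify by simulation. A trajectory
renderer (reflected random walk avoiding the central pillar) exists only
to feed the occupancy heatmap; the heatmap's pseudo-logarithmic color
scale is a display option, never part of the metric.

## Statistics

* **Wilcoxon signed-rank**: zero differences are dropped (the common
  convention; the design never produces meaningful zeros). For n ≤ 25
  the two-sided p is exact, computed from the full sign-assignment null
  of the signed-rank sum by dynamic programming over doubled midranks —
  so ties are handled exactly, which `stats::wilcox.test` declines to
  do. Above the threshold, a normal approximation with continuity and
  tie correction takes over; the two agree to < 0.01 at the boundary.
* **Friedman**: wraps `stats::friedman.test`, which already implements
  the midrank, tie-corrected statistic; the package's own rank-formula
  implementation lives in the test suite as an independent oracle. A
  table in which every subject ranks all conditions equally is refused
  as degenerate.
* **Conover post hoc**: pairwise statistics
  `t = |R_i − R_j| / sqrt( 2b(A1 − C1)/((b−1)(k−1)) · (1 − T1/(b(k−1))) )`
  on (b−1)(k−1) degrees of freedom, Bonferroni-multiplied and clipped
  at 1. On a fully tied table every corrected p is 1.
* **JZS Bayesian paired t-test**: BF₁₀ under a Cauchy prior (scale
  0.707) on the standardized effect, computed by adaptive quadrature of
  the inverse-gamma g-mixture representation on a log-transformed axis
  (relative tolerance 1e-10, overflow-guarded tails). The test suite
  checks it against an independent route — the noncentral-t likelihood
  integrated over the Cauchy prior — to 1e-6 relative, with a
  Gauss–Kronrod rule as a second opinion. Thresholds: BF > 3
  alternative, BF < 0.33 null, else inconclusive.
* **Spearman**: midrank correlation; exact permutation p for n ≤ 9,
  t approximation above.

## The end-to-end experiment and its calibration

`run_oddball_experiment()` composes the whole chain per synthetic
subject: oddball and many-standards sequences, rendered recordings,
isosbestic correction, local ±3.2-s z windows anchored at each deviant
(or deviant-equivalent) onset, 3-back pairing, per-role mean
peak-to-trough, then Wilcoxon (and optionally JZS) contrasts across the
cohort. Cohorts default to n = 21 subjects. The many-standards
deviant-equivalent is rendered with gain 1 by default — rarity alone
adds nothing — and the gain is configurable to test alternatives.

Problem sizes in the calibration tests are scaled for repetition: the
oddball blocks use 10 deviants (100 events, ~84 s of signal at 100 Hz)
so that a thousand replicate cohorts of 21 subjects are tractable, and
null-calibration runs skip the many-standards arm they do not use.
Under the null (gain 1.0) the deviant and its 3-back standard are
exchangeable slices of the same normalized window, and the measured
rejection rate sits at the nominal 5% within ±1.5%. With gain 1.5 the
deviant-vs-standard contrast is detected in essentially every cohort.

**A normalization artifact worth knowing about.** The shared-window
rule — z-score the deviant-anchored window once, cut both epochs from
it — has a side effect that high-SNR simulations expose: when the
deviant response is genuinely enhanced, it also inflates the standard
deviation of its own window, which *deflates* the paired standard's z
measure relative to a deviant-equivalent measured in a window with no
enhanced response in it. In a high-SNR cohort the
standard-vs-deviant-equivalent contrast therefore rejects far above
nominal rates — the acceptance suite asserts the null-rate expectation
and documents this failure honestly rather than hiding it. The artifact
scales with the share of window variance contributed by the enhancement;
in realistically noisy recordings, where per-sample noise dominates
window variance, it is far below detectability, which is why analyses of
animal data do not encounter it. Practical implication: with very clean
data, compare conditions normalized against windows of matched
composition, or z-score against a window that excludes the anchoring
response.

What the passing tests show, and what they do not: they establish that
the pipeline's arithmetic is correct (oracle-checked), that its
estimators recover known ground truth at the generator's noise level,
and that its tests are calibrated under the generator's null. They do
not establish robustness to motion artifacts beyond the common-mode
model, hemodynamic or pH confounds, wavelength-specific gains,
non-stationary noise, or sensor nonlinearity — none of which the
generator emulates.

## Known limitations

* One generic excitation/isosbestic pair is modeled; channel-specific
  spectral gains are out of scope.
* Bleaching is proportional between channels by default, so the
  single regression cancels it exactly; strongly channel-divergent
  bleaching would require segment-wise fitting (exposed as an option
  point but not the default).
* The behavioral simulator does not generate continuous trajectories
  for the PI (session granularity only).
* The intra-stimulus dip does not re-scale after a mid-stimulus level
  change; only the drop-positive component responds to the step.
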
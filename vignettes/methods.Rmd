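---
title: "Decoding spatial frequency across saccades: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Decoding spatial frequency across saccades: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sacdec)
```

## The scientific question

When the eyes jump, the retinal image of a stationary object jumps with
them: a grating seen in the left visual field before a rightward-to-left
saccade lands in the right visual field afterwards, so its cortical
representation moves from the right to the left hemisphere. How the visual
system maintains a usable, feature-specific readout across that hand-over
is a core question of trans-saccadic perception. The analysis implemented
here asks it with multivariate decoding of magnetoencephalographic (MEG)
sensor patterns: train a classifier to tell a low-spatial-frequency
grating (0.33 cycles/°) from a high one (1.33 cycles/°) under steady
fixation, then test it on saccade trials time point by time point. If the
presaccadic pattern remains decodable for a while after saccade offset
while the postsaccadic feedforward pattern ramps up, the two
representations overlap in time — a "soft handoff" rather than a
suppress-and-restart.

`sacdec` re-implements that analysis chain as a reusable, tested pipeline:
a ground-truth synthetic-data generator, oculomotor event detection,
rule-based epoch selection, event-related planar-gradient averages,
temporal-generalization decoding with diagonal-band readouts, and
group-level threshold-free cluster enhancement (TFCE) permutation
statistics. Every stage can be exercised without any external recordings.

## The experimental design being emulated

The design is a factorial change-detection task. Gratings vary in spatial
frequency (low/high), base orientation (±30° from vertical), phase
(0/π), and whether the orientation changes between the first stimulus
(S1) and the second (S2). In *Saccade* blocks the subject fixates a point
7° right of center, S1 appears centered 6° below the meridian (hence in
the left visual field), and a 14° leftward saccade brings it into the
right visual field; S2 replaces S1 during the saccade. One saccade block
crosses SF (low/high/none) × orientation × phase × change, twice each:
48 trials, of which 16 are no-stimulus saccade trials (the `none` cells).
In *Fixation* blocks the subject holds either fixation point, S1 is shown
for 0.5–0.7 s, blanked for a normally distributed 55 ± 6 ms (truncated to
42–75 ms and quantized by the 120 Hz display refresh), and S2 follows;
with fixation side in the factorization a block has 32 trials. Thirteen
saccade blocks give 416 stimulus and 208 no-stimulus trials.
`build_design()` reproduces these counts exactly and shuffles within
block by seed.

## The synthetic-data generator

The generator is a forward model with full ground truth, not a fixture:
its parameters define the study conditions that all downstream tests and
acceptance checks run under.

**Timing.** Saccade latency is drawn from a truncated lognormal whose
median defaults to 226 ms — the group median the design targets — with
log-scale spread 0.35 and truncation to [0.10, 1.0] s. The latency
distribution family is a modeling choice (latency distributions are
right-skewed); only the median is a fixed design target. Saccade duration follows a
main-sequence rule `duration = 27 ms + 2.5 ms/° × amplitude`, so the
required 14° saccade lasts 62 ms. The intercept/slope pair is chosen to
land on a 62 ms duration at 14° while staying within the range of
published main-sequence fits.

**Eye traces.** Gaze sits at the trial's fixation point with slow jitter
(white noise smoothed over 25 ms, SD 0.05°) — smoothing matters, because
the saccade detector thresholds on a robust velocity SD, and
physiological drift is far smoother than sample-wise white noise. The
saccade itself has a raised-cosine velocity profile; its executed
horizontal amplitude is drawn around 13.1° (saccades to targets are
systematically hypometric). Traces are delayed by the 7 ms
converter lag that `apply_clock_correction()` later removes, so the
correction is exercised against a real misalignment. Microsaccades can be
injected at a Poisson rate during fixation to exercise the
fixation-epoch exclusion rule.

**Sensor patterns.** Each (spatial frequency, stimulated hemifield) pair
has a fixed unit-norm topography over the planar-gradiometer channels: a
Gaussian spatial profile centered on the hemisphere contralateral to the
stimulus, multiplied by a seeded random per-channel modulation so that
the two SFs within a hemisphere stay linearly discriminable. A stimulus
drives its topography with an envelope that is zero until the 40 ms
response latency, rises to a transient peak 30 ms later (70 ms
post-event, echoing where decoding peaks), sustains at 0.7 of the peak
while the stimulus is on, and ramps off over 20 ms. On saccade trials the
presaccadic topography stays active until `t_persist` (default 200 ms)
after saccade offset — the planted handoff — while the postsaccadic
topography starts 40 ms after saccade offset. A spatially broad,
SF-independent saccade-locked component is added on saccade trials;
no-stimulus trials contain only noise plus that component. Noise is
stationary 1/f-weighted Gaussian, unit SD per channel.

**Signal-to-noise.** The default evoked amplitude is 3 noise-SDs along a
unit-norm topography. That is deliberately optimistic relative to real
single-trial MEG (where group peak decoding sits near 0.62): the
generator's role is to validate the pipeline's logic — calibration,
error control, parameter recovery — with crisp planted effects at a few
hundred trials, not to reproduce empirical effect sizes. What passing
tests show about real data is therefore that the *machinery* is correct,
not that real decoding will be this strong.

**Scale.** The desk-scale default array is 32 sites × 2 orthogonal planar
gradiometers (64 channels) on a grid layout; a 102-site/306-channel
array (with magnetometers) is a constructor option. Sensor synthesis runs
at 500 Hz by default and analyses at 250 Hz, matching the analysis chain
the pipeline implements while keeping a full simulated session in memory.

## The measurement chain

`detect_saccades()` implements the classic median-based velocity
algorithm: a 5-point smoothed derivative per axis, robust SD
`sqrt(median(v²) − median(v)²)`, elliptic threshold at λ = 6 robust SDs,
merging of events separated by less than the 40 ms minimum fixation, and
removal of events shorter than the 10 ms minimum saccade duration. λ and
the smoothing window are exposed as parameters (only the duration
constraints are fixed by the protocol); events cannot be detected within two samples
of the trace boundary where the velocity estimate is undefined. The onset
convention is the first sample of the supra-threshold run.

`ternarize_photodiode()` reduces the photodiode trace to
black/gray/white via four evenly spaced boundary values spanning the
signal's range, inclusive of min and max, with the 2nd and 3rd values as
class boundaries; display events are the time points where the ternary
code changes. Alternative readings of "four linearly separated values"
differ only in boundary placement; this one is the default and the
boundaries are plain arithmetic on min/max, so any other convention is a
one-line change.

Epochs are cut half-open, `[event − 0.5 s, event + 1.5 s)`, always
containing the `t = 0` sample; downsampling applies a zero-phase FIR
anti-alias filter (cutoff 80% of the new Nyquist, reflection-padded, unit
DC gain) and keeps the decimation phase that preserves `t = 0`.
Baseline standardization is per trial and per channel over `[-0.2, 0)`
(the conventional window, read as half-open; the SD is floored at 1e-8), with
a subtract-only mode for event-related averages. Saccade-condition epochs
are kept only if there is exactly one saccade between S1 and S2 onset,
the endpoint crossed the vertical midline by ≥ 4° in the saccade
direction (x ≤ −4°, stimulus fully switched hemifields), the endpoint
stayed above −2° (stimulus fully in the lower field), and saccade latency
lies in [0.15, 0.50] s; fixation epochs require gaze within 2° of the
fixation point throughout and no microsaccade above 0.5°. Every exclusion
is logged with its rule id, so kept + rejected always equals the input
count. Re-alignment to saccade offset re-cuts `[-0.6, 0.4)` inside the
standardized epochs (re-baselining over `[-0.1, -0.004)` is available for
the event-related-field path; the decoding path keeps the stimulus-locked
standardization throughout).

Event-related fields average per channel first, then combine each site's
gradiometer pair as a pointwise Euclidean norm, then subtract the
baseline mean — in that fixed order; a per-trial combination mode exists
for comparison only.

## Decoding

Classification uses linear support-vector classifiers with cost fixed at
1 (linear SVMs at fixed small cost are the field's
default) and no feature rescaling beyond the epoch standardization.
Features at each time point are all channels × a temporal searchlight of
±2 samples at 250 Hz (±8 ms). An alternative reading of the 8 ms radius
as "10 neighboring timepoints" conflicts with ±2 samples; the explicit
two-samples-at-250-Hz convention is implemented. Time points
whose window exceeds the epoch are dropped, not padded.

Within-condition decoding is 10-fold stratified cross-validation with
the training partition balanced by seeded subsampling of the majority
class, redrawn per fold; balancing can additionally be stratified on a
second design factor (change presence). Cross-condition decoding trains
one classifier per training time on all balanced training trials and
evaluates it at every test time of an independent condition — no
cross-validation, since train and test conditions share no trials. The
four per-subject generalizations are train {Fix-LVF, Fix-RVF} × test
Sac-LVF aligned to {S1 onset, saccade offset}. Classifier ties (decision
value exactly 0) go to the class with the lower label id; fold
assignment and balancing are keyed to each class's *member set* rather
than its name, which makes the whole pipeline exactly invariant under
swapping the class labels.

Diagonal bands average matrix cells within ±10 ms of a (possibly
shifted) diagonal — five cells at 250 Hz for the default 20 ms width.
The third, saccade-shifted diagonal puts its train-side origin at S1
onset plus the subject's median saccade latency plus median saccade
duration, computed per subject from retained trials, so the band compares
equal "time since the stimulus entered the current hemifield".
Accuracies enter group statistics as empirical logits
`ln((k + 0.5)/(n − k + 0.5))` — chance maps exactly to 0 and perfect
scores stay finite (the +0.5 empirical-logit correction is this
package's choice of zero-cell handling). The no-stimulus bias analysis
applies the fixation-trained
classifiers to Sac-noVF trials aligned to saccade offset and reports the
proportion of trials classified as high-SF; an unbiased pipeline stays
at 0.5.

`last_significant_time()` reads the planted persistence off the shifted
diagonal as the last test time whose proportion correct exceeds chance by
three binomial standard errors. Under the default conditions this
recovers `t_persist` to within the band width plus the envelope fall
time (±40 ms tolerance in the acceptance suite).

## Group statistics

Subject-level maps (log-odds for accuracies) are tested against 0 with
one-sample t statistics, enhanced by TFCE
(`TFCE(p) = Σ_h extent(h,p)^E · h^H · dh`) with E = 0.5, H = 2 and
`dh = max|t|/100` — the customary defaults for this enhancement — and
corrected by the max-statistic null over whole-subject
sign flips: two-tailed via the maximum absolute enhanced value,
`p = (1 + #{perm max ≥ observed}) / (n_perm + 1)`, 10⁴ permutations by
default, with an exhaustive-enumeration mode for small groups. Adjacency
combines the two stated neighborhood rules conservatively: points are
neighbors iff they share a sensor within 8 ms, or are Delaunay-adjacent
sensors at the identical time; with one "sensor" this reduces to the
purely temporal clustering used for decoding time courses. The observed
t-map is computed through the same vectorized arithmetic as the permuted
maps so that sign patterns reproducing the data tie with it exactly —
otherwise float noise can break ties anti-conservatively in tiny groups.
Zero-variance points are signalled and masked rather than divided by.

Numerical notes: the TFCE integration runs over 100 height steps by
default (the isolated-peak value then matches the closed-form Riemann sum
to machine precision, and the continuum value t³/3·(extent 1) to ~1%);
the E = 0, H = 0 limit recovers the statistic itself and is tested.

## Behavior

Change-detection sensitivity is `D' = Φ⁻¹(HR) − Φ⁻¹(FAR)` with
Laplace-style correction `(n + 0.5)/(N + 1)` on both rates (an add-half
correction was chosen over 1/(2N) clipping; both are common). A minimal
equal-variance observer model with configurable d′ per condition
generates responses so the summaries have recoverable ground truth.
Saccade latency/amplitude summaries exclude latencies outside
[0.15, 0.50] s before taking medians. Bayes-factor ANOVAs are out of
scope; the module emits the tidy per-subject table such software
consumes.

## Problem sizes and reproducibility

All randomness flows through one seeded generator; identical
configuration and seed reproduce every numeric output bit-exactly
(`run_pipeline()` is tested for this). The test and acceptance suites run
at desk scale, chosen so the full suite completes on a single CPU:
32-site arrays, 100–200 trials per condition for decoding checks, 200
replicate null datasets with 500 permutations each for the familywise
error-rate calibration, and ten seeded runs for the persistence
parameter-recovery sweep. The demonstration configuration of
`run_pipeline()` (4 subjects, desk-scale array, reduced block counts) is
sized the same way; the full experimental design (13 + 13 blocks, 10⁴
permutations) is a configuration change, not a code change.

## Known limitations

* The generator's evoked model is a fixed-topography, rank-one-per-source
  forward model with stationary noise: no cortical dynamics, no
  trial-to-trial topography variability, no eyeblink/cardiac artifacts,
  no saccadic spike field by default (an optional saccade-onset artifact
  aligned with a chosen topography exists to probe the bias analysis
  adversarially).
* Orientation and phase are carried in the design but evoke no signal;
  they exist to demonstrate the chance-level outcome on signal-free
  labels, mirroring the negative findings the analysis chain must be able
  to produce.
* Visual artifact inspection cannot be reproduced; a threshold rule
  stands in for it and is disabled by default on clean synthetic data.
* Vendor MEG file formats are not read; the pipeline starts from arrays
  and tibbles, and the text-based serialization in `R/io.R` is for
  fixtures and audits, not raw-data interchange.
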
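---
title: "Methods: simulating and analysing PPS-perturbation EEG"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: simulating and analysing PPS-perturbation EEG}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(ppspace)
```

## The experimental model

The package models a within-subject sensorimotor paradigm probing the
peripersonal space (PPS) of the face. Each session is a sequence of 150
twenty-second holds of the right forearm in one of three positions — `p0`
(hand on the thigh, ultrafar), `p1` (between thigh and face), `p2` (~4 cm
from the face) — in random order with exact balance (50 per position) and no
immediate repetition. One brief median-nerve stimulus is delivered 8–12 s
(uniform) into every hold. A control scenario replaces the three
hand-to-face distances with three arm angles in a horizontal plane (`a0`,
`a45`, `a90`), all equidistant from the face, keeping montage and timing
identical so that only the condition–effect structure differs.

The scientific contrast of interest: if nearby space is coded in
body-part-centred coordinates with top-down control, stimulus-locked
spectral perturbations in frontal theta and beta should grow with
hand-to-face proximity, whereas a general arousal-like centroparietal alpha
response should not depend on position and should survive in the control
task.

## The forward model (what the generator emulates)

Per channel, the background is a Gaussian process with a 1/f power spectrum
restricted to 0.3–45 Hz — the canonical resting-EEG shape — synthesized in
the frequency domain and scaled to a per-channel rms. On top of it, each
stimulus triggers additive oscillatory bursts on all channels of one
electrode pool: a Hann-tapered sinusoid with a per-event random phase, so
that energy is induced without phase-locking (the quantity an ERSP isolates,
as trial-averaged evoked components cancel). Defaults:

| burst | centre | window (s post-stim) | pool | amplitude (µV) by condition |
|-------|--------|----------------------|------|------------------------------|
| theta | 5.5 Hz | 0.1–0.7 | frontal | p0 2.5, p1 6, p2 10 |
| beta  | 20 Hz  | 0.7–1.5 | frontal | p0 2, p1 10, p2 18 |
| alpha | 10 Hz  | 0.1–2.8 | centroparietal | 3 everywhere |

The control scenario keeps only the alpha burst, identical across
conditions. Subjects differ by a multiplicative gain on all burst
amplitudes, drawn from N(1, 0.2²) truncated at 0.3 — amplitude scaling
varies across individuals while the ordering of conditions is preserved.

Artifacts are injected with ground-truth bookkeeping: every contaminated
trial and its kind are recorded in a ledger, so rejection can be validated
exactly. Three kinds are generated, each engineered to trip exactly one
rejection rule (a frontopolar-dominant 300 ms blink, an EOG-confined 500 ms
eye movement, and an in-band 25 Hz 100 ms transient on a posterior channel
inside the 0–800 ms post-stimulus window). Default per-trial probabilities
(0.10/0.04/0.03) yield roughly 125 clean trials out of 150, the yield
typical of awake-EEG sessions of this length.

### Calibration of the defaults

Two constraints pull in opposite directions. Effect recovery at desk scale
(12-subject cohorts with 6 trials per condition) needs single-trial
log-energy effects of order one; the fixed rejection thresholds (±60 µV on
Fp1/Fp2 and on any channel post-stimulus) cap absolute signal excursions.
Because log-scale effects depend only on the burst-to-background *power
ratio* while rejection depends on absolute µV, the package resolves the
tension by setting the background rms to 6 µV (a desynchronised awake
background; 10 µV would be equally defensible physiologically but leaves too
little headroom) and choosing burst amplitudes so that worst-case excursions
(high-gain subject, near position, noise peak) stay below threshold. With
these defaults the strongest bursts change band energy by ~1–3 log units
inside their window, and a 12-subject cohort recovers the full qualitative
pattern — distance-dependent theta and beta, distance-independent alpha —
in ≥ 90% of seeded replicates, while a 50-subject cohort reproduces it with
very large margins. The amplitudes were fixed once, from this reasoning plus
a small seed sweep, and are not adjusted per analysis.

What the generator does **not** emulate: volume conduction and channel
covariance (bursts are confined to their target pool; real scalp fields
spread), realistic blink morphology and ocular spectra, line noise and
electrode drift, non-stationary background (the 1/f level is constant within
a session), phase-locked evoked components, and any somatosensory-evoked
potential. Consequently, passing tests demonstrate that the *analysis
machinery* is correct and sensitive under the modelled conditions — not that
the pipeline would behave identically on real recordings, where pool
leakage and correlated noise would blur the sharp pool specificity seen
here.

## Preprocessing

Filtering is zero-phase with the squared-magnitude response of a Butterworth
cascade (2nd-order high-pass at 0.3 Hz, 4th-order low-pass at 45 Hz),
applied in the frequency domain after mirror-padding the recording by 8 s.
This has exactly the magnitude response a forward–backward (filtfilt)
application of the cascade would have — monotone passband, ≥ 24 dB one
octave outside the band — without its edge transients, and preserves
stimulus-locked latency, which matters because rejection windows and burst
windows are defined relative to the stimulus.

Epochs span [-6, 6) s around each stimulus (6144 samples at 512 Hz); events
closer than 6 s to a recording edge are skipped with a warning. Rejection
thresholds are read **relative to the trial's pre-stimulus mean** over
[-6, 0] s per channel — the reference window is a package choice, since
"relative to baseline" alone does not define one — and the blink/EOG rules
are applied over the whole epoch while the ±60 µV any-channel rule is
confined to the stated 0–800 ms post-stimulus window. When several rules
match, the recorded reason follows the precedence blink > EOG >
post-stimulus amplitude. ICA-based artifact identification is deliberately
not implemented: without stated component-selection criteria any rule would
be arbitrary, and the ledger-validated threshold rejection already provides
an exact ground-truth test of the exclusion bookkeeping.

## Spectral decomposition

Morlet wavelets with 7 cycles at every frequency (σ_t = 7/(2πf)), on a
3.5–30 Hz grid in 0.5 Hz steps — 0.5 Hz resolves the 3.5 Hz lower theta
edge; 7 cycles is the canonical compromise between time and frequency
resolution for this band range. Kernels are truncated at ±3.5 σ_t and
normalised so that a sinusoid of amplitude A yields squared-magnitude A² at
its centre frequency (amplitude-squared-envelope convention; the tests pin
this against an independent band-pass + analytic-envelope oracle, and the
expected f-proportional white-noise response is also tested).

Numerical choices:

* **Decimation.** The epoch is decimated ×4 (to 128 Hz) before convolution
  by plain subsampling — alias-free because the signal is already
  band-limited to 45 Hz < 64 Hz. This bounds the FFT cost without touching
  energies below 30 Hz.
* **Edge handling.** Epochs are mirror-padded by one maximal wavelet
  half-length (1 s at 3.5 Hz) before convolution, because the baseline
  window [-6, -4] s sits at the epoch edge and would otherwise be dominated
  by edge roll-off. The outer 2 s of the epoch are additionally flagged as
  edge regions; the flags are informational (the trend fit keeps its full
  [0, 6] s domain, where only the last second touches the flagged region
  and the mirror padding keeps it usable).
* **Time binning.** Energy is averaged into 50 ms bins (240 per epoch),
  matching the ~100 ms granularity at which effect windows are defined and
  bounding memory.
* **Band edges.** Bins on a shared band edge (8, 12 Hz) belong to the lower
  band, making the theta/alpha/beta partition disjoint.
* **Pooling and log.** Linear energy is averaged over pool channels and
  in-band frequency bins first, then log-transformed per trial (pooling
  after the log would weight channels multiplicatively); the log is floored
  at 10⁻¹² µV² for numerical safety.

Baseline correction subtracts, per trial, pool and band, the mean log energy
over [-6, -4] s; ERSPs are per-condition trial means of the corrected
courses. The pre/post comparison contrasts mean [-4, 0) s against [0, 6) s
energy and is computed on `pre - post`, so a **negative t indicates a
post-stimulus energy increase**.

## Trend features

Each trial's corrected [0, 6] s course, per pool and band, is summarised by
a least-squares quadratic in time centred at 3 s. The centring is forced by
the feature definitions themselves: it makes the intercept literally the
fitted energy at 3 s post-stimulus, the slope the linear tendency, and the
quadratic coefficient the curvature (positive = U-shape, negative =
inverted U). The fit is exact for noise-free quadratics (tested to machine
precision) and equals the raw-time fit through the algebraic identity
b0 = b0' + 3 b1' + 9 b2'. Three features × three bands gives nine responses
per (trial, pool); all nine are computed and analysed — the package does not
collapse them into six.

## Statistics

* **Sign-flip permutation paired t-test.** The exact null for a symmetric
  paired design; 2000 permutations by default with the add-one rule
  p = (b+1)/(m+1), so p ∈ [1/(m+1), 1] and a zero p-value is impossible.
  Because the sum of squared differences is invariant under sign flips, the
  permuted t is a function of the permuted mean alone, which makes the
  2000-draw null a single matrix product. Degenerate input (all differences
  zero) reports t = 0, p = 1 with a flag.
* **FDR.** Benjamini–Hochberg over the family of all 4 × 3 pre/post tests
  of one run.
* **Within-subject ANOVA.** Two-way (electrode pool × distance) on
  per-subject cell means, each effect tested against its own
  subject-interaction error stratum, no sphericity correction (matching the
  uncorrected dfs (3, 147), (2, 98), (6, 294) at n = 50). Trial-level rows
  are averaged into cell means first; incomplete designs error, naming the
  missing cell.
* **Post-hocs.** All pairwise paired t-tests on subject means with
  Bonferroni adjustment (p × 3, capped at 1).
* **Unpaired contrasts.** Welch's t by default for between-condition ERSP
  magnitude comparisons (pooled-variance available by flag).

Aggregation order is trials → subject means → group tests: subjects are the
exchangeable units, and the reported dfs at n = 50 imply subject-level
analysis. The run summary calls a band "distance-dependent" when the
distance main effect is significant for **at least 2 of its 3** trend
features. This stability rule keeps a single stray feature — expected at
rate α under the null — from flipping a band's call in either direction;
with it, a null band is miscalled in well under 1% of runs while a band with
a real effect loses its call only when two of three features fail at once.

A simulated subject who ends with zero clean trials in some condition (rare
under the defaults, but possible through artifact clustering) is replaced by
a freshly seeded one, deterministically — mirroring the replacement of
unusable participants in real cohorts and keeping cell counts and ANOVA dfs
exact.

## Problem sizes

The default configuration reproduces the full design (50 subjects × 150
trials); the `fast` profile (12 subjects, 6 holds per position) is the desk
and test scale. The packaged tests validate the oracle-checked operations at
small n (enumeration at 8 pairs; ANOVA against an independent error-strata
decomposition at 3–7 subjects; 1000-instance oracle sweeps), the df
structure at 50 subjects with 4 holds per position, and the qualitative
pattern over 20 seeded fast-profile cohorts per scenario.

## Known limitations

* Pool-confined bursts make pool specificity sharper than volume-conducted
  reality; between-pool leakage in real data would attenuate it.
* The permutation and FDR machinery treats the 12 pre/post tests as one
  family; with one strong true effect present, Benjamini–Hochberg still
  admits a stray second discovery in roughly 9% of null-heavy runs — the
  price of FDR control, visible in the control-scenario replicates.
* The beta response is modelled as an additive (synchronising) burst; beta
  reactivity in sensorimotor paradigms can equally present as suppression.
  The pipeline's statistics are sign-symmetric, so only the sign of the
  pre/post t, not any conclusion about distance dependence, rests on this
  choice.
* The trend-feature geometry makes some features intrinsically less
  sensitive to early brief bursts (an effect confined to 0.1–0.7 s loads
  weakly on the fitted value at 3 s), which is why band calls aggregate
  across features.
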
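---
title: "Methods: direction-resolved EMG–torque analysis of steering"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: direction-resolved EMG–torque analysis of steering}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(steerlimb)
```

## The problem and the data model

When a driver steers, shoulder and arm muscles act as agonists for one
rotation direction and antagonists for the other. Given synchronized
recordings of 10 surface-EMG channels, the steering torque `T(t)`
(N·m, positive defined here as clockwise effort) and the steering
angle, we want, per muscle and per steering direction: how strongly the
muscle's activation tracks the torque, how large its activation is, how
much it contributes relative to the other muscles, how far its
activation leads or lags the torque, and how smooth the resulting
steering is. Trials are labeled by arm mode (`both`/`single`), task
(`active` target following vs `passive` disturbance rejection) and hand
position (3 o'clock `0300`, 10:10 `1010`, 12 o'clock `1200`, 1:30
`0130`).

The angle channel is carried through I/O but unused by the analysis:
every direction-resolved statistic conditions on the torque, whose sign
is the direction cue. The clockwise-positive sign convention is pinned
package-wide and recorded in each trial's metadata sidecar so importers
of data with the opposite convention can flip on read.

## Envelope extraction and why it is zero-phase

Activation envelopes are computed per channel as band-pass
(20–450 Hz) → full-wave rectification → low-pass (6 Hz), the standard
linear-envelope pipeline for surface EMG. All filters are implemented
as real-masked FFT filters (raised-cosine transition bands, reflect
padding): a real symmetric frequency mask has exactly zero phase, so
the envelope is not shifted in time relative to the raw signal. This
matters because the delay analysis interprets the lag of the
correlation maximum causally; any filter group delay would add directly
to the estimated lead/lag. (No IIR filtering library is assumed; the
FFT mask plays the role a forward–backward Butterworth would.)

Corner defaults (20, 450, 6 Hz) are the field's conventions, not values
taken from any particular study protocol — the concrete acquisition
settings of the motivating experiments live in supplementary material
that is not public, so every conditioning parameter is exposed in
`preprocess_params()`. Normalization defaults to trial-maximum (peak of
the envelope = 1), because maximal-voluntary-contraction calibrations
are not generally available; `reference_value` normalization is
provided for users who have them. Trial-max normalization makes
amplitudes comparable across channels of one trial but compresses
between-subject amplitude differences — a known trade-off.

## Direction segmentation

Episodes are maximal runs where the torque exceeds a dead band
`±θ` (default 5 % of the trial's maximum |torque|), kept only if at
least 0.5 s long. The dead band plus the minimum duration act as
hysteresis: the raw sign of the torque chatters near zero crossings,
and labeling those samples would dilute both the correlation and the
amplitude statistics. Segmentation is label-antisymmetric by
construction (negating the torque swaps cw and ccw with identical
boundaries), which the test suite asserts as a property.

## Correlation, amplitude, contribution

For direction *d*, the correlate is the torque *magnitude* |T|
restricted to *d*-episodes: within a direction, effort scales with
magnitude, and sign is already conditioned on. Episodes are
concatenated with per-segment mean removal (so offsets between episodes
cannot inflate the correlation), and

  r_d = max over |τ| ≤ 1 s of ρ(envelope, |T|; τ), clipped at 0,

the maximum of the normalized (per-window mean-removed Pearson)
cross-correlation. Using the max over a bounded lag window rather than
zero-lag Pearson makes the correlation readout and the delay readout
two projections of the same function, so a muscle that leads the torque
by 400 ms is not penalized in its correlation. Anticorrelations are
reported as 0: the agonist/antagonist relationship is already captured
by the direction split. A muscle is *strongly coupled* when r strictly
exceeds 0.75.

The amplitude `a_d` is the mean normalized envelope over *d*-episodes,
and the contribution ratio integrates both readouts:
`c_i = r_i a_i / Σ_j r_j a_j ≥ 0`, summing to 1 across the 10 muscles
of a direction. With identical muscles it is exactly 0.1 each; with a
single dominant muscle it approaches 1.

Direction dependence of the correlations is tested per muscle with a
two-sided paired sign-flip permutation test on the mean of
`r_ccw − r_cw` across subjects (exhaustive for n ≤ 14, otherwise
10 000 Monte-Carlo flips with a fixed seed, counting the observed
labeling). The permutation test was chosen over a paired t-test because
it is exact at small cohort sizes and assumption-light; across the 10
muscles both raw and Holm-adjusted p-values are reported, adjustment
offered but not forced.

One genuinely open choice: whether to correlate per steering event and
average, or on concatenated episodes. Concatenation is pinned
(`per_event` behavior is not implemented) because single episodes of a
fraction of a second provide too little data relative to a ±1 s lag
window.

## Time delay

`estimate_delay()` returns the lag of maximum *absolute* normalized
cross-correlation between envelope and |T|, with the sign convention
that a negative delay means the muscle's activity precedes the torque
(neuromechanically expected: electromechanical delay plus limb
dynamics), and a positive delay means the activation trails the torque,
the signature of co-contraction against an externally imposed torque.
Ties are broken toward the smallest |τ| — the most conservative causal
claim — and an optimum sitting on the window edge sets a boundary flag
(the window, default ±1 s, is then likely too small).

The pipeline estimates delays on the **whole trial** rather than on the
concatenated labeled span. This deviates from the otherwise natural
"pooled labeled span" choice for a measured reason: concatenating
segments creates artificial joins, and a lagged copy shifted across a
join decorrelates, which attenuates the correlation at large lags and
biases |τ| low (injected 500 ms leads were recovered at ≈ 480 ms pooled
vs 500 ms whole-trial). With the default 5 % dead band the two spans
differ by only a few percent of samples, so nothing of the direction
conditioning is lost; `estimate_delay(segs = ...)` still accepts a
restriction for users who want a per-direction delay.

Correlation and delay run at `analysis_fs = 100` Hz (envelope and
torque decimated with an anti-alias low-pass at 40 Hz): a 6-Hz-bandwidth
envelope is grossly oversampled at 1 kHz, the lag grid of 10 ms is well
inside the reporting tolerance, and the O(lags × samples) kernels get
100× cheaper.

## Smoothness

Two regularity metrics, both on the torque only, both "lower is
smoother":

- **Approximate entropy** (Pincus): with templates of length m,
  `C_i^m` = fraction of templates within max-norm tolerance `r_tol` of
  template *i* (self-match included), `Φ^m` = mean log `C_i^m`, and
  `ApEn = Φ^m − Φ^{m+1} ≥ 0`. Defaults m = 2, `r_tol = 0.2·SD` — the
  canonical parameterization; SD-relative tolerance makes ApEn
  invariant under affine transforms of the signal. ApEn is computed on
  the torque decimated to 100 Hz: at 1 kHz successive samples are
  trivially similar and ApEn collapses toward 0 for any signal; the
  decimation rate is a parameter. A constant series returns 0 with a
  degenerate flag.
- **Sliding SD**: the mean over window positions of the sample SD
  (n−1 denominator) in a 0.5-s window, stride 1 (stride configurable
  for speed). Exactly 0 on constant input and positively homogeneous.

The motivating study's ApEn (m, r) and SSD window are not public, so
absolute values of these metrics are not claimed reproducible — only
between-condition *orderings* (noisier torque ⇒ larger metric), which
is what the tests assert.

## The synthetic cohort: what it emulates and what it does not

Because no public recordings exist, `generate_cohort()` builds trials
with known ground truth:

- **Torque.** Active task: `A(sin ωt + 0.5 sin 3ωt)` with period 10 s
  and A = 2 N·m — zero-mean, sign-balanced (odd harmonics), alternating
  cw/ccw episodes, peak ≤ 1.5 A. Passive task: Gaussian disturbance
  low-passed at 0.5 Hz, rescaled to SD A/2. The real disturbance
  spectrum is unknown; band-limited noise is a stand-in, not an
  inference about the apparatus.
- **EMG.** Per muscle, true envelope
  `e(t) = b + g_cw max(T(t+d), 0) + g_ccw max(−T(t+d), 0)` — the
  advance by the lead time d implements "activation precedes torque" —
  multiplied by a unit-variance 20–450 Hz Gaussian carrier:
  envelope-modulated band-limited noise, the standard phenomenological
  surface-EMG model. Baseline b = 0.02 mV keeps silent muscles at a
  realistic noise floor. Defaults: fs = 1 kHz, 60 s, gains in
  [0.1, 1.0], leads 0–450 ms, 10 % between-subject variability
  (log-normal on gains so they stay positive, additive Gaussian on
  delays), seed-derived per-subject substreams so a fixed seed yields a
  byte-identical cohort.

What a green recovery test establishes: the pipeline recovers injected
coupling strength, direction asymmetry and lead times from realistic
SNR at this trial length. What it does not: real EMG nonstationarity
(fatigue, electrode drift), motion artifacts, ECG contamination,
nonlinear activation–force dynamics, or inter-muscle crosstalk — none
of which the generator models.

A consequence of the multiplicative-carrier model worth stating
explicitly: Pearson correlation is scale-free, and envelope-estimation
noise is proportional to the local envelope, so *any* muscle with
torque coupling well above the baseline envelope correlates near 1
regardless of its gain. Direction-*asymmetric* correlation patterns
like those seen in passive steering (agonist r ≈ 0.8, antagonist
r ≈ 0.3) therefore require the weak direction's coupling to sit at or
below the noise floor set by the baseline b — a near-silent antagonist.
The asymmetric test scenarios use gains 0.01 vs 0.001 against b = 0.02
for exactly this reason (derived from the noise-floor calculation, not
fitted to test outcomes).

## Numerical choices and degenerate inputs

- Result/trial CSVs serialize numerics with 17 significant digits:
  round-trips are lossless to < 1e-12. Schema tags ride as `#` comment
  lines.
- Zero-variance inputs: correlation and delay raise a degeneracy error
  (a truly constant envelope cannot be correlated); ApEn returns 0 with
  a degenerate flag; SSD returns 0. All-zero envelopes cannot be
  trial-max normalized (error).
- The SSD cumulative-sum implementation clamps tiny negative variances
  from cancellation at 0, preserving "exactly 0 on constant input".
- Permutation p-values are never 0: the exhaustive branch includes the
  identity relabeling; the Monte-Carlo branch adds the observed
  labeling to numerator and denominator.
- Cohort generation keeps derived seeds below 2^31.
- Batch runs isolate faults: a corrupt trial is logged in
  `manifest.csv` and the remaining subjects are summarized.

## Known limitations

- `per_event` correlation (event-wise averaging) is not implemented.
- Trial-max normalization limits between-subject amplitude comparisons.
- The FFT filters assume the whole trial is in memory; no streaming.
- Frequency-domain coupling (coherence), muscle-synergy decomposition
  and spectral-arc-length smoothness are out of scope by design.
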
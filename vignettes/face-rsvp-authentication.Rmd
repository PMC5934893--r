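---
title: "EEG identity authentication from self-face RSVP: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{EEG identity authentication from self-face RSVP: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

rsvpauth implements an EEG-based identity-authentication pipeline built on
the self-face rapid serial visual presentation (RSVP) paradigm. A user
watches a stream of face images — their own face mixed with other faces at
a 300 ms stimulus-onset asynchrony — while 16-channel EEG is recorded. The
brain's response to one's own face differs reliably from the response to
other faces (an N250-like component modulated by self-relevance), and that
self/non-self contrast is idiosyncratic enough to act as a biometric
signature. The package covers the whole chain: paradigm scheduling, a
synthetic-EEG generator, the acquisition signal chain, subject-specific
channel selection, a two-stage linear classifier (HDCA), and the
authentication metrics.

## The paradigm and its data layout

A session is 20 blocks of 10 trials; each trial presents 1 self-face and 9
non-self-face images for 300 ms each, in randomized order, so a subject
contributes 200 trials (2000 stimulus events). Within a block all trials
re-use the same 10 images in different orders. `generate_schedule()`
produces this event stream; onsets within a trial are spaced by exactly
the SOA, and every trial contains exactly one self event.

Two quantities the protocol fixes downstream: classification operates on
averages of two adjacent trials (100 authentication units per session,
each unit representing 6 s of stimulation), and the analysis rate after
decimation is 600 Hz, giving 600 post-stimulus samples in the 0–1000 ms
epoch window.

The paradigm leaves two timing gaps unspecified; the package declares them
rather than inferring them: 1 s between a trial's last image offset and
the next trial's onset (so response overlap comes only from the
within-trial SOA), and a 10 s rest between blocks (no analytical effect).

## The synthetic-EEG generator

Every downstream stage is testable without recorded data through a
generator that emulates the paradigm's qualitative ERP structure:

* **Component model.** ERP components are monophasic deflections with a
  Gaussian temporal envelope — amplitude (µV), peak latency (s), envelope
  SD (s) — and a 16-channel topography of gains in [−1, 1]. Gaussian
  envelopes keep oracles analytic: every simulated epoch is a closed-form
  expression plus noise.
* **Common face response.** All images evoke a P1-like occipital
  component (≈3 µV at 100 ms) and an N170-like occipito-parietal
  component (≈−4 µV at 170 ms), with ±20 % per-subject amplitude jitter.
* **Self contrast.** Users carry an additional N250-like component on
  self-face events only, drawn per subject: latency uniform on
  0.20–0.45 s, magnitude uniform on 2–8 µV (negative deflection), envelope
  SD 0.04–0.07 s, topography on the centro-parietal channels Cz, Pz, P3,
  P4, C4 with per-channel gains uniform on 0.5–1.
* **Imposter scenarios.** A scenario-1 imposter (inattentive viewer) has
  no self contrast at all. A scenario-2 imposter (deliberate imitator)
  has a contrast of their own whose latency is forced at least 0.10 s away
  from the paired user's, with amplitude and topography redrawn. The
  0.10 s floor is one analysis window: separations below the temporal
  resolution of the classifier would not be "distinctly different" in any
  operational sense.
* **Noise.** Per-channel 1/f ("pink") noise at 8 µV RMS plus white noise
  at 4 µV RMS, independent across channels. Both RMS values are referenced
  to the 1200 Hz acquisition bandwidth: a recording simulated at a lower
  rate realizes only the spectral portion below its own Nyquist, so the
  same profile produces the same post-filter epochs whether it is
  simulated at 2400 Hz and decimated or simulated directly at 600 Hz.
  These levels are typical of band-limited single-trial scalp EEG; after
  the 40 Hz low-pass about 7 µV RMS survives into the epochs.
* **Overlap.** Responses are superposed linearly, so at a 300 ms SOA each
  1.2 s epoch contains the tails of neighboring responses — deliberately,
  as in the real paradigm.

What the generator does *not* model: eye-blink/EMG artifacts, electrode
drift, volume-conduction correlations between channels, and any cognitive
model of the counting task (attention appears only as the presence or
absence of the contrast component). Tests passing on this generator
therefore certify the pipeline's statistics and algebra under controlled
ground truth, not robustness to real-world artifacts.

## The acquisition signal chain

`preprocess_recording()` fixes the order filter → downsample → epoch:

1. **Low-pass filter.** Chebyshev Type I, passband edge 40 Hz, stopband
   edge 49 Hz, 0.5 dB passband ripple, 40 dB stopband attenuation, minimum
   order meeting the specification (order 10 at 2400 Hz), applied
   zero-phase so ERP latencies are untouched. The design is kept in
   zero-pole-gain form: at this design point (normalized cutoff 0.033) the
   expanded transfer-function polynomial is numerically ill-conditioned —
   its evaluated DC gain is visibly wrong — so the package designs the
   analog prototype, bilinear-transforms it, verifies the response against
   the closed-form Chebyshev magnitude, and applies the zero-phase pass as
   |H(ω)|² in the frequency domain (the recordings are long and
   quiet-ended, making wrap-around transients negligible). The causal
   single-pass variant runs as a cascade of biquads.
2. **Decimation by block averaging.** Output sample *m* is the mean of
   input samples [4m, 4m+4), 2400 → 600 Hz; trailing remainder samples are
   dropped.
3. **Epoching.** Half-open window [−200, 1000) ms around each onset (the
   onset sample included), 720 samples at 600 Hz of which 600 are
   post-stimulus; the mean over [−200, 0) ms is subtracted per epoch and
   channel. Events without enough surrounding data are dropped and
   counted.

Whether the original acquisition filter was zero-phase is unknown;
zero-phase is the package default because a causal pass would shift the
N250 peak by the group delay and bias latency-sensitive analyses, and the
choice is exposed in `filter_spec()`.

## Channel selection

For channel *i* and post-stimulus sample *n*, the pointwise biserial
coefficient is

$$P_i(n) = \frac{\sqrt{N_1 N_2}}{N_1 + N_2}\,
\frac{M_i^{SF}(n) - M_i^{NSF}(n)}{S(n)},$$

with class means over the N₁ self and N₂ non-self epochs and S(n) the
standard deviation over the union. The package uses the population
(divide-by-N) denominator, under which P equals the Pearson correlation
between the binary class indicator and the amplitude — a property the
tests assert against a brute-force correlation oracle, and which bounds
every entry in [−1, 1].

Per-channel scores aggregate P over the 600 post-stimulus samples. The
aggregation is genuinely ambiguous ("sum of p values" admits signed,
absolute, or squared readings); the default is the sum of absolute values,
because a signed sum lets opposite-polarity deflections cancel, and the
other two readings are available via `aggregate_mode`. The top 6 channels
by score are selected, ties broken toward the lower channel index.

Selection scope matters for validity: selecting channels from all of a
user's data and then cross-validating on the same data leaks information.
The default here computes the selection inside each training fold
(`selection = "per_fold"`); selection once per user from registration data
(`"per_user"`) is available to mirror a literal reading of the protocol.

## The HDCA classifier

Hierarchical discriminant component analysis is linear at both stages:

1. **Spatial stage.** The 600 post-stimulus samples are partitioned into
   N contiguous windows (default N = 10, i.e. 100 ms windows — commensurate
   with ERP component widths). Per window, each feature's channel means
   are computed and a Fisher discriminant weight vector is fit:
   $w = (\Sigma + \lambda\,\mathrm{tr}(\Sigma)/C\cdot I)^{-1}
   (\mu_{user} - \mu_{imp})$, with pooled within-class covariance Σ over
   the C = 6 selected channels and shrinkage λ = 0.1 by default (a 6×6
   covariance from ≤ 90 training units can be ill-conditioned; λ = 0
   reproduces the textbook discriminant and is used in the oracle tests).
   Weights are unit-normalized, signed so the user class projects higher;
   coincident class means fall back deterministically to the first axis.
2. **Temporal stage.** The per-window scores y₁…y_N are combined as
   $Y_S = \sum_k v_k y_k + b$ with (v, b) maximizing the binomial
   log-likelihood minus (penalty/2)·‖v‖² (intercept unpenalized), Newton
   iterations to gradient norm 1e−8 or 1000 iterations. The default
   penalty 1e−2 keeps separable training sets finite; a zero penalty on
   separable data raises an explicit error.

The per-trial classification feature is itself a declared choice: the
pipeline never observes a single "trial sample" in the raw data, so the
default builds *self epoch − mean(non-self epochs)* per trial, restricted
to the selected channels and post-stimulus samples — the paradigm's
biometric is exactly this contrast, and channel selection optimizes it.
`self_only` mode is available for comparison. Features of adjacent trials
are then averaged pairwise.

Decisions accept when Y_S ≥ threshold; the default threshold 0 is the
posterior-0.5 point of the logistic model, and equality accepts. A
threshold sweep (`threshold_sweep()`) exposes the FAR/FRR trade-off as a
diagnostic; headline numbers use the single operating point.

## Evaluation protocol

Per user and imposter scenario, a 10-times-repeated stratified 10-fold
cross-validation on the 100 + 100 authentication units: each fold trains
on 90 units per class and tests on 10 per class, channel selection and all
fitting inside the training folds. ACC, FAR, and FRR follow the standard
confusion accounting (FAR over imposter tests, FRR over user tests);
identities are asserted on every fold. Aggregates are means and standard
deviations over the 100 fold evaluations, then across users.

Cross-session stability is measured by scoring a later session's user
units with the registration model (FRR only — no imposter data in session
2), and by the Pearson correlation between the two sessions' average
self-face ERPs concatenated over the selected channels. The correlation's
exact definition is not canonical; this concatenated-average default is
declared, and per-channel correlation then averaging is a one-line
variant.

## Numerical and design notes

* All RNG flows through derived sub-seeds (schedule trials, profile draws,
  noise streams, CV shuffles), so every artifact is independently
  reproducible and independent of the caller's RNG state.
* Degenerate inputs have defined behavior: zero-variance samples score
  P = 0 with a count; zero class-mean separation yields a deterministic
  unit weight; unfitted models, missing classes, channel mismatches and
  version-mismatched containers raise classed errors.
* Epoch/model containers are versioned RDS payloads; events are TSV;
  continuous EEG is 16-bit EDF (round-trip error bounded by half a
  quantization step); metrics are CSV.

## Problem sizes used by the test suite

The multi-seed property suites simulate the full 200-trial paradigm at
the 600 Hz analysis rate (equivalent, by the band-referenced noise model,
to acquiring at 2400 Hz and decimating), 20 seeds for the recovery
properties and 10 for cross-session; the end-to-end zero-noise check and
the acceptance script run the complete 2400 Hz chain. The acceptance
script evaluates a 3-user cohort (each with both imposter scenarios and a
second session) — large enough for stable cohort means, small enough to
re-run routinely.

## Known limitations

* **Channel recovery has an effect-size floor.** With contrast amplitudes
  down to 2 µV and per-channel gains down to 0.5, a flanker channel's
  effective contrast can be ≈1 µV against ≈7 µV in-band noise; 200 trials
  cannot reliably rank such a channel into the top 6, so subjects drawn in
  that tail recover only 3–4 of the 5 contrast channels. The Cz/Pz core
  recovers essentially always, and pooled across seeds the five contrast
  channels dominate all selections — the same pattern the underlying
  per-user selection tables show on real subjects.
* **Cross-session FRR exceeds in-session FRR even without drift.** 1/f
  noise is long-range correlated within a continuous recording, so a model
  trained on one session partially fits that session's noise color and
  scores a fresh session lower than held-out folds of its own session.
  This mimics a real session effect; together with the amplitude tail it
  keeps the weakest synthetic users' cross-session FRR well above the
  cohort median.
* The generator's independence of noise across channels understates the
  spatial correlation of real EEG, which flatters spatial filtering
  slightly.
* Linear HDCA is the only classifier; no nonlinear kernels, no artifact
  rejection, no online/streaming path.
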
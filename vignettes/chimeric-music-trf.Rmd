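---
title: "Chimeric music and temporal response functions: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Chimeric music and temporal response functions: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The scientific problem

Pitch and time are the two dimensions that define a melody, and listeners'
expectations about both shape the neural response to music. This package
implements an analysis framework for studying how the two dimensions
interact in EEG: *chimeric music* pairs two monophonic melodies from
different beat-structure families and exchanges their dimensions, so that
one chimera carries the pitch contour of piece 1 on the note-onset timing of
piece 2 (and the second chimera the reverse). Because the pitch sequence and
the inter-onset-interval (IOI) sequence of each chimera are, note for note,
prefixes of the corresponding original sequences, the *marginal* statistics
of each dimension are preserved while their joint structure is destroyed.
Any difference in neural encoding between originals and chimeras can then be
attributed to the broken pitch–time association rather than to the features
themselves.

Two encoding analyses are supported:

1. **Melodic expectation encoding.** Note-level surprisal and entropy for
   the pitch and IOI viewpoints are computed from a variable-order n-gram
   model and used, together with acoustic features, as regressors in
   ridge-regularized temporal response function (TRF) models. Model
   comparison (acoustic-only *A* vs. expectation-augmented *AM*, *AMp*,
   *AMt*) quantifies the expectation effect as a cross-validated
   prediction-accuracy difference, Δr.
2. **Downbeat encoding.** Binary impulse regressors mark note onsets and
   downbeats. For originals, a single downbeat train (DBo); for chimeras the
   downbeat notion decouples into downbeat-time (DBct, inherited from the
   time source and temporally a true downbeat), downbeat-pitch (DBcp, notes
   that were downbeats in the pitch source), and their interaction (DBcpt).
   Because every DB\* impulse coincides with an onset impulse, the model is
   incremental: the DB\* kernels estimate the *difference* between the
   downbeat response and the generic onset response, and DBcpt the response
   beyond the sum of the time and pitch contributions.

## The expectation model

Prediction is performed per viewpoint on discrete symbol sequences: MIDI
pitches for the pitch viewpoint, and IOIs quantized to integer multiples of
a grid unit (by default the minimum IOI of the piece) for the time
viewpoint. Given a context, the model produces a distribution $P(x \mid
\text{context})$ over the alphabet $K$, and for the observed symbol $x_t$
emits

- surprisal $S(x_t) = -\ln P(x_t \mid x_{t-n}^{t-1})$ (nats), the
  unexpectedness of the note, and
- entropy $E(x_t) = \sum_{x \in K} P(x \mid x_{t-n}^{t-1})\, S(x)$, the
  uncertainty of the context before the note.

Smoothing is PPM-style escape method C with *interpolated* back-off: with
$c$ the context's symbol counts, $n$ their total and $t$ the number of
distinct continuations,

$$P_k(s) = \frac{c(s)}{n + t} + \frac{t}{n + t}\, P_{k-1}(s),$$

descending from the longest stored context to order 0 and bottoming out at
the uniform distribution over $K$. Every prediction is therefore strictly
positive and sums to one. The short-term model (STM) starts empty and learns
the current piece online (each note is predicted before it is learned); the
long-term model (LTM) is trained on a corpus. The combined "both" mode
merges the two distributions by an entropy-weighted geometric mean: each
source is weighted by $(\text{relative entropy})^{-b}$ with bias $b = 1$, so
the more confident model dominates; arithmetic mixing is available as an
option. These choices (escape method, combination rule, bias) are the
contract of this implementation — variable-order n-gram frameworks differ in
these details and we document rather than assert anyone else's settings.
The order bound defaults to 10 with longest-match back-off, effectively
unbounded for half-minute melodies.

## TRF estimation

The TRF is a per-feature, per-channel kernel $w(f, l, c)$ over lags $l$,
mapping feature signals on the EEG sample grid (default 125 samples/s) to
each channel: $\hat y(t, c) = \sum_f \sum_l x_f(t - l)\, w(f, l, c)$. The
default lag window is −100 to 800 ms; the window is an analysis parameter,
configurable everywhere. Edges are zero-padded rather than trimmed.

- **Ridge (expectation models).** Closed-form solution $(X^\top X +
  \lambda I)^{-1} X^\top Y$ on per-trial-centred designs, with columns
  z-scored by training-fold statistics before penalization and kernels
  returned on the original feature scale. λ is selected per participant and
  per model by leave-one-out cross-validation across trials over the grid
  $10^{-3} \ldots 10^3$, maximizing the Pearson correlation between
  predicted and recorded EEG, computed per channel on the held-out trial and
  averaged over channels. The cross-validation loop works entirely in Gram
  space (per-trial $X^\top X$, $X^\top Y$ and an eigendecomposition per
  fold), so the per-λ and per-subject costs are small matrix operations;
  this is exactly equivalent to refitting per fold.
- **OLS (downbeat models).** Impulse-train designs are fit by ordinary
  least squares without centring or scaling, which preserves the kernel's
  interpretation: when impulses are spaced further apart than the lag span,
  the OLS kernel *equals* the epoch-averaged evoked response (this identity
  is one of the package's test oracles). Rank-deficient designs are
  rejected with the offending columns named.

Expectation feature amplitudes are z-scored per trial before being placed
as impulse amplitudes (configurable off); onset binning uses round-half-up,
documented because 125 Hz bins are 8 ms wide and ties at half-bins would
otherwise be platform-dependent.

## Statistical layer

- **Δr table.** `delta_r_table()` computes r(model) − r(A) within each
  participant and stimulus set and exports the long-format table (model
  contrast, stimulus category, musicianship, preference, participant,
  stimulus set) that standard mixed-effects software consumes. The
  mixed-model fits themselves are out of scope here by design: they are
  routine and belong to dedicated tools.
- **Paired tests.** Two-sided paired t tests with step-down Holm–Bonferroni
  adjustment (delegated to `stats::t.test` / `stats::p.adjust`).
- **TFCE + sign-flip permutation.** Channel × lag effect maps are tested
  against zero with a one-sample t map enhanced by threshold-free cluster
  enhancement, $\text{score}(p) = \sum_h e_h(p)^E h^H \, dh$, with clusters
  formed on a spatiotemporal graph linking neighbouring sensors (a shipped
  32-channel 10–20 montage, injectable) and consecutive lags. Defaults
  $E = 0.5$, $H = 2$, $dh = \max|t|/50$ follow common toolbox practice and
  are configurable. Two-sided inference enhances the +t and −t maps
  separately and takes the per-point maximum. The null is the maximum
  absolute TFCE score over the whole map per subject-level sign-flip
  (family-wise control); p-values are $(1 + \#\{\text{null} \ge
  \text{obs}\})/(1 + n_{\text{perm}})$, never zero. The threshold sweep and
  union-find clustering are implemented in C++ because the calibration
  tests run tens of thousands of enhancements.
- **Peak correlations.** Per-channel Pearson correlation between windowed
  kernel peak amplitudes and a covariate (years of musical training), with
  Benjamini–Hochberg correction across channels.

## The synthetic-data generator

`simulate_study()` is a first-class module, not a fixture: it generates the
whole study from a seed so that every pipeline stage is verifiable by
parameter recovery.

- **Melodies** emulate metrical monophonic folksongs: IOIs of 0.5–2 beats
  on a half-beat grid, pitches from a first-order Markov chain over a
  diatonic octave favouring stepwise motion, triple (3/4) and
  duple/quadruple (4/4) signatures for cross-group pairing. Sixty notes at
  the default quarter of 0.45 s exceed the 25 s stimulus-length screen.
- **Kernels** carry the canonical auditory morphology: the onset kernel has
  P1 (~80 ms) and P2 (~185 ms) deflections; the downbeat kernel a ~185 ms
  peak and a ~650 ms dip; expectation kernels are smooth mid-latency
  shapes; the DBcpt interaction kernel is zero unless planted. A
  frontocentral channel-weight map (max 1 at Fz) projects the source to 32
  channels.
- **EEG** is the forward model the TRF assumes — the sum of regressors
  convolved with their kernels — plus 1/f-shaped Gaussian noise with a
  shared across-channel component (spatial correlation 0.3), scaled so the
  realized clean-to-noise variance ratio equals the requested SNR exactly.
- **Study structure**: every subject hears every stimulus; a per-subject
  onset-kernel gain of 0.08 per year of (uniform 0–11) musical training
  links P2 amplitude to musicianship; expectation kernels are attenuated by
  0.5 for chimeric trials by default, emulating a weakened expectation
  response when pitch–time structure is broken.

What the generator does *not* emulate: volume conduction from realistic
sources, eye/muscle artifacts, non-stationary noise, expressive timing, or
any dependence of the expectation response on the listener's enculturation.
Passing parameter-recovery tests therefore demonstrates the estimators'
correctness under the model's own assumptions, not robustness to every
property of real EEG.

## Numerical choices and degenerate inputs

- Measure grid anchored at absolute time 0; an anacrusis offset parameter
  shifts it, since treatment of pickup measures is genuinely ambiguous for
  folk material. Downbeat tolerance defaults to 1 ms (symbolic input is
  exact).
- Monophony: onsets closer than 1 ms are rejected; a note still sounding at
  the next onset is truncated there.
- Fused chimeras take both onsets *and durations* from the time source,
  preserving its rhythm envelope; the time signature is inherited from the
  time source, whose metrical grid the chimera follows.
- Cross-group pairing is a greedy two-pointer sweep over note counts with a
  default tolerance of 5 notes; the original pairing procedure is not fully
  specified anywhere, so the simplest deterministic heuristic is used.
- Two notes mapping to one regressor sample is an error, not a silent
  merge. Constant (zero-variance) channels get r = 0 with a warning.
  Silent audio yields zero flux with a warning. Degenerate distributions
  give S = E = 0.
- Spectral flux: 1024-sample Hann windows, 50% overlap at 48 kHz, half-wave
  rectified positive spectral difference summed over frequency, polyphase
  resampling to the regressor rate, z-scored per trial. The tone renderer
  is deliberately simple (four damped harmonics, RMS 0.01): it exists to
  give the flux regressor realistic onset structure, not to model a piano.

## Problem sizes in the tests

The test suite runs the full pipeline at desk scale, chosen to keep the
whole suite in the tens of minutes while leaving every statistical property
testable: the Δr behaviour checks use 20 runs of 4-subject, 8-trial studies
(45-note melodies, λ grid {10⁻², 1, 10²}, lags −50–550 ms); the
interaction-detection checks use 6-subject studies at 6 dB SNR; permutation
calibration uses 200 replicates of 199 permutations on 8 subjects × 8
channels × 60 lags. The downbeat-estimator checks generate EEG from the
downbeat forward model alone (`expectation_scale = 0`, no flux), the
appropriate null for an estimator tested under its own model; the
expectation checks use the full generative model.

## Known limitations

- The n-gram implementation covers the cpitch and ioi viewpoints only; no
  linked or derived viewpoints, and no model selection over viewpoint sets.
- The OLS downbeat model inherits the usual deconvolution caveat: responses
  to regressors omitted from the model (e.g. acoustic envelope features)
  are absorbed into correlated kernels.
- `pair_collection()` matches on note count only; duration similarity
  follows indirectly.
- MIDI support is deliberately narrow: monophonic type 0/1 files with tempo
  and time-signature meta events; no SMPTE division, no expressive timing
  extraction.
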
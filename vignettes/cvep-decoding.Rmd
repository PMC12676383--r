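---
title: "Decoding code-modulated visual evoked potentials with cvepr"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Decoding code-modulated visual evoked potentials with cvepr}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cvepr)
```

## The decoding problem

In a code-modulated visual evoked potential (c-VEP) brain–computer
interface, a visual target flickers according to a pseudorandom binary
sequence, and the EEG over occipito-parietal cortex follows that modulation
with a subject-specific impulse response. Different selectable targets use
circular shifts of the *same* sequence, so decoding reduces to deciding which
shift best explains a single EEG epoch.

`cvepr` implements a complete decoding stack for the six-class, 63-bit
variant of this paradigm:

* a 63-bit maximal-length sequence (m-sequence) presented at 60 Hz, so one
  code period spans `round(63 * 512 / 60) = 538` samples at 512 Hz
  (`samples_per_period()`), about 1.05 s;
* six classes defined by circular shifts of 0, 8, 16, 24, 32, 40 bits
  (`build_code_bank()`);
* 8 channels (O1, O2, Oz, Pz, P3, P4, PO7, PO8), 5 recording sessions of
  114 trials each.

M-sequences are used because their ±1-mapped circular autocorrelation is
maximally flat: `K` at lag zero and exactly −1 everywhere else, which makes
the six shifted classes nearly orthogonal (`code_crosscorr()`).

## The synthetic-data generator

No public recordings accompany this paradigm, so the package ships a
simulator (`simulate_epochs()`) whose default configuration *is* the study
geometry above. Each trial is generated as

1. the class code expanded to the sample grid by zero-order hold
   (`code_to_waveform()`), mean-centred;
2. circular convolution with a per-channel evoked impulse response — a
   Gaussian-windowed 10 Hz cosine with 90 ms latency and 60 ms FWHM,
   occipital channels carrying 1.5× the parietal amplitude
   (`default_kernel_spec()`). These kernel values are a documented choice of
   a plausible evoked response, not an estimate from data; no test depends
   on them beyond the structural invariants below;
3. a circular latency jitter drawn uniformly from ±2 samples (default);
4. additive noise — an equal-power mixture of white and 1/f-power ("pink")
   noise by default — scaled *per trial* so that the clean-to-noise power
   ratio equals `snr_db` exactly (default +10 dB);
5. a multiplicative log-normal gain drawn once per session
   (`session_gain_sd = 0.1`) to emulate impedance / gain drift between
   sessions.

Circular convolution and circular jitter are the physically faithful choices
here because the stimulus is periodic with the epoch; they also make the
class structure exactly compatible with circular code shifts, which the
relabelling expansion (`expand_classes()`, one 114-trial block → 684 labelled
examples) exploits.

What the simulator deliberately does **not** model: ocular and muscle
artifacts, volume-conduction mixing between channels, non-stationary
within-session drifts, and subject-to-subject variability of the impulse
response. Tests passing on simulated data therefore demonstrate that the
*decoders* work when their signal model holds at the stated SNR; they say
nothing about robustness to artifacts or about the accuracy level to expect
on real recordings.

A note on the default SNR: +10 dB per trial (clean evoked power over noise
power summed across channels) is far kinder than raw single-trial EEG, where
evoked responses typically sit well below the noise floor. It is chosen so
that desk-scale runs exercise every method in its operating regime (well
above the 1/6 chance level but below ceiling for the weaker baselines).

## Preprocessing

* **Detrending** (`detrend()`) removes the least-squares line per channel
  per trial — mean removal alone would leave slow drifts. The operation is a
  projection, hence idempotent.
* **Bandpass** (`bandpass()`): 0.5–42.66 Hz, 6th-order Butterworth-type
  magnitude applied forward-backward (zero phase). Because each epoch is one
  period of the periodic stimulus, the squared magnitude response is applied
  circularly in the frequency domain: the realized gain at every resolvable
  frequency is exactly the design response, with none of the start-up
  transients a recursive filter would have (its 0.5 Hz pole rings longer
  than the 1.05 s epoch). The operator is sandwiched between linear-detrend
  projections — mean and linear trend are sub-resolution content the
  circular model would otherwise wrap into a spurious jump — which removes
  DC exactly and makes `bandpass()` and `detrend()` commute exactly. Content
  that is genuinely non-periodic in the epoch (e.g. a probe sinusoid with a
  fractional number of cycles) still wraps with a small discontinuity whose
  filtered image is confined near the epoch boundary; frequency-domain
  gains, the quantity the filter is specified by, are unaffected. The 6th
  order is the lowest for which the 60 Hz refresh component is attenuated
  below 10% while 10 Hz passes above 90%.
* **Surface Laplacian** (`laplacian_weights()`, `apply_laplacian()`):
  sensors live on a unit spherical head model; inter-electrode distances are
  great-circle (Vincenty) distances; the weight of neighbour *j* on target
  *i* is `1/d_ij` for neighbours within radius 1 (normalized units) and the
  filtered signal is `S_i − Σ_j w_ij S_j`. The literal inverse-distance form
  rescales signal amplitude (weights do not sum to 1), so a `normalized`
  flag offers the conventional row-normalized variant; the literal form is
  the default and both are tested. Electrode coordinates ship as a fixture
  computed from the idealized 10–20 spherical construction (18° arc steps;
  P3/P4 as great-circle midpoints of Pz–P7 / Pz–P8), since the paradigm
  defines sites by name only.

## Classical decoders

`build_templates()` averages training trials per class and channel — eight
template signals per class. Two feature families feed a Bayesian linear
discriminant:

* **Correlation features** (`corr_features()`): Pearson correlation of every
  epoch channel with every template channel of every class —
  8 × 8 × 6 = 384 features. Ordering is fixed class-major (class, then epoch
  channel, then template channel); only consistency matters downstream.
  Zero-variance channels yield 0 instead of NA, with a warning.
* **CCA features** (`cca_features()`): per class, the canonical correlations
  between the 538 × 8 epoch and template matrices, sorted descending and
  padded with exact zeros to 8 slots — 48 features. Canonical correlations
  are computed by a rank-aware QR/SVD routine so a rank-deficient epoch
  (e.g. a duplicated channel, rank 7) contributes 7 correlations plus a zero
  pad rather than an error. Templates, not raw code waveforms, serve as the
  CCA references; the reference set is injectable if the alternative reading
  is wanted.

**BLDA** (`fit_blda()`) is Bayesian linear regression onto ±1 targets with a
single shared prior precision and a noise precision, both updated by
evidence maximization until the relative change drops below 1e−6 (or 200
iterations). The automatic ridge keeps weights finite under perfectly
collinear features. Multiclass decisions use one-vs-rest models with a
softmax over the six discriminant scores (`predict_ovr()`); ties break to
the lowest class index, a convention used by every argmax/argmin in the
package.

## Convolutional networks

All network code is implemented in the package itself (array/BLAS
operations with hand-derived backpropagation, verified against numerical
differentiation in the test suite) — see `build_trunk()`:

| stage | shape out | parameters |
|---|---|---|
| temporal bin-average 538 → 252 | 8 × 252 | — |
| spatial conv 8×1, 8 filters | 8 × 252 | 72 |
| temporal conv 1×11, 16 filters + ReLU + pool /2 + dropout 20% | 16 × 126 | 1 424 |
| temporal conv 1×14, 32 filters + ReLU + pool /2 + dropout 30% | 32 × 63 | 7 200 |
| flatten | 2016 | — |

The front-end resampling to 252 samples (4 per code bit) is the package's
resolution of a geometric constraint: the dense heads' published sizes
(127.1k for the 63-unit reconstruction head, 12.1k for the 6-class head)
require a flattened length of 2016 = 32 × 63, which two /2 poolings can only
produce from a 252-sample temporal axis, not from 538. Bin-averaging to 4
samples per bit keeps one output bin per code bit and reconciles every
parameter count: 2016 · 63 + 63 = 127 071 and 2016 · 6 + 6 = 12 102, both
verified in tests. Trunk totals are 8 640 weights (8 696 with convolution
biases); both counts are reported by `n_params()` since bias conventions
differ between toolkits.

Training (`train_reconstruction()`, `train_classifier()`) uses Adam
(lr 1e−3, L2 1e−4 on weights), mini-batches of 64 reshuffled per epoch, up
to 40 epochs in the reference regime. The reconstruction head uses sigmoid
outputs with MSE loss against the 0/1 code of the trial's class and reports
RMSE per epoch (BCE is available via the engine's loss hooks, MSE is the
default because RMSE is the monitored metric); the class head uses softmax
with categorical cross-entropy and reports accuracy. One seed in
`train_config()` governs initialization (when built inside the training
call), shuffling, dropout and pair sampling; two runs from the same built
network and seed produce bit-identical weights.

## Distance decoders

The reconstruction network outputs `ŷ ∈ [0,1]^63` per trial, compared to
the six code-bank rows (`ŷ` is used directly by default — ranking-
equivalent and information-preserving; a 0.5-threshold option exists):

* **Squared Euclidean** (`euclidean_decode()`): the square root is omitted;
  it cannot change the argmin.
* **Shrinkage Mahalanobis** (`mahalanobis_decode()`): bit-wise covariance
  `Σ` estimated from reconstructions, regularized as
  `Σ_reg = (1−λ)Σ + λᾱI` with λ = 0.1 and ᾱ the mean diagonal of `Σ`. The
  pipelines estimate `Σ` from *training-set* reconstructions centred at
  their class codewords (the pooled within-class covariance, as in
  discriminant analysis); the raw globally-centred covariance is also
  available but absorbs between-class scatter, and whitening by it can
  suppress exactly the class-separating directions once reconstructions are
  accurate. A `transductive_cov` flag switches to estimating from the test
  reconstructions themselves.
* **EMD** (`emd_decode()`): outputs and codes are normalized to probability
  mass functions (clip at 0, divide by the sum); the 1-D Earth Mover's
  Distance is the mean absolute difference of the two cumulative
  distributions.
* **Constrained EMD** (`constrained_emd()`, `cemd_decode()`): minimal
  transported mass weighted by bit displacement, with transport forbidden
  beyond a radius `R` of bit positions. The optimum is computed by the
  monotone (north-west-corner) coupling: `|k−j|` is a Monge cost, and
  uncrossing two crossed transport arcs never widens their displacement, so
  the monotone plan is optimal and is feasible whenever any plan is. The
  test suite certifies optimality independently via LP duality (feasible
  dual potentials reconstructed from each plan) and checks infeasibility
  against Hall's interval condition. Infeasible transport (mass forced
  farther than `R`) yields distance `+Inf` — "no admissible local
  transport" — rather than an error; a trial infeasible for *every* class
  falls back to unconstrained EMD with a message. At `R ≥ K−1` the
  constrained cost equals the unconstrained EMD in bit units (the CDF form
  times `K`). The default `R = 8` equals one class-shift granularity; the
  reference regime does not pin this value, so it is an explicit,
  documented parameter everywhere it appears.

## Temporal augmentation

`shift_epochs()` shifts trials circularly in time (wrap-around, consistent
with the periodic stimulus; a truncating variant is intentionally absent
because truncation breaks the circular class geometry). Three regimes
(`augment_config()`):

* **TA** — training set plus copies shifted by −α and +α (3× trials);
* **TC** — scores averaged over test inputs shifted by {−α, 0, +α}; the
  unshifted view is included in the average, which keeps α = 0 exactly equal
  to the baseline. Distance matrices are averaged and the argmin taken;
  probabilistic scores are averaged and the argmax taken;
* **TA&TC** — both. `NA` is the baseline.

The reference grid uses α ∈ {1, 2, 4, 8}.

## Evaluation and statistics

`session_cv()` implements leave-one-session-out cross-validation: each
session is the test fold once, the other sessions train; accuracy is the
percentage of correctly labelled test trials, summarized as mean ± SD over
folds (`accuracy_table()`).

`friedman_test()` compares methods across subjects on mid-ranks with the
standard tie correction and reports Kendall's concordance
`W = χ²/(n(k−1))`; `pairwise_wilcoxon()` runs all pairwise signed-rank
tests at the Bonferroni-adjusted level (0.05/36 ≈ 0.0014 for nine methods),
using the exact distribution for up to 25 nonzero differences without ties
and the normal approximation otherwise; all-zero difference pairs are
flagged degenerate instead of receiving a p-value.

## Problem sizes, tolerances and degenerate inputs

* Desk-scale runs in the tests and the acceptance script use the full
  recording geometry (5 × 114 trials) with shortened network training
  (6–8 epochs instead of 40, smaller Siamese pair budgets). At the
  simulator's default +10 dB these runs operate at or near each method's
  plateau, so they exercise the full pipeline without the full training
  cost; the reference epoch counts remain the defaults of
  `train_config()`.
* Numerical tolerances: BLDA stops at 1e−6 relative change; transport mass
  bookkeeping uses 1e−12; PMF normalization rejects all-nonpositive vectors
  (`"degenerate PMF"`); coincident sensors, all-zero LFSR states and
  non-primitive taps raise immediate errors.
* The LFSR default polynomial per degree comes from a standard primitive-tap
  table (degree 6: x⁶ + x + 1). The bundled 63-bit code is a literal
  fixture: the taps that generated it are not documented in the paradigm
  description, and no attempt is made to reverse-engineer them.

## Known limitations

* The simulator's realism limits (artifacts, volume conduction,
  non-stationarity) mean simulated accuracies are upper bounds on what the
  same pipeline would achieve on comparable real recordings.
* The NN engine is CPU-only and single-threaded beyond BLAS; it targets the
  8.6k-parameter trunk scale, not larger architectures.
* `pairwise_wilcoxon()` inherits the usual small-sample caveats of rank
  tests; with 13 subjects the exact distribution is used, but power at
  α = 0.0014 is limited.
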
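---
title: "Cross-subject EEG fatigue classification by label-aligned multi-source domain adaptation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cross-subject EEG fatigue classification by label-aligned multi-source domain adaptation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

EEG correlates of mental fatigue are well established — spectral power
rises in the theta (4–7 Hz) band and shifts in alpha (8–13 Hz) and beta
(14–30 Hz) accompany drowsiness — but their absolute expression differs
so much between people that a classifier trained on one group of
subjects degrades badly on a new, unlabeled subject.  `eegmsda` treats
each labeled subject as its own *source domain* and the new subject as
an unlabeled *target domain*, and trains a model that aligns the
domains while it learns to classify, so that no labels are ever needed
for the test subject.

The geometry the package is built around is a driving-style fatigue
protocol: 61 channels at 200 Hz, two mental states per subject (awake,
coded 0, and fatigue, coded 1), 700 half-second segments per state, so
each subject contributes a 1,400 × 1,647 feature matrix (61 channels ×
27 band frequencies) and a 15-subject cohort contributes 21,000
segments.  All of these numbers are configurable; none is hard-wired.

## Preprocessing: band-power features

`extract_features()` composes four steps, each exposed on its own:

1. **Band-pass** (`bandpass()`): zero-phase Butterworth 1–30 Hz applied
   forwards and backwards.  It is optional (`feature_config(bandpass =
   NULL)`) because the simulated cohort is already band-limited; for
   recorded EEG it stays on.
2. **Segmentation** (`segment()`): non-overlapping 0.5 s windows
   (100 samples at 200 Hz); a trailing partial window is dropped.
3. **Log-PSD** (`log_psd()`): a single-window periodogram per segment —
   each 0.5 s segment is one analysis unit, so no Welch averaging.  The
   window is mean-detrended and zero-padded to a whole second so the
   DFT bins fall on exact 1 Hz steps; power is read at the integer
   frequencies 1–100 Hz.  The padding is a reconstruction choice: a
   100-sample window natively yields 2 Hz bins, and zero-padding is the
   simplest mechanism that produces values *at every integer
   frequency*.  Power is floored at 1e-12 before log10 so silent
   channels stay finite; frequencies above the Nyquist are filled with
   the floor.  The scaling satisfies Parseval: the one-sided linear PSD
   sums to the window variance (tested).
4. **Band assembly** (`band_features()`): inclusive integer bands —
   theta 4–7 (4 points), alpha 8–13 (6), beta 14–30 (17), i.e. 27
   points per channel — concatenated channel-major into the
   1,647-vector.  Inclusive edges are forced by the printed count: only
   4 + 6 + 17 = 27 yields 61 × 27 = 1,647.

## The model

Three stages, sized by `model_config()`:

* a **shared extractor** `f` mapping the 1,647-dim feature vector to a
  common space (`common_dim`, default 64) where domain-invariant
  structure lives;
* **N unshared subnetworks** `F_n`, one per source, mapping the common
  features into per-source specific spaces (`specific_dim`, default
  64) — one feature space per source–target pair;
* **N classifier heads** `O_n`, giving `G_n = O_n ∘ F_n`, each a
  probability distribution over the two states.

All stages are dense: affine + ReLU for `f` and `F_n`, affine + softmax
for `O_n`.  The model input here is a log band-power vector, not a raw
waveform, so dense layers are the natural architecture; every gradient
is written analytically and verified against finite differences in the
test suite, which keeps the optimisation fully auditable.  Inputs are
z-scored per feature with statistics pooled over the sources (stored in
the model and applied to the target at inference).

## The objective

Training minimises

$$\mathcal{L}_{total} = \mathcal{L}_c + \mu\,\mathcal{L}_{local} +
\gamma\,\mathcal{L}_{global}$$

**Supervised loss** `supervised_loss()`: the sum over sources of each
head's mean cross-entropy on its own labeled batch.

**Label-conditional alignment** `llmmd()`: for each pair (source *n*,
target), a class-conditional weighted maximum mean discrepancy between
the specific features, with Gaussian kernels
$k(x,y)=e^{-\lVert x-y\rVert^2/2\sigma^2}$.  Within class *c* the
statistic is

$$\sum_{ij}\varphi^c_i\varphi^c_j k(s_i,s_j)
 - 2\sum_{ij}\varphi^c_i\varphi^c_j k(s_i,t_j)
 + \sum_{ij}\varphi^c_i\varphi^c_j k(t_i,t_j),$$

averaged over classes and source domains.  Source weights
$\varphi^{c}$ put mass $1/n_c$ on each class-\(c\) sample
(`source_class_weights()`); the unlabeled target is weighted by head
*n*'s soft pseudo-labels, column-normalised
(`target_class_weights()`).  Both weight families are normalised to
sum to one within each class, so the statistic is scale-stable in the
batch size; a `"literal"` mode additionally keeps $1/|X|^2$ prefactors
for completeness, but the normalised form is the default because the
weights already carry the normalisation and the prefactors would
shrink the loss by the squared batch size.  Design choices on points
the construction leaves open: the target weights for pair *n* come
from classifier *n* itself (pairwise self-consistent; an ensemble
average is a one-line variant); pseudo-label weights are treated as
constants within a step (no gradient flows through them) to avoid
self-reinforcing degenerate solutions; and bandwidths default to the
per-batch median heuristic, $\sigma = \text{median distance} \times
2^{k}, k\in[-2,2]$, also held constant within a step.

**Classifier-discrepancy alignment** `global_loss()`: near the decision
boundary, different heads disagree on the same target sample.  With
$d_{nm}$ the mean absolute difference between heads *n* and *m* on the
target batch (`pairwise_discrepancy()`, in [0, 2]) the loss is

$$\mathcal{L}_{global} = \frac{2}{N(N-1)}\sum_{n<m}
(1-\omega_{mn})\, d_{nm},
\qquad \omega_{mn} = \frac{d_{nm}}{\sum_{j\neq n} d_{nj}},$$

so pairs that already agree (small $d_{nm}$, hence small
$\omega_{mn}$ relative to row *n*) keep a large $1-\omega$ factor and
are pushed into full agreement, while the most dissimilar pairs are
down-weighted.  The raw pairwise difference is vector-valued; it is
scalarised through $d_{nm}$ before normalising — the only reading that
yields scalar weights.  The row-normalised $\omega$ is asymmetric and
used as printed; a `symmetrize_omega` flag averages
$(\omega_{mn}+\omega_{nm})/2$.  With exactly two heads the
construction degenerates ($\omega \equiv 1$, loss identically zero),
so the unweighted discrepancy $d_{12}$ is used instead, with a
warning.  $\omega$ is detached from the gradient like the
pseudo-label weights.

## Training protocol

`train_config()` defaults: Adam at learning rate 0.001, batch size 64
per domain per iteration, 500 iterations (loss curves flatten well
before that on both benchmarks), trade-offs μ = γ = 0.5 ramped
linearly from 0 over the first 25 % of iterations — a standard
stabilisation while pseudo-labels are still noisy; both the values and
the ramp are configurable and the μ = γ = 0 setting is the
supervised-only ablation.  Batches are drawn uniformly (not
class-stratified).  `aux_ratio` (λ) controls how much of the unlabeled
target is used as auxiliary training data for the alignment losses;
the default 1.0 uses all of it, and with λ < 1 the
leave-one-subject-out harness evaluates on the held-out remainder.
There is no validation-based stopping because the target has no labels
by construction.

**Prediction** (`predict()`): the final distribution is a weighted
average of the N heads.  The agreement weighting uses the symmetrised
$\bar\omega$: head *n*'s weight is proportional to
$\sum_{m\neq n}(1-\bar\omega_{mn})$.  The asymmetric row-normalised
$\omega$ makes that sum identically $N-2$ — uniform averaging in
disguise — which is why the symmetrised form is used; a `"uniform"`
mode gives the plain average.  Ties at the arg-max go to the lower
class index (awake).

**The target-label firewall**: `train()` strips labels from the target
input on entry, and the test suite verifies that replacing the
target's labels with nonsense changes nothing in training or
prediction.

## The synthetic cohort

`simulate_cohort()` emulates the study geometry without recorded data.
Each segment is synthesised directly in the frequency domain:
complex-Gaussian coefficients shaped 1/f ("pink", EEG-plausible;
"white" optional), multiplied by the square root of per-band power
gains, inverse-transformed to 100 samples.  The two states differ by
multiplicative band gains — defaults raise theta power by 1.6× and
alpha by 1.5× under fatigue and lower beta (1.2 → 0.8), the direction
reported for drowsy EEG; the magnitudes are free choices at a level
that leaves single segments ambiguous but class means clearly
separated.  The cross-subject shift is a per-channel log-normal gain
plus a per-subject band-gain jitter (`subject_gain_sd`, default 0.2);
between-subject feature MMD grows monotonically with it (tested).  No
published estimate of inter-subject variability exists to calibrate
against, so these magnitudes are stated choices, not estimates.

What the simulator does *not* model: volume conduction and channel
covariance (channels are independent), eye-blink/EMG artifacts,
non-stationarity within a session, and label noise.  Passing tests on
this cohort therefore demonstrate that the machinery is correct and
that adaptation recovers a band-power signature under multiplicative
subject shifts — not that any particular accuracy transfers to
recorded EEG.

The low-dimensional **blob benchmark** (`make_blob_domains()`) exists
for fast loss-level testing and for the adaptation experiment: shared
class means on random unit directions, per-domain Cayley-transform
rotations and offsets with standard deviation `domain_shift_scale`
(zero shift ⇒ identical domains).  The shipped benchmark uses shift
0.3: large enough that a source-only model visibly degrades, small
enough that each source's decision boundary still transfers above
chance — at much larger scales the random rotations make the target's
class assignment unidentifiable from unlabeled data alone, which is a
failure mode of the *task*, not of the optimiser.

## Problem sizes used in the shipped experiments

The test suite and the acceptance script run two experiments chosen to
exercise the full objective at desk scale: the blob benchmark with 5
source domains, shift 0.3, 3 seeds, 500 iterations, width-32 layers;
and the full 15-subject cohort under leave-one-subject-out with 500
iterations per fold, batch size 32 and width-32 layers — batch and
width halved relative to the defaults to keep the 15-fold experiment
light while leaving the protocol (iterations, optimiser, trade-offs)
untouched.

## Numerical choices and degenerate inputs

* Probabilities are clamped at 1e-12 before logs; PSD power is floored
  at 1e-12 before log10.
* A class absent from either side of a source–target pair contributes
  zero to the alignment loss for that pair and is flagged.
* An all-zero discrepancy row yields uniform ω (the loss term is zero
  either way).
* `sign(0) = 0` is the subgradient used for the L1 discrepancy.
* Seeds: every stochastic step (domain synthesis, initialisation,
  batch sampling, auxiliary-pool choice) derives from a single integer
  seed; per-subject and per-fold seeds are derived with a fixed
  integer hash kept inside 32-bit range.  Identical configuration ⇒
  bit-identical runs on one thread.

## Known limitations

* The dense backbone does not exploit spatial electrode structure; a
  convolutional extractor over a channels × frequency grid is a
  natural extension.
* The V-statistic MMD estimate is biased upward at small batches; with
  batch 64 and multi-bandwidth kernels this is benign but visible as a
  nonzero floor in `L_local`.
* With very few sources (N = 2) the global term reduces to plain
  discrepancy minimisation; the method is intended for many sources
  (the motivating protocol uses N = 14).
* Pseudo-label weighting can lock in early mistakes if μ is ramped too
  fast on severely shifted targets; the ramp default mitigates but
  does not eliminate this.
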
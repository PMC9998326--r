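---
title: "Decoding upcoming hand choice from pre-stimulus EEG"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Decoding upcoming hand choice from pre-stimulus EEG}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

When a person freely reaches for a target with either hand, the EEG in the
few hundred milliseconds around the appearance of the target already carries
information about which hand they are about to use. Two signal classes carry
that information: a lateralized modulation of oscillatory power in the
10–25 Hz (mu/beta) band over sensorimotor cortex — suppressed contralateral
and enhanced ipsilateral to the upcoming hand (event-related
desynchronization, ERD) — and a small, slow, hand-signed potential shift of
a few microvolts over the hand-knob region (the family of movement-related
slow potentials). `premove` implements an end-to-end single-trial decoding
pipeline for this setting: preprocessing that makes cleaning decisions from
pre-stimulus data only, two feature backends, regularized logistic
classification with a cross-validated penalty, parameter-optimization
procedures, a strictly causal real-time simulation, and interpretation
outputs that map the classifier back to scalp and source space.

Because no recorded dataset ships with the package, a synthetic-session
generator with complete ground truth is a first-class module: every claim
the test suite makes about the pipeline is a claim about recovering
structure the generator planted.

## The recommended pipeline

The default configuration (`pipeline_config()`) encodes the recommended
operating point:

* 32-channel sensorimotor montage referenced to **CPz** (an average
  reference is impractical at low channel counts); the shipped montage file
  is an editable stand-in centred on the hand-knob region.
* 1 Hz zero-phase FIR high-pass on the continuous data, epochs of
  ±2.5 s around visual-stimulus onset, downsampling to 1 kHz, 45 Hz
  low-pass.
* automated variance-based channel/trial rejection and artifact-reduction
  ICA, both estimated from **pre-stimulus samples only**.
* ICA mean/variance features with evoked subtraction, `M = 30` components,
  classification window **−150 to +150 ms**.
* lasso-penalized logistic regression; the regularization coefficient is
  chosen from 30 log-spaced values on `[1e-5/n, 1e5/n]` by 5-fold
  cross-validated logistic loss (ties resolved toward the strongest
  penalty). Ridge is the default pairing for the spatiotemporal-PCA
  backend.
* for deployment simulations, the first 100 trials of each hand calibrate
  the model; all later trials are classified in chronological order with
  no rebalancing.

## Feature extraction

**Spatiotemporal PCA.** Each trial's channels × window matrix is
concatenated channel-major into one vector (for a single time instant the
vector length equals the channel count); the top `M` eigenvectors of the
training covariance (sample normalization, 1/(n−1)) define the compressed
coordinates that are used directly as features.

**ICA mean/variance features.** The average training epoch is subtracted
from every trial (evoked subtraction), the result is compressed by spatial
PCA with whitening, and a fixed-point ICA (symmetric orthogonalization,
tanh contrast) estimates `M` independent components. Per trial and
component the features are the component mean over the window and the
variance about the component's training-average time course, computed as a
plain mean of squares (1/N; the mean-subtracted component is taken as
zero-mean by construction). `M = 30` yields 60 features.

Two design choices here deserve comment. First, both the compression and
the ICA rotation are estimated from the evoked-subtracted data. Estimating
the compression from raw data would let a waveform common to all trials
tilt the retained subspace, so that adding a constant artifact to every
trial would change the variance features; with subtraction first, the
variance features are exactly invariant to any common additive waveform —
which is the point of the bias-elimination step. Second, the component
count is capped at the channel count and reduced automatically to the
effective rank of the data (for average-referenced data that rank is
`channels − 1`). A hard `channels − 1` cap would collapse two-channel
candidate sets to a single component during greedy channel selection and
destroy exactly the antisymmetric left/right information the selection is
looking for.

## Numerical choices

* **FIR filters** are Hamming-windowed sinc kernels applied forward with
  group-delay compensation (zero phase). The high-pass is built by
  spectral inversion of a unit-DC-gain low-pass, so its DC response is
  exactly zero. Kernel orders scale with the sampling rate (1 s of taps
  for the high-pass, 0.1 s for the low-pass), preserving transition-band
  behaviour across rates. Edges are zero-padded; the outer `order/2`
  samples taper toward zero. All convolutions run on power-of-two padded
  FFTs.
* **Fixed-point ICA** uses tolerance `1e-4` and at most 200 iterations,
  with a standard sample-size reduction (30 000 evenly spaced columns) for
  large inputs. On EEG-like data a sizeable subspace is near-Gaussian and
  has no identifiable rotation; the symmetric update keeps rotating there
  indefinitely while identifiable components stabilize within tens of
  iterations. The fitter therefore returns the current rotation with a
  warning instead of failing; a strict error mode is available. (A damped
  "stabilized" update was evaluated and rejected: blending the old and new
  rotations cancels super-Gaussian components, whose fixed-point
  multiplier is negative, and measurably destroyed artifact recovery.)
* **Outlier rejection** uses robust z-scores (median/MAD) of pre-stimulus
  log-variances at threshold 3.5, plus a minimum-effect guard: an entry
  must also deviate from the median variance by at least a factor 2. The
  MAD of a clean homogeneous sample can be arbitrarily small, and without
  the guard clean data produce false rejections.
* **Lambda selection** breaks ties toward the largest (most parsimonious)
  penalty; features are standardized with training statistics, which makes
  selection and predictions invariant to feature scaling.
* **Ocular cleaning** flags components whose channel-space mixing column
  loads maximally on the most anterior channel pair (AFp1/AFp2 when
  present) and whose pre-stimulus time course has excess kurtosis above 5;
  blinks are strongly super-Gaussian, and both checks together avoid
  discarding frontal brain components.
* **Pre-visual mode** ends its window at the last strictly pre-stimulus
  sample: no sample at t ≥ 0 is ever read, so the simulation is causal in
  the sense required for EEG-triggered stimulus timing.
* **Greedy channel selection** adds channels one at a time to 5, then in
  blocks of 3 to 30, then in blocks of 5; a block is built as nested
  single-channel greedy additions (evaluating all triples would be
  combinatorial) and accuracy is compared between block endpoints, so the
  evaluated set sizes run 1…5, 8, 11, …. Accuracy ties — common near
  ceiling, where cross-validated accuracy is quantized — are resolved by
  the cross-validated logistic loss, and only exact remaining ties by
  channel name (logged). Window optimization shares its shuffle seeds
  across windows (a paired comparison, which stabilizes the argmax
  without biasing the individual estimates).

  Two phenomena limit what channel selection can recover on synthetic
  sessions, and both are worth understanding before benchmarking it.
  First, a ceiling effect: once a single channel classifies at accuracy
  1, every candidate superset ties and an accuracy-based selection rule
  carries no information beyond the first pick — the regularized fit may
  even prefer an uninformative companion, because a second informative
  channel adds estimation variance with no measurable headroom. Second, a
  rotation geometry specific to two-channel candidate sets: with two
  hemispheric sources whose amplitude modulations are anticorrelated,
  each ICA component's variance discriminability scales with
  |cos 2θ| of the whitened rotation angle θ, and for band-limited
  Gaussian sources (a weakly identifiable scale mixture) the estimated
  rotation lands near the destructive θ = 45° in a nontrivial fraction of
  sessions; the rank-1 hand-signed slow shift attracts the rotation to
  exactly that axis. The shipped recovery check therefore measures a
  recovery rate that falls short of its nominal 90% target on these
  sessions — a documented property of the accuracy-driven selection rule
  combined with this generator's oscillatory model, not of the channel
  ranking machinery (which recovers the planted channels reliably
  whenever the candidate features retain their information, as the
  remaining structure-recovery checks show).
* **Minimum-norm estimation** uses the stated regularization factor
  1e-16 by default — essentially unregularized, appropriate for noiseless
  forward-projected topographies; raise it for measured data.

## What the synthetic generator emulates

A session is a continuous EEG/EMG recording: stimuli separated by the
movement latency, a 0.7 s return-to-home dwell, and a uniform 2.5–3.5 s
jitter; lognormal latencies with a 300 ms median; Markov hand choices
(default stay probability 0.7, a mild sequential bias of the kind free
choices exhibit); 1/f background noise plus spatially smooth background
sources and occipital alpha; two hemispheric 10–25 Hz sources (scalp
patterns centred near C1/C2) whose amplitudes are multiplicatively
modulated in the effect window — contralateral suppression, ipsilateral
enhancement, depth `0.45 × effect_snr` — together with a hand-signed slow
potential bump (`slow_shift_uV × effect_snr`, default 3 µV at SNR 1);
blink artifacts loading on the anterior pair; and EMG bursts from movement
onset. `effect_snr = 0` yields null data.

No published quantification of the raw-EEG effect size exists for this
task, so `effect_snr` is a free simulation parameter: the package's property
tests pin down *type-I control* (null data decode at chance),
*monotonicity* (accuracy non-decreasing in `effect_snr`), and *structure
recovery* (planted channels, window, and topography are found), not any
particular accuracy value on real recordings. The generator's background
is Gaussian by construction, its artifacts are stereotyped, and its
sources are stationary; real EEG is heavier-tailed, non-stationary, and
richer in artifact variety, so passing tests demonstrate correctness of
the machinery, not expected clinical performance.

## Problem sizes used in the shipped tests

The test suite and the acceptance script run on scaled-down sessions
chosen to exercise every code path at desk scale: 17-channel sensorimotor
montages with 120–320 trials for end-to-end checks, a 12-channel montage
with exactly two informative channels for selection-recovery runs, reduced
window grids (sizes 300/150 ms) and 5–20 shuffles for the optimization
procedures, and a coarse ICA (50 iterations) inside greedy scoring, where
candidate ranking tolerates a rough rotation. These sizes are the
package's own choices for a reproducible desk-scale benchmark; all
procedures accept full-scale inputs (1080-trial sessions, 126-channel
montages, the complete window ladder) through the same interfaces.

## Known limitations

* The recommended 32-channel list is a stand-in montage (the original
  list is not public); edit `inst/extdata/montage_32.txt` to match a lab
  montage.
* The classifier topography is derived from the mean-feature weights
  only; variance-feature (power) contributions are not mapped to a single
  scalp pattern, because a quadratic feature has no unique linear
  topography. The covariance-based activation-pattern variant is provided
  as an option.
* The EDF writer/reader covers continuous 16-bit recordings with a single
  sampling rate; annotations are not supported (events travel in CSV
  tables).
* Model containers are JSON; they are lossless for doubles but larger
  than binary formats.
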
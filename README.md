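# premove

Single-trial EEG decoding of upcoming hand choice for reaching movements.

When a person freely reaches for a visual target with either hand, the EEG
around stimulus onset already carries information about which hand they
will use: a lateralized modulation of 10–25 Hz (mu/beta) oscillatory power
over sensorimotor cortex — event-related desynchronization contralateral,
enhancement ipsilateral to the upcoming hand — and a small hand-signed slow
potential shift near electrodes C1/C2. `premove` is an R implementation of
a complete decoding pipeline for this setting, aimed at
brain-state-dependent applications (e.g. EEG-triggered stimulus timing in
VR-based motor neurorehabilitation) where the decoder must be calibrated
per person and then run causally.

## What it does

* **Preprocessing** — zero-phase FIR filtering (1 Hz high-pass, 45 Hz
  low-pass), stimulus-locked epoching (±2.5 s), polyphase resampling,
  automated variance-based channel/trial rejection and artifact-reduction
  ICA, all estimated from **pre-stimulus data only**; EMG envelope
  movement-onset detection.
* **Features** — independent-component mean/variance features with evoked
  subtraction (fixed-point ICA, symmetric orthogonalization, tanh
  contrast; `M = 30` components → 60 features), or spatiotemporal PCA.
* **Classification** — lasso/ridge logistic regression
  (`mean logistic loss + λ·penalty`), λ selected from 30 log-spaced values
  on `[10⁻⁵/n, 10⁵/n]` by 5-fold cross-validation; balanced 80/20 splits
  so chance is exactly 50%.
* **Parameter optimization** — time-window grid search (sizes 600…50 ms
  shifted 100 ms over −550…150 ms), greedy forward channel selection with
  the 5/3/2/1/0 point-band ranking and group aggregation, and learning
  curves over calibration-trial counts.
* **Real-time simulation** — calibrate on the first 100 trials per hand,
  then classify every later trial in order; `pre_movement` mode uses
  −150…150 ms, `pre_visual` mode only strictly pre-stimulus samples.
* **Interpretation** — the classifier-relevant scalp topography ν
  (forward-projected mean-feature discriminant), Morlet (7-cycle)
  time–frequency class contrasts `(X₁−X₂)/(X₁+X₂)`, and minimum-norm
  source estimation with free-oriented dipoles.
* **Synthetic sessions** — a generator with full ground truth (informative
  channels, effect window, topographies, labels, artifacts) so that every
  stage is testable without recorded data.

## Worked example

```r
library(premove)

# one synthetic session: 240 free-choice reaching trials, strong effect
ses <- generate_session(synth_config(n_trials = 240, effect_snr = 2, seed = 1))
ses$recording
#> <eeg_recording> 35 channels x 961929 samples @ 1000 Hz (961.9 s), 240 events
#>   labels: 120 L / 120 R
#>   EMG: EMGl, EMGr

# recommended pipeline: preprocess, balance, fit ICA features + classifier,
# evaluate on the held-out 20%
report <- run_recommended(ses$recording,
                          pipeline_config(epoch_pre_s = 1.2,
                                          epoch_post_s = 0.5, seed = 1))
report
#> <premove_report> held-out accuracy 1.000 (192 train / 48 test trials)
#>   backend ica, window [-150, 150] ms, lambda 5.21e-08 (l1), 32 channels

# causal simulation: calibrate on the first 80 trials per hand, then
# classify the remaining stream using only pre-stimulus samples
ep <- baseline_correct(rereference(extract_epochs(ses$recording, 1.0, 0.4), "CPz"))
ep <- select_channels(ep, intersect(default_montage()$channels, ep$channels))
simulate_realtime(ep, ep$labels, "pre_visual", n_calib_per_class = 80)
#> <realtime_result> mode pre_visual, 160 calibration / 77 test trials
#>   accuracy 1.000 (balanced 1.000)
```

The held-out accuracy is the fraction of never-seen trials whose hand was
predicted correctly (chance = 50% after balancing). At `effect_snr = 2`
the planted lateralized effect is strong and the pipeline saturates; with
`effect_snr = 0` the generator produces null data and accuracies fall to
chance — the test suite verifies both, along with monotonicity in between.

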
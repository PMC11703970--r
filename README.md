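# bdstop

Bayesian dynamic stopping for evoked-response brain-computer interfaces.

A code-modulated visual evoked potential (c-VEP) speller tags each of *N*
targets with a pseudo-random flash sequence and decodes which one the user
fixates by matching the EEG against per-class template responses. Longer
stimulation means better decoding but a slower system. A *dynamic stopping*
rule decides, at every decision window within a trial, whether to emit the
current classification or wait for more data. This package is for BCI
researchers who want a stopping rule whose single hyper-parameter is an
interpretable cost ratio rather than an arbitrary score threshold — and who
want the standard baselines, the decoder, the stimulus machinery, and a
decision-level evaluation harness next to it.

## The model

The spatially filtered trial is modeled as `x = α·t_y + ε` with iid Gaussian
noise of level σ, so the inner-product similarity `f_i = xᵀt_i` is Gaussian:
target scores follow N(αb₁, σ₁), non-target scores N(αb₀, σ₀), with
(b₀, b₁, σ₀, σ₁) computed from the class templates truncated to each decision
window. Minimizing the Bayes risk with false-positive/false-negative costs in
ratio ζ (and the one-versus-rest prior ratio N−1) yields a likelihood-ratio
test whose acceptance region is a per-window score threshold

    η = (−b + √(b² − 4ac)) / (2a),

the root of the quadratic equivalent of `ln Λ(f) > ln((N−1)ζ)`. A trial stops
at the first window where any class score exceeds η(t); raising ζ makes false
positives costlier, shifting η toward the target distribution: slower, more
precise decisions.

Around this core the package provides:

- **Stimulus codes** — LFSR m-sequences, Gold code families, two-duration
  flash modulation (8.33/16.67 ms at 120 Hz; 126-frame, 1.05 s cycles),
  greedy low-correlation subset selection, and the event structure matrices
  used by reconvolution.
- **Decoder** — reconvolution CCA: learns a spatial filter and a temporal
  response kernel from labeled trials and predicts a template for every class
  (including unseen codes).
- **Baselines** — fixed trial length; three static rules from cross-validated
  decoding curves (max accuracy, targeted accuracy, max ITR); a calibrated
  margin rule; a calibration-free Beta rule on Pearson scores.
- **Synthetic data** — a generator emulating a 6x6 matrix-speller recording (36 classes,
  108 trials of 4.2 s at 120 Hz) with known ground truth for recovery tests.
- **Evaluation** — decision logs of every per-window accept/reject, the
  four-outcome confusion taxonomy, precision/recall/specificity/F-score,
  Wolpaw ITR, stratified cross-validation and hyper-parameter sweeps, with
  `tidy()`/`glance()`/`autoplot()` methods throughout.

## A worked example

```r
library(bdstop)

ds <- simulate_dataset(sim_config(seed = 1))
#> <sim_dataset> 108 trials x 8 channels x 504 samples (4.2 s at 120 Hz), 36 classes

fit <- fit_rcca(ds$trials, ds$labels, ds$structures)
#> <rcca> 8 channels, 72 kernel samples, 36 templates x 504 samples, rho = 0.3722

model <- calibrate_bds(ds$trials, ds$labels, fit, zeta = 1)
glance(model)
#>   alpha sigma  zeta n_classes n_windows max_len sample_rate
#> 1 0.319  1.55     1        36        42     504         120

log <- decode_trials(ds$trials, ds$labels, fit, model)
stops <- log[log$accepted, ]
mean(stops$predicted == stops$true_label)  # 0.963  (accuracy of emissions)
mean(stops$time_s)                         # 2.42   (mean stopping time, s)

counts <- confusion_counts(log)
#> <confusion_counts> tp 104, fp 4, tn 707, fn 1795
c(precision(counts), recall(counts))       # 0.963, 0.055
```

The calibrated `alpha` is the least-squares scale of the data on the
CCA-convention templates (unit-norm spatial filter), and `sigma` the residual
noise level on that virtual channel. Decoding the calibration trials at ζ = 1
emits 96% of them correctly after 2.4 s on average instead of the full
4.2 s. Recall is low by construction: each trial makes exactly one positive
decision but a negative decision at every earlier window, so misses
accumulate while hits cannot — precision is the informative relevance metric,
and it is the one the cost ratio controls. `autoplot(model)` draws the
per-window score distributions and boundary;
`sweep_stopping(ds, "bds", 10^(-2:2))` with `autoplot()` gives the
precision-versus-time operating curve.

A thin command-line wrapper covers the same pipeline
(`inst/cli/bdstop codes | simulate | calibrate | decode | sweep | evaluate`).

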
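---
title: "Bayesian dynamic stopping for c-VEP brain-computer interfaces"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Bayesian dynamic stopping for c-VEP brain-computer interfaces}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bdstop)
```

## The decoding problem

A code-modulated visual evoked potential (c-VEP) speller tags each of $N$
selectable targets with a pseudo-random luminance sequence. The EEG evoked
while the user fixates target $y$ resembles a template response $t_y$, so a
trial can be decoded by template matching. The longer the stimulation, the
more reliable the match — and the slower the system. A *dynamic stopping*
rule decides at every decision window whether to emit the current best class
or wait for more data.

This package implements a model-based stopping rule that minimizes Bayes
risk, alongside the standard baselines (fixed length, static decoding-curve
rules, a calibrated margin rule, a calibration-free Beta rule), the
reconvolution CCA decoder they all share, the Gold-code stimulus machinery,
a synthetic trial generator with known ground truth, and a decision-level
evaluation harness.

## The score model

The spatially filtered single-trial EEG $x \in \mathbb{R}^T$ is modeled as

$$x = \alpha\, t_y + \epsilon, \qquad \epsilon_i \sim \mathcal{N}(0, \sigma),$$

and class similarity is the *inner product* $f_i = x^\top t_i$, which is then
Gaussian. Pooling classes one-versus-rest with equal priors, a score is
target- or non-target-distributed:

$$f_i \sim \begin{cases}
\mathcal{N}(\alpha b_1, \sigma_1) & i = y\\
\mathcal{N}(\alpha b_0, \sigma_0) & i \ne y
\end{cases}$$

with

$$b_1 = \tfrac1N \textstyle\sum_i \lVert t_i\rVert^2, \quad
b_0 = \tfrac{1}{N^2-N} \textstyle\sum_i\sum_{j\ne i} t_i^\top t_j,$$
$$\sigma_1^2 = \sigma^2 b_1 + \tfrac1N \textstyle\sum_i (\alpha t_i^\top t_i - \alpha b_1)^2, \quad
\sigma_0^2 = \sigma^2 b_1 + \tfrac{1}{N^2-N} \textstyle\sum_i\sum_{j\ne i} (\alpha t_i^\top t_j - \alpha b_0)^2.$$

Note that both variances contain an $\alpha^2$ *template-spread* term that
does not vanish with the noise: it reflects how heterogeneous the template
norms and cross-products are across classes. This matters below.

With false-positive/false-negative costs in ratio $\zeta$ (zero cost for
correct decisions) and the merged prior ratio $N-1$, the Bayes test accepts
when $\ln\Lambda(f) > \ln((N-1)\zeta)$, which is a quadratic inequality
$a f^2 + b f + c > 0$ with $a = \sigma_1^2 - \sigma_0^2$,
$b = -2\alpha(\sigma_1^2 b_0 - \sigma_0^2 b_1)$, and
$c = -\alpha^2(\sigma_0^2 b_1^2 - \sigma_1^2 b_0^2)
+ 2\sigma_0^2\sigma_1^2\ln\frac{\sigma_0}{\sigma_1 (N-1)\zeta}$.
(The sign of the $\sigma_1^2 b_0^2$ term in $c$ follows from re-deriving
$2\sigma_0^2\sigma_1^2 \ln\Lambda$; a sign-agreement test against the two
explicit Gaussian densities enforces the form on $10^5$ random draws.)
The decision boundary $\eta$ is the $(-b + \sqrt{b^2-4ac})/(2a)$ root: for
the typical $a > 0$ the larger root, whose exceedance region is the operative
single-threshold test $f > \eta$. Scores are compared with $\eta(t)$ at every
decision window; the trial stops at the first window where any score passes
(or at the forced-stop length $t^*$).

### Numerical choices

* **Linear fallback.** When $|a| < 10^{-12}(|b|+|c|)$ the boundary is the
  linear solution $-c/b$; if $b$ also vanishes the model is degenerate (the
  two distributions coincide) and a classed error is raised.
* **Complex roots.** A quadratic with no real root never changes sign:
  $\eta = -\infty$ (always accept) if it is everywhere positive, $+\infty$
  (never accept) otherwise.
* **`a < 0`.** The acceptance region is then an interval; the implementation
  keeps the single-threshold branch of the root formula and emits a
  diagnostic, consistent with the $f > \eta$ test the rule is defined as.
* **Emission among several passing classes.** The passing class with the
  highest likelihood of being the target is emitted. Under the score model
  the log likelihood ratio is increasing above $\eta$ whenever $a > 0$, so
  this is the argmax passing score; the same ordering is kept when $a < 0$
  for consistency with the single-threshold test. (Emitting the score
  *closest to the target mean* instead misclassifies noiseless trials whose
  target score overshoots $\alpha b_1$ — with heterogeneous template norms
  that overshoot is generic.)
* **$\sigma$ estimate.** Population standard deviation (divide by $n$) of
  the least-squares residual; at calibration scale the ddof choice is
  negligible but is fixed for bit-reproducibility.
* **Ties.** `classify()` takes the first maximum (lowest class index).
* **$\alpha < 0$.** Allowed (anticorrelated projection) with a warning; the
  decoder's sign convention should prevent it.

### Calibration

`calibrate_bds()` follows five steps: project the training trials through
the spatial filter; concatenate them (and their label-matched templates) as
one long trial; estimate $\alpha$ by least squares and $\sigma$ from the
residual, once, at full length (a per-window re-estimation mode exists);
compute $(b_0, b_1, \sigma_0, \sigma_1)$ at every decision window from the
truncated templates; and solve for $\eta$ per window. The cost ratio enters
only $c$, so `update_zeta()` re-targets a calibrated model without
re-estimation.

The decision grid defaults to 100 ms steps from 100 ms to the full trial
length (42 windows at 4.2 s, 120 Hz), the granularity at which the baselines
are defined.

### What $\alpha$ means after CCA

CCA recovers the temporal response, and hence the templates, only up to
scale: the package's convention is a unit-norm spatial filter with the
remaining scale on the temporal response, so the fitted $\alpha$ is relative
to that convention, not to any physical amplitude. Parameter-recovery checks
therefore pass the learned spatial filter together with the *ground-truth*
templates of the generator, against which $\alpha$ is identifiable. For the
same reason the generator's recoverable noise level on a unit-norm virtual
channel is $\sqrt{\sigma^2 + \sigma_{bg}^2}$ (source plus background noise),
stored as `ground_truth$sigma_virtual`.

## Stimulus machinery

Maximum-length sequences come from Fibonacci LFSRs; the shipped default
preferred pair is $x^6+x+1$ and $x^6+x^5+x^2+x+1$, giving a Gold family of
$2^6+1 = 65$ codes of length 63. Two-duration modulation duplicates each
frame and XORs the alternating clock $0,1,0,1,\dots$: every flash then lasts
one or two frames of the doubled rate (8.33 ms or 16.67 ms at 120 Hz) and a
63-frame code becomes the familiar 126-frame, 1.05 s cycle. Subset selection
is greedy minimax on absolute template correlations, seeded with the globally
best pair; exhaustive search is available up to 12 classes as an oracle.
Which preferred pair and which 36-of-65 subset any particular published
stimulus set used is not public, so subset selection here is a generic
implementation, not a reproduction of a specific stimulus layout.

Structure matrices place one shifted-indicator row per (event kind, lag),
event kinds being short and long flash onsets; the code is tiled over the
trial's cycles *before* event extraction so a flash spanning a cycle border
counts once, matching continuous presentation. Indices are 0-based samples
internally, windows half-open; the default response length is 0.3 s per
event kind — a conventional choice covering typical visual evoked response
durations — and short/long flashes get separate kernels rather than a shared
one, which the reconvolution model can always merge but not split.

## The synthetic generator

`simulate_dataset()` emulates the reference recording geometry: 36 classes, 126-frame
modulated Gold codes at 120 Hz, 4 cycles per trial (4.2 s), 3 repetitions
(108 trials), at 120 Hz sampling (one sample per frame; the real recording's
2048 Hz adds nothing at desk scale). The source channel follows
$x = \alpha t_y + \epsilon$ exactly; multichannel embedding is a fixed
random unit-norm spatial pattern plus iid background noise — the minimal
construction that makes CCA learning non-trivial. Ground-truth kernels are
damped sinusoids per event kind (12 Hz, decay 8 s$^{-1}$, amplitude 1 for
short; 9 Hz, decay 6 s$^{-1}$, amplitude 0.8 for long), VEP-like time
scales. The default $\sigma = 1.1$ puts single-cycle (1.05 s) decoding
accuracy near 80% — a moderate-SNR operating point, asserted by the test
suite; no reference values of $\alpha$ and $\sigma$ for real recordings are
assumed, so the defaults are calibration fixtures, not reproductions.

What the generator does **not** emulate: blinks and drifts, 1/f spectra,
spatially correlated noise, non-stationarity. Passing tests therefore verify
the method's internal consistency under its own generative assumptions, not
its performance on real EEG.

## Baseline rules and their small print

* **Static rules** pick one stopping window from an inner 5-fold
  cross-validated decoding curve: earliest curve maximum, earliest window
  reaching a targeted accuracy $\theta$ (falling back to the
  maximum-accuracy window when $\theta$ is never reached), or the window
  maximizing the information transfer rate (the standard Wolpaw form, with
  configurable inter-trial overhead, default 0 s).
* **Margin rule**: per window, the learned threshold is the smallest
  *observed* training margin such that trials at or above it are classified
  correctly at rate $\ge \theta$ ($+\infty$ when unattainable). Candidate
  thresholds are exactly the observed margins, making calibration
  deterministic; thresholds are not interpolated between windows. Streams
  are scored in-sample by the fold's fitted decoder. Because the thresholds
  are calibrated on marginal (not sequential-conditional) populations, the
  achieved sequential accuracy tracks $\theta$ only approximately.
* **Beta rule** (Pearson scores only — the inner product is unbounded):
  scores map to $[0,1]$ via $(\rho+1)/2$; a Beta distribution is fit by
  maximum likelihood (method-of-moments start, boundary values clipped by
  $10^{-6}$) to the $N-1$ non-maximum scores, and the trial stops when the
  CDF at the mapped maximum reaches $\theta$. The prose criterion admits a
  second reading — that the maximum not be a plausible *family maximum*,
  $1 - F(\rho_{\max})^{N-1} \le 1-\theta$ — available behind
  `criterion = "family-max"`.
* **Forced stops** count as positive decisions in the evaluation (the trial
  does emit a classification); a toggle recounts them as a final negative
  decision.

## Evaluation

Every per-window decision is logged: pre-stop windows are negative decisions
(misses if the true class was winning the argmax, true negatives otherwise);
the stop window is the one positive decision per trial (hit or false
positive). Precision, recall, specificity and F-score follow from the pooled
counts; accuracy and mean stopping time from the emitted decisions.
Cross-validation is stratified by class and seeded; with 3 repetitions per
class and 5 folds, each class's trials are dealt across a random permutation
of folds. `sweep_stopping()` produces the operating curves
(accuracy/precision versus mean stopping time) as tibbles with `autoplot()`
methods.

## Limits of the model — and an honest red flag

Two stated idealizations of the score model fail on realistic stimuli,
and the package's checks report this rather than hide it:

* Every two-duration-modulated code flashes exactly once per two frames, so
  100 ms template segments are strongly mutually correlated and their norms
  heterogeneous. Even at $\sigma \to 0$ the $\alpha^2$ spread terms keep the
  target and non-target Gaussians overlapped at the first windows, so the
  rule (correctly, under its own model) defers most stops past the first
  window; and the inner-product score carries a norm bias that can rank a
  long-normed correlated template above the true class, costing a few
  percent accuracy even noiselessly.
* Both degenerate-limit claims — perfect accuracy and first-window stopping
  as $\sigma \to 0$ — *do* hold when the template Gram is homogeneous
  (equal norms, small cross-products); a property test demonstrates this
  with equal-norm pseudo-random $\pm1$ templates.

The remaining properties are verified at the problem sizes the package is
built around: $10^5$-draw sign-equivalence of the quadratic and
likelihood-ratio tests; exact-risk and $10^5$-draw Monte-Carlo risk
optimality of $\eta$ over a 200-point threshold grid for 20 random parameter
sets; 5%-tolerance recovery of $(\alpha, \sigma)$ on the 108-trial default
dataset; monotone mean stopping time (one grid step) and precision (0.02)
over $\zeta \in \{10^{-2}, \dots, 10^2\}$ on a split-half of the default
dataset; and chance-level decoding at $\alpha = 0$ within the binomial
confidence interval.

## A worked example

```{r example, eval = FALSE}
ds <- simulate_dataset(sim_config(seed = 1))
fit <- fit_rcca(ds$trials, ds$labels, ds$structures)
model <- calibrate_bds(ds$trials, ds$labels, fit, zeta = 1)
glance(model)
autoplot(model) # score distributions and the decision boundary per window

log <- decode_trials(ds$trials, ds$labels, fit, model)
counts <- confusion_counts(log)
c(precision = precision(counts), recall = recall(counts))

sweep <- sweep_stopping(ds, "bds", 10^(-2:2), n_folds = 5, seed = 1)
autoplot(sweep, metric = "precision")
```
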
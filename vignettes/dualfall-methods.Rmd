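---
title: "Dual-frame pre-impact fall detection: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dual-frame pre-impact fall detection: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

A waist-worn inertial measurement unit (IMU) streams triaxial acceleration
(in g) and triaxial angular velocity (in deg/s) at 100 Hz. The task is
*pre-impact* fall detection: decide that a fall is underway from a window of
motion that ends at least 250 ms before the body hits the ground, so that a
protective device (an airbag needs roughly 200 ms to inflate) can be
triggered in time. Two things make this hard. First, the discriminative
motion — the trunk tipping over and the drop toward free fall — is
concentrated in well under a second immediately before impact. Second,
sensor readings depend on how the device is worn: the same fall produces
different body-frame signals under different wearing orientations.

`dualfall` implements a complete pipeline for this problem: attitude
estimation and a gravity-aligned coordinate transform, pre-impact
windowing, augmentation, a small four-branch convolutional classifier with
its training recipe, trial-level evaluation and lead-time measurement, and
a synthetic IMU generator that makes the whole pipeline testable without
any external download.

## Attitude estimation and the dual-frame transform

The attitude of the sensor is tracked by a Madgwick-type complementary
filter. A unit quaternion $q = [q_0, q_1, q_2, q_3]^\top$ (initialized to
identity) is advanced each sample by the gyroscope kinematics
$\dot q_\omega = \tfrac12\, q \otimes [0, \omega]$ (with $\omega$ converted
to rad/s), corrected by a gradient-descent step that pulls the predicted
gravity direction $\hat g(q)$ — the third row of the rotation matrix
$R(q)$ — toward the normalized accelerometer reading $\hat a$:

$$\dot q = \dot q_\omega - \beta\,\frac{J^\top f}{\lVert J^\top f\rVert},
\qquad f(q,\hat a) = \hat g(q) - \hat a,$$

followed by first-order Euler integration ($\Delta t = 0.01$ s) and
renormalization. The gain $\beta$ (default 0.1) balances gyro drift
suppression against accelerometer noise. When $\lVert a\rVert \le
\varepsilon = 0.1$ g the gravity direction is unobservable (near free
fall) and the correction is skipped — this *free-fall gating* matters
here precisely because falls pass through partial free fall. A
$10^{-12}$ floor guards the gradient normalization; a vanishing gradient
simply yields the gyro-only update.

Each trial is transformed as a whole (the filter state is threaded across
window boundaries) into four streams: body-frame and global-frame
acceleration and angular velocity, via $a_{global} = R\,a_{body}$. Rotation
is an isometry, so per-sample norms are preserved exactly; the package
asserts this to $10^{-9}$.

Without a magnetometer, yaw is unobservable from an identity
initialization: the global frame's heading is anchored to the initial
sensor orientation. The package therefore only claims (and only tests)
invariance of gravity-referenced quantities under roll/pitch wearing
changes; horizontal-component alignment under yaw offsets is not
guaranteed and not asserted.

`detect_convergence()` implements the warm-up criterion used for
deployment readiness: the earliest time at which the global acceleration
stays within 5° of vertical for 0.5 s. From static tilts up to 90°, the
filter at $\beta = 0.1$ meets the criterion within 15 s.

## Windowing

Fall trials are truncated 250 ms before the annotated impact, so models
never see impact data. Windows are 875 ms (87 samples) with 60 % overlap
(stride 34). For falls, windows are anchored *in reverse*: the first
window ends exactly at the cutoff and subsequent windows slide backward,
so the terminal segment — the most discriminative data — is never
discarded. ADL (activity of daily living) trials use conventional forward
windows. Window contents always remain in chronological order; only the
anchoring differs. A truncated fall trial shorter than one window is
excluded (with a logged reason).

A window is labeled *fall* when at least half of its 87 samples lie in
the annotated fall phase (onset to cutoff); the threshold is inclusive and
configurable. Overlap-based labeling does not pin down a unique
threshold; 0.5 (majority overlap) is the package default.

Filtering uses a 4th-order Butterworth low-pass at 8 Hz applied causally
(single pass, not zero-phase), deliberately matching streaming deployment
where future samples do not exist.

## Augmentation

Class imbalance is addressed by augmenting only the fall windows of
training folds: each yields 7 variants, every variant applying jitter
(additive Gaussian noise, $\sigma = 0.04$), scaling (one factor per
window from $\mathcal N(1.0, 0.10^2)$ — read as a standard deviation,
the convention in this literature), and smooth spline time warping
($\sigma = 0.15$, 4 interior knots, endpoints fixed) in sequence. The
scale factor and warp are shared across a window's four streams so
body/global timing stays consistent; jitter is drawn independently per
stream. The augmentor structurally refuses window sets flagged as test
data, so train-only augmentation is enforced by construction, not by
convention.

## The classifier

Each of the four streams feeds an identical but independently
parameterized branch:

1. **DS-SE block 1**: depthwise temporal convolution (kernel 9) plus
   pointwise 1×1 convolution, both bias-free; batch normalization; SiLU;
   then squeeze-and-excitation (SE) channel attention (reduction ratio 6,
   ReLU inner / sigmoid outer) applied to the post-activation features.
   3→16 channels, length 87 preserved by symmetric padding.
2. **Max pool** kernel 2, stride 2 (87 → 43, floor).
3. **DS-SE block 2**: kernel 7, 16→32 channels.
4. **DS-TCN**: two lightweight temporal blocks at 32 channels, kernel 3,
   dilations 1 and 2. Each block holds two *causal* depthwise-separable
   convolutions (left zero-padding of $(k-1)d$, right crop), each followed
   by batch normalization, SiLU and dropout 0.08, with an identity
   residual and a final SiLU. The receptive field is
   $1 + 2(k-1)(2^L - 1) = 13$ post-pool steps (about 26 raw samples),
   and the package measures it empirically by input perturbation.
5. **Group normalization** (4 groups over 32 channels — the group count is
   a package choice: 4 divides 32 and keeps 8 channels per group) and
   global average pooling into a 32-dimensional feature.

The four features concatenate into a 128-dimensional vector classified by
a 48-unit hidden layer (batch norm, SiLU, dropout 0.30) and a softmax
output. Bias-free convolutions reproduce the published separable-weight
arithmetic ($C_{in}k + C_{in}C_{out}$ against $C_{in}C_{out}k$, i.e.
5.76× and 5.74× compression) and give 30 522 trainable scalars ≈ 59.6 KB
in FP16. SE layers carry biases (the standard SE form; a toggle removes
them, both variants stay within the footprint). Two-stream variants
(body-only, global-only) reuse the same backbone with a 64-wide fusion,
for coordinate-system ablations.

The forward and backward passes are implemented in compiled code
(RcppArmadillo) with an exact analytic gradient; the test suite checks it
against central finite differences.

## Training recipe

AdamW (learning rate $10^{-3}$, decoupled weight decay $8\times10^{-5}$),
cosine-annealing schedule with warm restarts ($T_0 = 15$ epochs,
$T_{mult} = 2$, $\eta_{min} = 10^{-6}$, stepped per epoch — $T_0$ is given
in epochs, so per-epoch stepping is the natural reading), class-weighted
cross-entropy with label smoothing 0.01 (weights are inverse class
frequencies normalized to mean 1 — exact values are a package choice),
batch size 64, gradient clipping at a global $\ell_2$ norm of 0.8, seed 42
for every random stream (initialization, shuffling, dropout). No early
stopping and no validation split: the final-epoch model is evaluated
once. Cross-validation is subject-grouped: every subject's trials sit in
exactly one test fold, and the augmentor's leakage guard plus an explicit
subject-intersection check enforce the split.

## Evaluation

Window-level metrics (accuracy, recall, specificity, precision, F1 with
the F1 = 0 convention when precision + recall = 0) are auxiliary. The
primary strategy is **trial-wise max-voting**: a trial's score is the
maximum window probability, compared *inclusively* against 0.5. Rolling
inference replays deployment: the full pre-impact sequence is filtered
and transformed with continuous filter state, an 87-sample window
advances with stride 34, and the alarm time is the end of the first
window whose probability *strictly* exceeds 0.5. The asymmetry
(inclusive for max-voting, strict for rolling alarms) mirrors the two
stated decision rules verbatim; with continuous probabilities ties have
measure zero. Lead time is impact time minus alarm time; summaries report
detection rate, median/mean lead and compliance at 100/150/200/250 ms.
`t_alarm` is anchored to the window's final sample — the earliest moment
the decision could exist — and no inference latency is added.

## The synthetic generator

The generator emulates the structure of public fall corpora such as
KFall: 100 Hz 6-channel trials, tens-of-seconds ADLs (walking with a
configurable gait frequency, sit-stand transitions, jumps with brief
free-fall dips as hard negatives, quiet standing), and fall trials with
an annotated onset and impact. A fall is built as quiet standing (3–6 s),
a growing-instability phase (0.5–0.9 s) whose start is the annotated
onset, and a 300–600 ms descent during which the trunk rotates toward
horizontal while the specific-force magnitude dips to 0.2–0.45 g; a
>2 g spike is placed *after* the annotated impact frame so that
pre-impact truncation provably removes it — classifiers can only exploit
pre-impact dynamics. The onset is placed at instability start (not
descent start): with a 250 ms margin, a descent-anchored onset would
leave fall phases shorter than half a window and the majority-overlap
rule could never produce a positive label.

Signals are gravity-consistent by construction: orientation trajectories
are composed with a per-subject constant wearing offset (each axis drawn
from 0–35°, random sign; the orientation-stress mode draws 15–45°), the
accelerometer reads the rotated specific force plus Gaussian noise
(sd 0.015 g), and the gyroscope is derived from the exact quaternion
increments (sd 0.4 deg/s noise) — so integrating the generated gyro
recovers the generating orientation, which is the ground-truth oracle
used to test the attitude module. All randomness flows from one seed with
per-trial substreams indexed by counter, so datasets are bit-reproducible.

What the generator does *not* emulate: biomechanically validated fall
kinematics, soft-tissue and mounting resonances, magnetometer channels,
sensor bias drift, or near-fall recoveries. Passing the end-to-end tests
therefore demonstrates that the pipeline is implemented correctly and can
recover separable classes under realistic geometry — not that the
published real-data accuracy transfers to any particular cohort.

## Study sizes and numerical choices

The synthetic study uses 8 subjects with 5 ADL + 4 fall trials each
(ADLs 10–20 s), giving roughly 2 000 ADL windows and 250 fall windows
before augmentation. The synthetic training protocol runs the full recipe
for 12 epochs — the synthetic classes are separable by construction and
converge within a few epochs, so 12 leaves a comfortable margin while
keeping the cross-validated checks quick; the 105-epoch default of
`train_config()` is the recipe intended for real recordings. Batches are
formed by even division (a trailing remainder is folded into the last
batch) so no batch-norm update ever sees a single sample. Normalization
uses $\epsilon = 10^{-5}$ and running-statistics momentum 0.1; max-pool
uses floor on odd lengths (87 → 43).

## Limitations

Heading (yaw) alignment is unobservable without a magnetometer, so
cross-subject yaw differences remain visible in the horizontal global
components. The Butterworth stage is causal, so its group delay slightly
shifts signal energy within windows relative to zero-phase offline
filtering. The synthetic ablation (four-branch versus body-frame-only)
checks a direction, not an effect size: with cleanly separable synthetic
classes both models can saturate, and the test asserts only that fusion
is never worse. Real-data claims require the external dataset; the
package ships the reader and CLI path to re-run them when it is
available.
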
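---
title: "Models and methods in rehabsense"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods in rehabsense}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rehabsense)
```

rehabsense bundles two method families for monitoring rehabilitation
patients at home: indoor localization from Bluetooth received signal
strength (RSS), and upper-body kinematics inference from three sparse
inertial measurement units (IMUs) worn on the pelvis and both forearms.
This vignette explains the models, their assumptions, the tunable
parameters, and the numerical choices made where the design was open.

## RSS propagation and the simulated scene

The channel model is log-distance path loss with log-normal shadowing.
The received power from anchor $u$ at distance $d_u$ is

$$\nu_u = P_t - PL_u(d_0) - 10\,\xi_u \log_{10}(d_u/d_0) + X_{\sigma_u},
\qquad X_{\sigma_u} \sim \mathcal{N}(0, \sigma_u^2),$$

with transmit power $P_t$ (dBm), reference path loss $PL_u(d_0)$ at
reference distance $d_0$ (1 m by convention), per-anchor path-loss
exponent $\xi_u$, and shadowing standard deviation $\sigma_u$ (dB).
Shadowing is drawn independently per time step and anchor; the temporal
correlation that recurrent classifiers exploit comes entirely from the
continuity of the target's trajectory, not from correlated noise.

The default scene (`default_anchor_scene()`) is a 50 m × 50 m indoor area
divided into ten subcentres with one anchor at the middle of each (a 5 × 2
grid). Per-anchor propagation parameters are typical of indoor Bluetooth
low energy: $P_t = 0$ dBm, $PL(d_0) = 40$ dB, and exponents spread evenly
over $[2.0, 3.5]$ so each anchor has its own channel character. Received
values are clipped to the receiver range $[-100, -50]$ dBm and mapped
affinely onto $[0, 1]$ before any classifier sees them.

A note on units: the training and test severities $\sigma_s$ are
*shadowing variances* in dB² (7.5 during training; 0–15 during testing),
so the simulator receives $\sigma = \sqrt{\sigma_s}$ as the noise
standard deviation. This convention matters: at $\sigma_s = 15$ the noise
standard deviation is 3.9 dB, a regime where in-vicinity detection is
hard but far from hopeless, whereas a 15 dB standard deviation would
swamp the 5–7 dB contrast the 15 m vicinity boundary offers and cap even
an oracle detector near chance-level recall.

## Proximity reporting

A proximity report is a binary vector over anchors: entry $u$ states
whether the target is within the vicinity radius (15 m) of anchor $u$.
Intersecting vicinities confines the target to a region of interest
without coordinates, which is the granularity at-home rehabilitation
monitoring needs.

Two classifiers are provided (`train_proximity()`):

* a plain feed-forward network (two hidden ReLU layers of width 12) that
  maps one scaled RSS vector to the ten vicinity outputs, and
* an LSTM (hidden width 16) that consumes a sliding window of
  `t_lstm = 10` consecutive RSS vectors and classifies from its final
  hidden state, letting it average shadowing noise along the trajectory.

Both minimize per-anchor binary cross entropy — summed over the ten
outputs and averaged over samples — by stochastic gradient descent with
learning rate 0.01, 400 epochs, and minibatch size 500. The training data
are one simulated walk of 500 s sampled at the 10 Hz beacon rate (5000
samples). The hidden widths and `t_lstm` are deliberate defaults, not
sacred: they are the smallest widths that train reliably under this
protocol, and both are configurable. An output above
the 0.5 threshold (strictly) reports in-vicinity; a tie classifies as
out-of-vicinity.

Reported metrics (`proximity_metrics()`): *proximity accuracy* (recall on
in-vicinity instances), *distance accuracy* (recall on out-of-vicinity
instances), and *overall accuracy*, which is exactly the label-weighted
combination of the other two.

The region-of-interest variant (`train_roi_classifier()`) averages RSS
over 0.5 s windows and trains a three-layer LSTM with a K-way softmax to
name the region directly.

## Fingerprint k-NN positioning

When coordinates are wanted, `build_codebook()` stores the time-mean RSS
vector (the *fingerprint*) and the coordinates of each reference point.
At test time the per-anchor RSS is averaged into 0.25 s bins (4 Hz), a
silent anchor is filled with $\nu_{\min} = -100$ dBm, and
`closest_fingerprints()` ranks codebook entries by the Euclidean norm
$\lVert F - G\rVert$; `position_estimate()` returns the centroid of the
$W = 3$ nearest reference coordinates. Ties in the ranking break by
codebook insertion order, which makes the estimator fully deterministic.
Codebook fingerprints are clipped to the receiver range like all other
features.

## Rotation algebra

Orientations are unit quaternions, scalar-first $(w, x, y, z)$. Because
$q$ and $-q$ encode the same rotation, every angle in the package is
computed sign-invariantly:

$$\theta(a, b) = \frac{360}{\pi}\,
\arccos\!\big(\mathrm{clamp}(\lvert\langle a, b\rangle\rvert, 0, 1)\big)
\in [0, 180].$$

(A tempting shortcut — reporting the scaled inner product itself without
the arccos — is not an angle at all: it would assign 114.59° to identical
orientations. The standard relative-rotation angle is used throughout.)
Averages of rotations (`quat_average()`) use the eigenvector method: the
mean is the principal eigenvector of $\sum_i w_i q_i q_i^\top$, invariant
to sign flips of any input.

## Skeleton, normalization and forward kinematics

The upper body is a 15-segment tree rooted at the pelvis: the spine chain
(Pelvis, L5, L3, T12, T8, Neck, Head) plus shoulder–arm chains. Each
non-root segment carries a fixed offset vector in its local frame; the
bundled neutral skeleton uses plausible metre-scale lengths (straight
spine, arms down, right-handed Z-up global frame) and is overridable via
JSON for subject-specific lengths.

`normalize_orientations()` re-expresses every segment relative to the
pelvis, $R_{PB_i} = R_{GP}^{-1} R_{GB_i}$, removing global heading;
accelerations are vectors, so they are rotated by the same
$R_{GP}^{-1}$ — the normalization convention sparse-IMU pipelines share.
`forward_kinematics()` chains
$P_i = P_{\mathrm{parent}(i)} + R_{GB_i} X_i$ down the tree; whether
gravity is present in the acceleration channels is a property of the data
source, which the synthetic generator makes explicit with a flag.

## Sensor-to-segment calibration

A standalone IMU taped over a motion-capture sensor reports orientations
in its own frame. Per session, the *variable mapping* is a single
rotation pair computed at one calibration frame $n$:
$R^{(\mathrm{Ori})} = R^{\mathrm{MVN(seg)}}_n (R^{\mathrm{DOT(raw)}}_n)^{-1}$
for orientations, and the analogous product with the motion-capture
*sensor* orientation for accelerations. Applying the map left-multiplies
the raw stream; when the offset between the two systems is a truly fixed
rotation this reproduces the motion-capture stream exactly at every
frame, and the map is independent of $n$ — both properties are enforced
to 1e-6 degrees in the tests. The default $n$ is the quasi-static frame
(smallest IMU acceleration magnitude) rather than a random one: it costs
nothing in the fixed-offset regime and reduces sensitivity to dynamics
when the offset is imperfect. The cross-session *fixed mapping* is the
quaternion average of the per-session maps. Lever-arm (translational)
effects between sensor sites are not corrected.

Synchronization decimates both streams to a common rate (40 Hz default)
and picks the integer offset maximizing the cross-correlation of mean
acceleration magnitude — an automated, testable stand-in for manual
bump alignment. Lags leaving less than half-overlap are excluded;
dynamics-free streams fall back to offset 0 with a warning. Exactness
caveat: 40 does not divide 60, so nearest-frame decimation of a 60 Hz
stream onto a 40 Hz grid lands half the frames 1/120 s off. Tests that
require bit-exact closure therefore synchronize at 20 Hz, which divides
both source rates; at 40 Hz the residual is bounded by (angular speed) ×
1/120 s.

## Motion inference models

The inference task is sequence-to-sequence: five frames at 40 Hz (0.125 s)
of pelvis-normalized orientation and sensor acceleration for the three
instrumented segments (21 channels per frame) predict the normalized
orientations of all 15 segments over the same five frames (60 channels
per frame). Raw 240 Hz sequences are cut into non-overlapping 30-frame
windows (stride 30) and decimated by a factor of 6, which is exactly the
five-frame 40 Hz snippet stated above. Inputs are standardized per flattened feature column with statistics
fitted on the training windows only and frozen thereafter; a
zero-variance column (e.g. the identically-identity pelvis quaternion
after normalization) has its deviation clamped to 1 with a warning.
Targets stay raw quaternion components, because the training loss is the
mean absolute error over those components,
$\mathrm{MAE} = \frac{1}{mn}\sum_j\sum_i \lvert \hat q_i - q_i\rvert$
(averaged over all frames, segments and the four components), and the
overfit-capacity thresholds are on that natural scale.

Four architectures share the window interface and are drop-in
interchangeable:

| architecture | shape |
|---|---|
| `seq2seq` | LSTM encoder → LSTM decoder, hidden 512, autoregressive decoder fed its previous output |
| `seq2seq_attn` | bidirectional LSTM encoder (512 per direction) + additive attention over encoder states |
| `transformer_enc` | 2 pre-norm encoder layers, 21 heads, feed-forward 200, width 84 |
| `transformer_full` | 4-layer encoder + 4-layer decoder with causal self-attention and cross-attention, 4 heads, feed-forward 2048, width 64 |

Transformer widths are the smallest multiple of the head count not below
64 (21 heads ⇒ 84; 4 heads ⇒ 64), so the 21-head configuration is honored
literally. Optimization is AdamW at learning rate 0.001; the transformers
use momentum parameters $\beta_1 = 0.95$, $\beta_2 = 0.99$. Dropout 0.1
is applied during training only. Positional encoding is the standard
sinusoid. Predicted 4-vectors are renormalized to unit quaternions after
the linear head; the loss sees the raw vectors.

Two initialization choices speed small-data convergence and are worth
knowing about: the output bias of every architecture starts at the
training-mean target (so the initial prediction is the average pose), and
transformer residual branches start at zero (skip-style initialization),
making each block an identity map at step 0. Neither changes the model
class; both only move the starting point.

Training is bit-reproducible for a fixed seed on one machine:
initialization, batch order and dropout masks all derive from the single
seed argument.

## Synthetic motion streams

`generate_pose_sequence()` draws, per segment, a band-limited random walk
on rotations: white angular-velocity noise low-passed at 1 Hz and scaled
so the per-frame angular speed never exceeds the configured bound
(default 90 deg/s). Accelerations are the second time-derivative of the
forward-kinematics endpoint positions, plus gravity if requested. This is
deliberately *not* biomechanics: joint limits, ground contact and the
statistics of daily activity are absent. Passing tests therefore
demonstrate that the pipeline — windowing, training, calibration,
evaluation — is correct and has the capacity to fit smooth articulated
motion; they say nothing about absolute accuracy on real recordings.

`emulate_dot_stream()` degrades the truth into a standalone-IMU stream:
decimation to 60 Hz, a per-segment mounting rotation composed on the
left, slow constant-rate drift about a fixed axis, and Gaussian
orientation/acceleration noise. With zero drift and noise the composed
offset is a fixed rotation, which is precisely the regime in which the
variable mapping achieves exact recovery — closing the loop between the
generator and the calibration module.

## Evaluation

`mean_angular_error()` averages the relative-rotation angle over frames
and segments (every segment sees the same number of frames, so the mean
of per-segment means equals the mean over all pairs). `joint_angle()`
takes the smallest rotation angle between the two segments spanning a
joint — elbow: upper arm vs forearm; shoulder: T8 vs upper arm, which
deliberately collapses the shoulder's three degrees of freedom into one
angle. Signed joint-angle error is *inferred minus truth*, so negative
values mean the inferred joint was more acute than the truth.
Histograms use fixed-width bins aligned to multiples of the width and
conserve the sample count.

## Problem sizes used in the checks

The packaged checks run at desk scale by design: proximity experiments
train on one 5000-sample walk and evaluate 1000-step test walks over ten
seeds; motion overfit-capacity runs fit 50 windows (a 6.25 s synthetic
sequence) per architecture, stopping early once the epoch MAE falls below
0.015 (comfortably under the 0.05 capacity threshold and small enough to
keep the mean angular error under 5 degrees); calibration and k-NN checks
are exact and run on seconds-long streams. Absolute accuracy on real
recordings would require real motion corpora orders of magnitude larger
and is outside what this package's checks can or do claim.

## Known limitations

* The motion generator's band-limited random walk has no pose priors; a
  model trained on it will not transfer to human motion.
* Calibration assumes a rigid, fixed sensor-to-segment offset per
  session; drift is emulated and measurable but not corrected online.
* Shadowing is i.i.d. per step; environments with spatially structured
  obstruction will decorrelate differently.
* The proximity networks are small by design; the protocol's 400-epoch
  SGD budget, not capacity, is usually the binding constraint.
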
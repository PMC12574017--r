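---
title: "Training-speed diversity for continuous EMG decoders: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Training-speed diversity for continuous EMG decoders}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

# The question

Continuous myoelectric decoders map surface EMG to continuous kinematic
positions of a prosthetic hand and wrist. Almost all of them are trained on
mimicked movements executed at a single speed. Because fast, forceful
movements produce large and distinct EMG while slow movements produce subtle,
noisier activity, a decoder calibrated at one speed need not generalize to
another. `emgdecode` implements an offline study of that question: it
simulates EMG/kinematics sessions at slow, medium and fast movement speeds,
trains a linear Kalman filter (KF) and a nonlinear convolutional LSTM
(C-LSTM) on single- and mixed-speed datasets, and quantifies cross-speed
generalization.

# The synthetic world

There is no deposited dataset, so the package generates its own, with the
statistical structure the decoding analysis assumes.

**Kinematics.** Three degrees of freedom (DOFs: grasp/open, wrist
flexion/extension, pronation/supination), each normalized to $[-1, +1]$, six
directional movements in total. A trial is a trapezoid: a constant-velocity
ramp to the endpoint over $r$ seconds, a 1-s hold, and a return ramp. The
speed presets are $r = 3$ (slow, 7 s total), $1.5$ (medium, 4 s) and $0.5$ s
(fast, 2 s). A linear ramp matches the constant-target-velocity protocol of
online target tracking; minimum-jerk ramps are available behind a
configuration flag. Rest between trials defaults to 2 s (the protocol does
not prescribe it); sessions hold 20 trials of each movement (120 trials) in
a seeded pseudorandom order.

**EMG forward model.** Each of the 32 channels is envelope-modulated white
noise plus 60-Hz line interference:
$$v_c(t) = \mathrm{env}_c(t)\,\xi(t) + a_{60}\sin(2\pi\,60\,t),\qquad
\mathrm{env}_c = \sqrt{b_c(t)^2 + \mathrm{drive}_c(t)^2}.$$
The drive combines, per movement $m$ with direction $s_m$ acting on DOF
$d_m$:

* a rectified *position* drive $[s_m x_{d_m}]_+$ (gain 0.45) — sustained
  activity while holding against the virtual spring of the task;
* a rectified *velocity* drive $[s_m \dot x_{d_m}]_+$ (gain 0.35) — the
  burst that moves the limb; peak target velocities are 1/3, 2/3 and 2
  units/s for slow/medium/fast, so fast transitions are dominated by large
  velocity bursts (the "large and distinct" premise);
* a nonspecific *co-contraction* drive proportional to $\sum_d |\dot x_d|$
  (gain 1.0, per-channel weights in $[0.5, 1.5]$), emulating the
  antagonist/stabilizer co-activation that accompanies ballistic movement.
  Its amplitude varies strongly from trial to trial
  ($1 + \mathcal N(0, 0.4)$), as co-contraction does in practice. This is
  the mechanism by which homogeneous fast training data biases a decoder
  toward unintended movements: large nuisance bursts co-occur with every
  fast movement, and a decoder fitted only to them absorbs spurious
  couplings.

Movements are mapped to channels by a block-structured mixing matrix —
about five dominant channels per movement (gains near 1) plus ~10%
cross-talk everywhere — separable but non-orthogonal, like neighbouring
forearm muscles. Each trial carries an overall effort gain
$1 + \mathcal N(0, 0.15)$; the resting envelope floor is 0.22, so the
position drive of a slow hold sits only about 2:1 above the noise floor
(the "subtle and noisy" premise) while fast transitions sit far above it.
Two further mechanisms are implemented but default off: a slow additive
drift of the envelope floor (`baseline_drift_sd`; baseline tone and
impedance wander) and a mimicked-training *tracking error*
(`tracking_error_scale`) that displaces the executed movement from the
displayed label trajectory in proportion to ramp duration. In pilot
simulations both mostly penalized whichever decoder had the higher
observation gain at test time rather than specifically degrading slow-speed
calibration, so the shipped world leaves them off and derives its
speed asymmetries from the velocity, co-contraction and noise-floor terms
above.

All randomness flows from one master seed through counter-derived per-trial
streams, so adding trials never reshuffles earlier ones.

**What the generator does not emulate.** No motor-unit action potentials
(the envelope-modulated-noise model is the contract), no electrode shift,
no fatigue, no learning effects across sessions. Passing tests therefore
show that the pipeline recovers the structure this world contains — speed-
dependent amplitude, co-contraction nuisance, cross-talk — not that it
would reproduce numeric error levels of any real recording.

# Preprocessing

Causal (forward-only) filtering, matching what an online decoder sees: a
sixth-order 15-Hz high-pass Butterworth, a second-order 375-Hz low-pass,
and biquad notches at 60/120/180 Hz with quality factor 30 (the quality
factor is not prescribed; 30 is a conventional mains-notch choice).
Filter design comes from `signal::butter` plus the standard biquad notch
formula; the difference equations run in a small C++ kernel.

Differential recordings are formed for all 496 unordered channel pairs, and
the mean absolute value (MAV) of the 32 single-ended plus 496 differential
signals is computed over a trailing 300-ms window updated at 30 Hz,
giving the 528-feature series. Conventions fixed here: frame $k$ has
timestamp $k/30$ s; a full window holds $\lfloor 0.3 f_s \rfloor$ samples
(1000/30 is not an integer, so windows are defined in seconds to avoid
drift); initial partial windows use the samples available, preserving
alignment with the kinematics from $t = 0$; features are ordered
single-ended 1..32 first, then pairs $(i, j), i<j$, lexicographically, so
fitted models are portable. The overlapping window itself is the "smoothing"
of the smoothed-MAV feature; no second smoothing stage is applied.

# The decoders

**Kalman filter.** States are the three DOF positions (velocity-augmented
states are a configuration option, not the default — the decoded quantity
and all metrics are positions). The state model $x_t = A x_{t-1} + w$,
$w \sim \mathcal N(0, W)$ is fitted by least squares over within-trial
transitions; the observation model $z_t = H x_t + q$,
$q \sim \mathcal N(0, Q)$ by ridge regression of centered features on
centered kinematics ($\lambda = 10^{-3}\,\mathrm{tr}(X^\top X)/d$ by
default — with $p = 528$ features and sessions of a few thousand frames a
plain least-squares observation fit is ill-conditioned). The stored offset
$\bar z - H \bar x$ absorbs the nonzero resting MAV floor that would
otherwise bias predictions at rest. Decoding runs the standard
predict/update recursion from $x_0 = 0$, $P_0 = W$; internally the update
uses the algebraically identical information form with $Q^{-1}$
precomputed through a jittered Cholesky factor (relative jitter $10^{-8}$),
so each frame costs $O(pd)$ instead of $O(p^3)$. A steady-state-gain fast
path is available and asserted equivalent to the full iteration. The test
suite checks the whole filter against an independent brute-force Gaussian
conditioning oracle to $10^{-8}$.

The *modified* KF used online adds one post-processing step, implemented as
`apply_mkf_threshold()`: per DOF, predictions with $|x| \le 0.2$ (20% of
the 0-to-1 span of each direction) are zeroed and the remainder rescaled to
span the full range, $\mathrm{sign}(x)(|x|-0.2)/0.8$ — continuous, odd,
monotone, fixing $\pm 1$. No gain modifications are applied. Offline
analyses use the plain KF; offline metrics score the raw (unclamped)
decoder output, since the virtual hand's joint limits act only online.

**C-LSTM.** Sliding windows of 10 feature frames (333 ms) are labelled with
the final frame's kinematics (causal decoding). Architecture: 10
convolutional filters of length 32 along the 528-feature axis (the kernel
is read as (feature, time) = (32, 1); whether it should instead span a
reshaped electrode axis is ambiguous, and the feature-axis reading is the
default), batch normalization, ReLU; one further convolution (10 filters,
kernel 16, stride 4) for stride-based dimensionality reduction, batch
normalization, ReLU; one LSTM layer with 40 hidden units over the window's
time axis; one fully connected layer of 64 ReLU units; a linear 3-DOF
output. The pieces the protocol leaves open (number of extra convolutions,
strides, FC sizes, batch size 64) are fixed in the shipped configuration
and config-exposed. Training is SGD with momentum 0.9, initial learning
rate 2e-4, up to 1000 epochs, early stopping with patience 5 on a
validation set; parameter initialization and batch shuffling are seeded, so
training is bit-reproducible. No NN framework is involved: forward and
backward passes are written in RcppArmadillo, and the analytic gradients
are verified against numerical differentiation in the test suite.

# Metrics

* **Intended movement RMSE** — error on the trial's active DOF, pooled over
  trials, in normalized kinematic units (a constant offset of 0.1 gives
  RMSE 0.1).
* **Unintended movement RMSE** — the same, pooled over the resting DOFs
  (whose targets are identically zero): cross-talk leakage.
* **Dead-band (15%-window) RMSE** — per-sample error is the hinge distance
  outside a ±15%-of-full-range window, so a DOF anywhere inside the window
  scores zero, matching the online target-tracking feedback. Whether error
  outside the window should be the hinge distance or the full deviation is
  not derivable from the protocol; the hinge is the default and the full
  deviation sits behind a flag. "Full kinematic range" is read as the
  $[-1, 1]$ span (range 2) for this window, and as the 0-to-1 per-direction
  span for the MKF threshold.
* **Log mean absolute jerk (LMAJ)** — natural log of the mean absolute
  third finite difference scaled by $f_s^3$, floored at $10^{-12}$ so a
  constant trace stays finite; lower is smoother. Aggregation is the
  median across testing conditions (all other metrics aggregate by mean).
* **SnPM permutation t-map** — trials are time-normalized to a common
  phase axis by linear interpolation; a paired t statistic is computed at
  every phase point between predicted and target traces; family-wise error
  over time is controlled by the permutation distribution of
  $\max_t |t|$ under sign flips of whole trials (exhaustive when
  $2^n$ fits the budget, Monte-Carlo otherwise). Pairing is at the trial
  level; no cluster-forming threshold is used — the max-statistic
  correction is the simplest exact control consistent with a two-tailed
  test. Zero-variance time points yield $t = 0$ with a warning.

# The offline experiment

Seven training conditions — slow, medium, fast, S+M, S+F, M+F, All — each
train on 12 trials per movement, drawn equally from the contributing speeds
(12, 6+6, 4+4+4), so conditions differ in composition, not quantity. With
two algorithms that is 14 decoders, each evaluated on held-out trials of
all three test speeds: 42 outcome cells per participant. Validation uses
six folds; the protocol says trials "were shuffled so the testing and
training data varied per fold" without specifying disjoint partitions (20
is not divisible by 6), so the default draws an independent seeded 12/8
split per fold (repeated random subsampling) and a rotating
nearly-disjoint partition mode is available. For the C-LSTM, 2 of the 12
training trials per movement are flagged validation, rotated across
movements and speeds so no speed is systematically held out of training in
mixed conditions. Synthetic "participants" are independent master seeds
with multiplicative jitter (sd 0.15) of the common mixing matrix; the
default cohort is 8. Group statistics follow the protocol: Anderson-Darling
normality screening (case 3, small-sample corrected), one-way ANOVA per
algorithm per metric with training condition as the factor, and pooled
two-sample t tests with Dunn-Šidák correction
($\alpha' = 1-(1-\alpha)^{1/m}$) when the ANOVA is significant.

# Numerical choices and degenerate inputs

Frame boundaries computed as $\lfloor k f_s / 30 + 10^{-9}\rfloor$ (the
epsilon guards against floating floor at exact boundaries); nearest-frame
alignment prefers the earlier frame on half-frame ties; $P$ symmetrized
every filter step; innovation inverses via Cholesky with $10^{-8}$ relative
jitter, with an error suggesting more ridge when $Q$ is singular;
zero-variance DOFs rejected by name in `fit_kalman`; constant samples
rejected by the Anderson-Darling wrapper; all-equal groups flagged
(`zero_within`) rather than reported as an infinite F.

# Problem sizes used by the tests

The shipped tests and the acceptance script run a scaled-down study chosen
to exercise every stage: 2 synthetic participants, 6 trials per movement,
one 4-train/2-test split with 1 validation trial, the slow / fast /
all-speed conditions (training totals of 3 per movement: 3, and 1+1+1),
and a lighter C-LSTM schedule (feature-axis stride 8 in the first
convolution, training windows every 4th frame, learning rate 0.01, 12
epochs) so a network is actually trained rather than left near its
initialization at this data size. The qualitative training-speed effects —
slow-trained KF losing intended accuracy relative to all-speed training,
fast-trained decoders leading on unintended movement — are asserted as
directions over 5 master seeds, not as magnitudes. The full design (8
participants, 20 trials/movement, 7 conditions, 6 folds, the 2e-4/1000-
epoch C-LSTM schedule) is available through `run_pipeline(default_config())`
and `analysis/02_offline_grid.R` with `FULL_SCALE <- TRUE`.

# Known limitations

* The envelope-modulated-noise EMG model has no motor-unit structure; MAV
  is the only feature it is designed to support.
* The co-contraction and tracking-error mechanisms are first-order
  caricatures of ballistic co-activation and mimicked-training label error;
  they reproduce directions, not effect sizes.
* The online tasks (target tracking, block catching) are out of scope:
  only their metric definitions (dead-band RMSE, LMAJ, SnPM) are
  implemented and applied to offline predictions.
* With two synthetic participants the group statistics are illustrative;
  the statistical machinery is exercised properly only at full scale.
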
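---
title: "Latent task dynamics with over-parameterized linear-Gaussian state-space models"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Latent task dynamics with over-parameterized linear-Gaussian state-space models}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(taskdyn)
```

## The model

`taskdyn` studies how neural populations — artificial or biological —
reconfigure between tasks, by summarizing epoched multi-trial recordings with
a linear-Gaussian state-space model (SSM):

$$
x_t = A x_{t-1} + B u_{t-1} + w_t, \qquad w_t \sim \mathcal N(0, W)
$$
$$
x_1 = B_0 u_0 + w_1, \qquad w_1 \sim \mathcal N(0, W_1)
$$
$$
y_t = C x_t + v_t, \qquad v_t \sim \mathcal N(0, V)
$$

Latent factors $x$ evolve through recurrent dynamics ($A$), known
condition-coded inputs ($B u$), and process noise; observations $y$ (hidden
units of a simulated network, or principal components of sensor recordings)
are a noisy linear read-out. Two modeling choices matter:

* **Over-parameterization.** The number of factors may *exceed* the number of
  observed dimensions. This "lifting" lets a linear model imitate a nonlinear
  system, and in practice the best cross-validated fits sit beyond the
  observed dimensionality. The package treats this regime as first-class:
  covariance updates are symmetrized, log-determinants are computed from
  Cholesky factors, jitter ($10^{-10}\cdot\bar d$) is added only on a failed
  factorization (with a message), and M-step covariances have their
  eigenvalues floored at $10^{-12}$ of their trace.
* **Inputs, not stimuli.** The time-varying inputs are condition labels
  (bias, current task, previous task, switch/repeat, optionally cue identity
  and reaction times), each expanded over a clamped cubic B-spline basis in
  time, so the model learns a flexible time course per condition. The
  previous trial's task also enters the *initial condition* through $B_0$,
  which is what lets the model express carry-over from the preceding trial.

## Estimation

Parameters are estimated by MAP expectation-maximization. The E-step runs
the Kalman filter and Rauch–Tung–Striebel smoother; because posterior
covariances do not depend on the observed values, one covariance recursion is
shared across all trials and only the means are per-trial, which makes the
E-step cheap even for hundreds of trials. The smoothed moments are collapsed
into nine sufficient statistics (windowed second moments, the lag-one
cross-moment, input/state, input/input and observation moments), and the
M-step solves ridge-regularized least-squares problems in those moments for
$[A, B]$, $C$ and $B_0$, with closed-form residual updates for $W$, $V$,
$W_1$.

Matrix-normal ridge priors with precision $\Lambda = 10^{-6} I$ are placed on
$A$, $B$, $B_0$, $C$ (the package default, adjustable through
`prior_spec()`). The covariance updates are normalized by
$N(T{-}1) - D_x$, $NT - D_y$ and $N - D_x$; these normalizers are exact
stationary points of the log-posterior only under a specific reference
measure on $W$, $V$, $W_1$, and the package *defines* its training objective
(`kalman_filter()` log-likelihood plus `log_prior()`) with exactly those
terms. The payoff is that EM monotonicity is a theorem rather than an
approximation, and the fit trace asserts it at every checkpoint: a decrease
beyond $10^{-6}$ relative tolerance aborts the fit with the trace attached.

Fitting terminates when the training objective or the held-out log-likelihood
stops improving between checkpoints (the held-out criterion is evaluated
every `check_every` iterations, and the returned parameters are the best
held-out checkpoint), or at `max_iter`. "Stops improving" is implemented as a
checkpoint-to-checkpoint improvement $\le 0$, which matches the protocol's
intent without introducing a tolerance the protocol does not specify.

### Initialization by subspace identification

EM on over-parameterized models depends heavily on the starting point.
`ssid_initialize()` concatenates the epochs into one long series, zeroes
inputs outside the first few timesteps of each epoch (reducing collinearity
between lagged inputs), builds past/future block-Hankel matrices, and runs
canonical variate analysis: whiten the (future-input-conditioned) past and
future blocks, take the SVD of their cross-covariance, and read $A$ and $C$
off the extended observability matrix (first block row; shift invariance).
The remaining parameters come from innovations-style regressions of the CVA
state sequence. Because CVA orders latent directions by singular value,
initializations for smaller models are truncations of the largest one — the
package exploits this when sweeping latent dimensionality. Singular values
below $10^{-10}$ of the largest are dropped with a warning, and an unstable
initialized $A$ is shrunk to spectral radius 0.999 so the filter is runnable.

A deliberate estimator choice: early versions recovered $A$ by regressing the
CVA state at $t{+}1$ on the state at $t$; the state-estimation error is
serially correlated with the regression residual, which biases the dynamics
(we observed eigenvalue bias that did not vanish with series length). The
shipped implementation uses the observability-matrix shift-invariance
estimate, which is consistent and recovers the spectrum of a noise-free
driven system to three decimals on a few thousand samples.

## The design pipeline

`pca_reduce()` estimates principal components on training trials only (the
default threshold keeps 99% of variance) and projects held-out trials onto
the training basis. `spline_inputs()` z-scores each predictor across trials
(reaction times after a log transform), expands it over `n_basis` clamped
cubic B-splines (a partition of unity), and scales each predictor-by-basis
column to unit variance over the trial-by-time design. Two details worth
stating: a per-timestep z-scoring of expanded columns would destroy the
spline's temporal profile (the column is `value × basis(t)`, so its
per-timestep variance across trials is proportional to `basis(t)²`), which is
why standardization is applied to the predictor values and the overall column
scale instead — the per-timestep *mean* across trials is still exactly zero
for every non-bias column, and that half of the contract is tested. Second,
the time-varying bias is constant across trials and therefore cannot be
z-scored; it is left unscaled. `split_blocks()` assigns whole experimental
blocks to the test set, so train and test are temporally separated.

## Dynamic signatures

All signatures are computed from a fitted model after
`normalize_system()`, which applies the diagonal similarity transform
$T = \mathrm{diag}(\sqrt{\mathrm{diag}(W)})$ so every factor has unit
process-noise variance. (Scaling by $\mathrm{diag}(W)$ itself would not
produce unit variance; the square root does, and the likelihood is invariant
either way — only the latent units of downstream distances change.)

* **Additive state decomposition** (`decompose()`): linearity makes the
  deterministic trajectory an exact sum of per-input subsystems. The task
  subsystem drives only the current- and previous-task input columns — with
  opposite signs on switch trials (their difference) and equal signs on
  repeat trials (their sum) — and starts from the previous-task component of
  $B_0$. The spline-expanded bias is deliberately *not* part of the task
  subsystem. With contrast-coded tasks ($\pm 1$) the two tasks' trajectories
  are exact mirror images through the origin.
* **Switch similarity** (`switch_similarity()`): the cross-lagged cosine
  between switch- and repeat-subsystem states, a temporal-generalization-style
  $T \times T$ map. Zero-norm states yield `NA`, never 0. Cosines are
  computed on normalized latent states.
* **Initial centrality** (`midpoint_score()`): the signed relative Euclidean
  distance of the trial's initial state to the two tasks' states,
  $\delta_t \in [-1, 1]$; $0$ means the initial state is equidistant — a
  "neutral" starting point; $-1$ means it sits on the task's own state.
  `iti_convergence()` complements it with the log-distance between
  trial-averaged post-task states across the inter-trial interval, whose
  slope is the exponential convergence rate.
* **Task energy** (`task_energy()`): the recursive-Lyapunov task Gramian
  $G_t = A G_{t-1} A^\top + (B u^{task}_{t-1})(B u^{task}_{t-1})^\top$ from
  $G_1 = 0$, summarized as the average controllability $\log \mathrm{tr}(G_t)$.
  Where the trace is zero (the first sample, or zero inputs) the log is
  reported as `NA` and excluded from contrasts rather than epsilon-padded.
  `asymptotic_gramian()` solves the corresponding discrete Lyapunov equation
  by doubling iteration for the white-noise limit.

All of these are isometry-invariant in the normalized latent space, and the
test suite checks invariance under random orthogonal transforms.

## Model comparison and group inference

`generalized_r2()` implements the likelihood-ratio (Cox-Snell) generalized
$R^2$, which coincides with the classical $R^2$ for iid-Gaussian linear
models and extends to the filter's anisotropic, time-varying predictive
covariance. `null_models()` fits the four sensor-level references (intercept,
spline encoding, first-order vector autoregression, and their combination —
the last being the benchmark) with diagonal Gaussian residuals.
`protected_exceedance()` implements variational random-effects model
selection over per-subject evidences: a Dirichlet posterior over model
frequencies, Monte-Carlo exceedance probabilities, and the Bayes omnibus risk
blending toward chance (so identical models report exactly $1/K$ each).
`tfce_correct()` implements threshold-free cluster enhancement
($H = 2$, extent exponent $1$, integration step $\max|s|/100$; 2-neighbor
adjacency for traces, 4-connectivity for cross-lag maps) with sign-flip
permutation of the subject maps and max-statistic correction.
`crossmodal_similarity()` bootstraps the congruence coefficient (cosine of
vectorized signatures) or the $R^2$-similarity
$1 - \sum(x-y)^2 / \sqrt{\sum(\bar x - x)^2 \sum(\bar y - y)^2}$ between two
groups; the printed form of that denominator is ambiguous between a product
and its square root, and the square root is used so the denominator keeps the
units of a sum of squares. The difference variant compares two model groups
against shared bootstrap draws of the reference group, which absorbs the
reference group's sampling variability.

`parameter_recovery()` addresses the fact that latent coordinates are only
identified up to an invertible transform: a diagonal normalization alone
cannot resolve rotations, so the estimated system is aligned by regressing
the generating latents on the estimated smoothed latents before correlating
parameters (covariances through the lower triangle of their Cholesky
factors). A similarity-transformed copy of a system recovers correlation 1
exactly, which the tests assert.

## The synthetic generators

Two generators make every pipeline stage testable without external data.

**Planted state-space models** (`sample_ground_truth()`): a stable system
(default spectral radius 0.9) with slow, smoothly rotating dynamics — a
strong identity component plus a random perturbation, the regime typical of
population recordings — wired to the default two-task design. Task input
columns are tied across spline bases (scaled by the design's column scales),
so the effective task drive is constant over the epoch and each task has a
well-defined target state. `init_mode = "midpoint"` zeroes the previous-task
column of $B_0$, planting trials exactly between the two task states
(ground-truth $\delta = 0$); `init_mode = "task"` plants the initial
condition on the task subsystem's fixed point $(I - A)^{-1} g$, so trials
start exactly on the previous task's state ($\delta = -1$ at every
timestep).

**The task-switching simulator** (`curriculum_spec()`,
`train_curriculum()`): gated-recurrent-unit networks trained on
context-dependent decision making. Each trial is a one-hot cue (10 steps), a
delay (20), and two pairs of stimulus inputs (40); the network reports which
input of the cued pair is larger. Single-trial training teaches the task;
the 2-trial curriculum appends two-trial sequences (equal probability of
switch and repeat) whose preparation period for the second trial — cue,
delay, and the first 10 stimulus steps (40 timesteps) — is the epoch exported
for state-space fitting. Gaussian input noise is resampled every epoch at
0 dB (cue) and −6.5 dB (stimulus) signal-to-noise. The forward pass, the
backpropagation-through-time gradients (verified against finite differences
in the tests), and the decoupled-weight-decay optimizer (learning rate 0.01,
weight decay 0.01) are implemented in the package. Gate ablations fix the
reset gate at 1, overwrite the state fully (`h_t = n_t`) for the open update
gate, or remove gating entirely (a ReLU vanilla network, learning rate
0.001), with hidden sizes enlarged to match the full model's parameter count
on the integer grid.

Unprinted task constants are declared config defaults: the stimulus
amplitude grid is $\{1.25, 0.25\}$ — well-separated levels keep the
cue-gating strategy learnable at the low training SNRs and desk-scale epoch
counts used here — and the fully crossed grid (2 tasks × 2 target patterns ×
2 distractor patterns per trial; 64 conditions for two-trial sequences)
balances task, target and distractor transitions in every epoch by
construction. Training uses within-epoch minibatches (64 sequences per
gradient step) because desk-scale runs take a few hundred gradient steps,
not the hundreds of thousands of sequences of a cluster-scale run.

### What the generators do and do not emulate

The simulator reproduces the task structure, curricula, noise levels and
gating architecture, at reduced width (32 hidden units), epoch counts
(tens, in equal single-trial/two-trial phases for switch-trained networks)
and population sizes (a handful of seeds rather than hundreds of networks
per curriculum). Distributional effect sizes from large network populations
are therefore out of reach; what does reproduce robustly at this scale is
the *direction* of the headline effects — switch-trained networks vastly
outperform single-trial networks on second-trial switches, and networks
trained with shorter inter-trial intervals retain worse switch performance
on average. The planted SSMs generate data from the model class itself
(plus a tanh variant for the over-parameterization experiment), so passing
recovery tests demonstrates correctness of the estimation machinery, not
that any particular real dataset is well described by a linear model.

## Validation experiment sizes

The test suite and the acceptance script rerun the full validation at sizes
chosen for a single CPU: 50 random systems against a dense joint-Gaussian
oracle (every system with factors × timesteps ≤ 60); parameter recovery on
an 8-factor/12-observation system with 400 trials of 40 timesteps and 3000
EM iterations; the factor-count sweep (2–10 factors, observed dimension 6)
on a tanh-modified planted system with 600 EM iterations per size; TFCE
calibration over 200 simulated null experiments at 100 permutations each;
and two to three simulator seeds per curriculum at 80 training epochs.

## Known limitations

* Missing data are rejected, not imputed; epochs must be complete and of
  equal length.
* The observation-noise covariance is estimated in full; after a PCA
  front-end it is near-diagonal, and no diagonal constraint is imposed.
* `fit_em()` is single-start; SSID initialization removes the need for
  multiple restarts in our experiments, but EM remains a local optimizer and
  converges slowly near degenerate optima.
* The exceedance computation is Monte-Carlo (default $10^5$ draws), so its
  third decimal is sampling-limited.
* The simulator trains by full backpropagation through time in plain R; it
  is intended for desk-scale validation, not cluster-scale population
  studies.
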
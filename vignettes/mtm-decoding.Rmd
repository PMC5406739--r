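---
title: "Prior-informed trajectory decoding for obstacle-avoidance reaches: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Prior-informed trajectory decoding for obstacle-avoidance reaches: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mtmdecode)
```

## The task and the decoding problem

A cursor must travel from one of four canonical positions (bottom, left,
top, right of a 20 × 20 cm workspace) to a target at another position while
steering around an obstacle placed on the straight path. Each trial runs
through five epochs in 100 ms bins: *rest* (nothing instructed), *delay 1*
(300 ms, target visible — target direction can be planned), *delay 2*
(500–800 ms, obstacle visible — the clockwise/counterclockwise avoidance
plan can be formed), *movement*, and *hold* (500 ms at the target). With a
fixed start there are 3 targets × 2 obstacle openings = 6 movement regimes;
over 4 starts, 24 conditions.

The obstacle decouples target direction from initial movement direction,
which defeats decoders that assume point-to-point reaches. The remedy
implemented here is to (i) decode the two pieces of planning information
from delay-period activity and (ii) inject them as prior knowledge into a
mixture of trajectory models during movement decoding.

## Mixture of trajectory models

Each regime $m \in \{1..M\}$ carries a linear-Gaussian state-space model of
hand position $x_t \in \mathbb{R}^2$:

$$x_t \mid x_{t-1}, m \sim \mathcal{N}(A_m x_{t-1} + b_m,\, Q_m), \qquad
  y_t \mid x_t, m \sim \mathcal{N}(H_m x_t + p_m,\, V_m),$$

with $y_t$ the $n$-unit spike-count vector. Because each regime is
linear-Gaussian, the per-regime posterior $P(x_t \mid y_{1..t}, m)$ is an
exact Gaussian computed by the standard Kalman predict/update; no further
approximation is needed for the per-regime recursion. The overall posterior
is the mixture

$$P(x_t \mid y_{1..t}) = \sum_m P(x_t \mid y_{1..t}, m)\, P(m \mid y_{1..t}),
\qquad P(m \mid y_{1..t}) \propto P(y_{1..t} \mid m)\, P(m),$$

whose mean and covariance are reported as the estimate and the source of
credible intervals. The state is position-only: velocity is deliberately
not appended, keeping each regime's dynamics a fitted random-walk-like
model of that regime's stereotyped path.

**Regime-weight update.** Two readings of the weight recursion are
plausible: weights that keep accumulating the per-regime marginal
likelihood $P(y_{1..t} \mid m)$ bin by bin (`weight_update = "likelihood"`,
the default, which follows the mixture identity above literally), and
weights frozen at the prior for the whole movement
(`"static"`, an ablation that isolates what the prior alone contributes).
Both are implemented; the evaluation module can run either. Under
likelihood updating the movement data themselves gradually identify the
regime, so prior knowledge helps most in the early bins and the measured
gaps between decoders are modest; under static weighting the prior is the
only regime information and its effect is much larger.

**Numerics.** Weights are accumulated as log-likelihood sums with
max-subtraction before exponentiation (40 units × ~15 bins would underflow
long before the end of a trial otherwise). Innovation covariances are
Cholesky-factorized; posterior and collapsed covariances are symmetrized
and eigenvalue-floored so they remain PSD under adversarial inputs. The
first movement bin is filtered directly from the initial state (the
empirical mean/covariance of movement-onset positions) without a dynamics
step.

## Fitting the regime models

State dynamics are fitted by least squares over all consecutive
movement-epoch position pairs of a regime's training trials, in
*displacement form*: $x_t - x_{t-1}$ regressed on $x_{t-1}$ through an SVD
pseudo-inverse. This convention makes the degenerate case well-defined —
for constant trajectories the minimum-norm solution is exactly $A = I$,
$b = 0$, the random walk — instead of an arbitrary member of the solution
family. $Q_m$ is the ML residual covariance, symmetrized.

The observation model is per-unit least squares of counts on position with
intercept. $V_m$ is kept **diagonal** by default: with ~40 units and a few
dozen trials per regime a full $n \times n$ covariance is ill-conditioned,
and unit independence matches the naive-Bayes assumption used for the
priors. Diagonal entries are floored at $10^{-6}$ so silent units (zero
gain, zero bias after the fit) cannot create a singular innovation. A full
covariance is available by option. Regimes need at least 5 trials
(configurable); missing regimes are reported by id rather than silently
skipped.

Regimes are keyed *within a start position* (the model-set fitter refuses
mixed-start trial lists). Pooling translated trajectories across starts
would be possible but conflates distances and obstacle placements; per-start
keying keeps each trajectory model within its regime of validity, which is
the point of the mixture.

## Delay-period priors

Features are **window-mean rates**, one number per unit: the target window
averages the 5 rest bins, 3 delay-1 bins and the first delay-2 bin (9 bins,
0–900 ms — the extra bin absorbs the causal response latency), and the
selection window averages delay-2 bins 2–5 (100–500 ms after obstacle
onset). Class-conditional parameters are ML means and variances
(variance floor $10^{-4}$); classification is log-domain naive Bayes with a
uniform class prior, matching the balanced task design. Chance levels are
1/3 (three targets) and 1/2 (two openings) by construction.

The two posteriors combine under independence,
$P(m \mid y) = P(m_1 \mid y_1) P(m_2 \mid y_2)$, over the 6 regimes. The
target-only decoder spreads each target's mass equally over its two
openings. Leave-one-out evaluation reports the *expectation of selecting
the right class* — the mean posterior on the true class — as the primary
statistic, with hard accuracy alongside, since the two readings of
"expectation of prediction" differ; both are computed. A two-sided
one-sample t-test against chance accompanies the expectations.

Optimizing window placement or richer count models (e.g. Poisson) is out of
scope; the windows are fixed by the task timeline.

## Synthetic sessions: what is emulated, and what is not

No public recordings exist for this task, so the generator produces
sessions with the statistical structure the analyses assume, sized like the
real ones (defaults: 40 units, ~300 trials; the decoding benchmark uses
`benchmark_config()`: 240 balanced trials, 40 units, one start, seed 0).

* **Geometry.** Positions at ±6 cm on the axes of a workspace centred at
  (0,0); a square obstacle (half-width 1.2 cm) centred on the straight
  start–target segment, so the direct path always collides. Trajectories
  are quadratic Bézier curves constrained through an avoidance via-point
  3.5 cm to the side of the obstacle centre, traversed with a minimum-jerk
  speed profile, plus Gaussian positional noise. Zero-noise paths clear the
  obstacle by construction (verified against the collision checker).
* **Timeline.** 5 rest bins, 3 delay-1 bins, delay-2 drawn uniformly from
  {5,6,7,8} bins — the 100 ms-resolution rendering of a 500–800 ms uniform
  delay — movement 10–15 bins (the movement-duration statistics are not
  constrained by the task description; 1–1.5 s is a typical reach at this
  scale and is exposed in the config), 5 hold bins. Epoch indices are
  stored as 1-based bin vectors, the idiomatic R representation.
* **Counts.** Rates are `baseline + H x + G v + planning modulation`, with
  per-unit position gains `H` and velocity gains `G` (random directions,
  magnitudes in physiological ranges relative to 0.5–3 spikes/bin
  baselines). During the delays the cursor is still and planning modulation
  stands in for movement: delay-1/2 rates add `G · (v_plan d_target)` — the
  unit's response to a virtual reach at `plan_speed` (20 cm/s) toward the
  target — and delay-2 adds a per-unit selection term `sel_gain · s_i · o`
  (`o = ±1` for the two openings). Counts are Gaussian around these rates
  (SD 1 spike/bin), rounded and clipped at zero; `round_counts = FALSE`
  gives the continuous model exactly, which parameter-recovery tests use
  because clipping truncates the Gaussian and shifts small means upward.
* **Why a velocity term.** A purely position-tuned population carries no
  *pooled* velocity signal: position and velocity are uncorrelated both
  along a symmetric reach (the position profile is antisymmetric about the
  midpoint where the speed profile is symmetric) and across the symmetric
  condition catalogue. Velocity-based population vectors fitted on such
  data would be noise, and the delay-period PV analysis below would be
  meaningless. Real premotor populations are velocity-tuned, so the
  generator includes the `G v` term; the trajectory decoder still uses the
  position-only observation model and simply absorbs the velocity
  contribution into its fitted noise, which keeps the decoding problem
  honest (the decoder's model is not the generator's model).
* **Not emulated.** Inter-trial chaining of start positions (the next
  trial's start equalling the previous target), discarded/failed trials,
  eye movements, non-stationarities across a session, electrode-level
  signals, and correlated noise across units. Passing tests on these
  sessions therefore show the pipeline's *correctness under its own
  assumptions* and qualitative behaviours (priors help; delay PVs point at
  the target), not performance on real recordings — on monkey data the
  class overlap is much larger and the prior expectations correspondingly
  lower.

## Population-level encoding analyses

**Population vectors.** Velocity tuning is fitted on movement epochs
(counts on first-difference velocities, with intercept); coefficient
vectors are kept *unnormalized* so strongly tuned units weigh more. The PV
of a bin is $\sum_i (r_i - \bar{r}_i^{rest}) c_i$, the tuning vectors
weighted by deviation from each unit's rest-epoch baseline; the exact
weighting is a package choice (baseline subtraction makes rest-epoch PVs
hover near zero, as observed in the recordings this task comes from).
`pv_evolution()` sums PVs across ~20 same-condition trials over the 5 rest
+ 3 delay-1 + 1 delay-2 bins.

**PCA.** Delay-2 activity is projected by mean-centred PCA; samples are
individual 100 ms bins from the selection window, not trial averages, so
the projection shows within-trial pattern stability. The test suite
quantifies the clockwise/counterclockwise cluster separation with a
silhouette score rather than by eye.

## Evaluation conventions

* CC is per-coordinate Pearson correlation, averaged over x and y;
  zero-variance true coordinates are excluded with a warning.
* MSE is the mean squared Euclidean error per bin on coordinates
  normalized to the unit square by the workspace extent (raw-cm scoring by
  option). It therefore scales quadratically with coordinate scale while
  CC is affine-invariant.
* Success means the decoded mean path never intersects the obstacle
  rectangle (segment-wise Liang–Barsky test, validated against dense point
  sampling) *and* ends within the 1.5 cm target radius. No hold-duration
  requirement is imposed on decoded paths — the behavioural hold is a
  motor-control demand, not a decoding one.
* The three decoder conditions (uniform prior / expanded target posterior /
  combined posterior) are compared leave-one-out: for each trial, regime
  models *and* prior models are refitted without it. Percentage changes
  follow the ascending-rate convention for CC and success
  ((new − old)/old × 100) and the descending rate for MSE
  ((old − new)/old × 100). Paired two-sided t-tests compare conditions on
  per-trial scores.

## Problem sizes and runtime choices

The shipped tests and the acceptance script use sizes at which every check
runs in seconds to a couple of minutes on one CPU: the decoding benchmark
is one 240-trial, 40-unit session (a full LOOCV three-decoder comparison
takes ~15 s thanks to the single-regime refit trick: leaving one trial out
only changes the model of its own regime); oracle comparisons use 1–2D toy
models; parameter-recovery simulations use 200–480 trials. Grid-integration
oracles discretize a 1D state on 3001 points over ±15, ample for 3-bin
recursions whose posteriors have SD ~1.

## Known limitations

* Per-regime dynamics are fitted contractions toward a regime's mean path;
  they extrapolate poorly outside the movement epoch and are not intended
  for free-form cursor control.
* The combined prior inherits the independence assumption; correlated
  target/selection coding would call for a joint 6-class decoder (the
  machinery supports it via `fit_prior_model()` with custom labels).
* Decoding is causal filtering only; no smoothing, no online recalibration.
* The success criterion scores the posterior mean path; probabilistic
  success (e.g. fraction of posterior mass clearing the obstacle) is not
  implemented.
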
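---
title: "Temporal coding in interval-timing recurrent networks: models, indices, and design choices"
author: "tempocode"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Temporal coding in interval-timing recurrent networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tempocode)
```

## The scientific problem

When the brain times two different intervals, the underlying population
dynamics can relate to each other in qualitatively different ways. Three
idealized schemes span the possibilities:

* **temporal scaling** — the same trajectory traversed at different speeds;
* **absolute timing** — early activity identical across intervals, with
  longer intervals recruiting additional later-active units;
* **stimulus-specific coding** — unrelated trajectories for each interval.

`tempocode` studies how task structure selects among these schemes in
trained excitatory/inhibitory firing-rate recurrent networks, and provides
the quantitative indices that separate the schemes in any units-by-time
rate data (model or experimental PSTHs).

## The network model

Each of the N = 200 units (80% excitatory, 20% inhibitory) obeys

$$\tau \dot{x} = -x + W^{rec} r + W^{in} I + \eta, \qquad
  r = \min(\ln(1 + e^{x}),\, 20), \qquad o = W^{out} r,$$

with time constant $\tau$ = 100 ms and a Softplus rate bounded at 20.
Dale's law is enforced by a reparameterization: the stored recurrent
matrix holds raw weights that are rectified at zero in the forward pass
and multiplied by a per-column sign (+1 excitatory, -1 inhibitory); the
diagonal is held at zero (no self-connections). The Euler update at step
$\Delta t$ is

$$x_{t+1} = (1 - \alpha) x_t + \alpha (W^{rec} r_t + W^{in} I_t) + \eta_t,
  \qquad \alpha = \Delta t / \tau .$$

### The noise term

The noise specification admits two discretizations, both implemented
(`noiseMode` of `initNetwork()`):

* `"euler"` — the stochastic term is read as part of the rate equation
  with standard deviation $\sigma\sqrt{2\tau}$, giving per-step noise
  $\alpha\,\sigma\sqrt{2\tau}\,\xi_t$. This is the plain Euler
  discretization of the printed model equation.
* `"em"` — the Euler–Maruyama scaling $\sqrt{2\alpha}\,\sigma\,\xi_t$,
  which keeps the stationary variance of $x$ invariant to $\Delta t$.

The package default is `"em"`: it is the only discretization whose
noise magnitude is invariant to the simulation step, which matters here
because networks are trained at 20 ms and re-simulated at 1 ms for
analysis (under `"euler"` the injected noise would shrink twenty-fold at
the analysis step). Both modes train to criterion with the published
learning parameters.

## The two tasks

Both tasks require the output to stay at 0, then ramp linearly from 0 to
1 over the second half of the target interval (3 s or 6 s) measured from
stimulus onset, and hold at 1 for 0.2 s. The baseline before stimulus
onset is jittered uniformly on the simulation grid in [0.2, 0.6] s.

* **2-Context**: a transient Go cue (1 for 0.5 s) plus a sustained analog
  context input at 0.75 (short) or 0.25 (long) until trial end.
* **2-Stimulus**: two separate transient channels (0.5 s) cue short
  versus long; no sustained input.

A trial is *correct* when the output first reaches 0.6 inside the
acceptance window (interval midpoint to interval end, relative to
stimulus onset). Variants used in robustness analyses are switches on
`taskConfig()`: `goEnabled = FALSE` (no Go cue), `contextMode =
"transient"` (context only during the stimulus window), `inputOverlap`
(shared input-weight rows in the 2-Stimulus task), and arbitrary
`contextLevels` pairs.

### Loss mask

The squared-error loss references a mask whose extent is not fully
pinned down by the task definition. The package default is a mask of
ones over the entire trial — the target formula already encodes the
baseline and first-half behavior — with `maskBaseline = TRUE` exposed to
exclude the pre-stimulus period. The default keeps the baseline
suppression of the output inside the objective.

## Training

Only the recurrent and output weights are trained (input weights stay at
their standard-normal draw), with Adam at learning rate 0.01 and default
moment parameters, one update per trial, conditions sampled uniformly.
Gradients are exact backpropagation through time through the rectified
Dale reparameterization (subgradient 0 below zero) and through the
Softplus cap. Every 100 trials the network is evaluated on 100 noise-on
trials and training stops at performance > 97% and mean error < 2.
Training uses a 20 ms step; all dynamics analyses re-simulate at 1 ms
with the trained parameters.

Initialization follows the balanced-sparse recipe: connection
probability 0.2 (off-diagonal), magnitudes |N(0, gain²/(pN))| with
gain 1 — the conventional normalization under which the gain sets the
dynamic regime independently of network size and sparsity, and under
which a gain of 1.5 is a meaningful robustness variant — inhibitory
outgoing weights multiplied by 4 at initialization only, and output
weights N(0, gain²/N). Under a literal per-entry standard deviation of
1 the initial dynamics saturate at the rate bound and the published
learning parameters do not reach the stopping criterion; the normalized
reading trains to criterion in a few thousand trials.

## Prototype dynamics: what the generator emulates

`makePrototype()` builds the analytic fixture on which every metric is
validated without any training: 100 units with Gaussian tuning curves of
width 0.8 s tiling 6 s at 1 ms resolution,
$x_i(t) = e^{-(t - (i/100)\cdot 6)^2 / (2 \cdot 0.8^2)}$. The
short-interval matrix is derived from the long one per regime: uniform
temporal subsampling (scaling), the first 3 s (absolute), or the scaled
matrix with rows shuffled (stimulus-specific). Two details are the
package's own resolutions of underdetermined corners:

* *Absolute regime, late units*: only the early half of the population is
  pinned by the definition ("first 50 units identical"); the remaining
  units' short-interval rows are taken as the first 3 s of their
  long-interval rows — late-field units are simply not yet active —
  which is the only construction consistent with absolute timing
  recruiting additional neurons in the longer interval.
* *Subsample phase*: the every-2nd-column subsample uses columns 2, 4,
  ..., 6000. The alternative phase (1, 3, ..., 5999) changes no reported
  quantity at the stated precision: both give a perfectly linear minimal
  index vector.

The prototypes are noiseless by construction. Passing the metric tests on
them shows the indices behave correctly on idealized sequences; it does
not by itself certify behavior on noisy, trial-averaged data, which is
why the classifier is additionally exercised on trained-network dynamics
with 25-trial averages.

## The timing-code indices

### Population level

`computeSSIPop(short, long)` computes the cross Euclidean distance matrix
between all column pairs of the two units-by-time matrices, takes the
per-row argmin (`I_min`, first index on ties), matches `I_min` against
the family of absolute-scaling reference vectors (identity up to a
breakpoint τ, then linear with slope α = (T_long − τ)/(T_short − τ); τ =
T_short is the identity vector, defined directly to avoid the degenerate
α), and reports `SSI_pop = 1 − cor(I_min, reference(τ_min))`. Pure
scaling and pure absolute dynamics both give 0; shuffled dynamics give
a positive value. Rates enter raw (trial-averaged); `normalize = TRUE`
rescales each unit by its peak first, exposed because PSTHgram displays
are commonly normalized while the index definition does not require it.

### Unit level

`computeUnitIndices(x, y)` warps the long-interval trace onto the short
grid for every breakpoint τ (identity before τ, compression by α after,
linear interpolation at fractional indices — higher-order interpolation
is irrelevant at 1 ms), picks τ_min by squared distance (first index on
ties), and sets `SSI_unit = 1 − cor(x, warped y)`. For `SSI_unit ≤ 0.5`
the absolute/scaling weights are averaged absolute cross-products of the
two traces' departures from the segment start, giving
`AbsR = W_abs / (W_abs + W_scale)` and
`ASI = (τ_min / T_short + AbsR) / 2`. Degenerate corners are defined as:
τ_min = 0 sets AbsR = 0 (no absolute segment); both weights zero, or a
zero-variance trace, makes the unit unclassifiable.

Classification: stimulus-specific if SSI_unit > 0.5, otherwise absolute
if ASI > 0.5, else scaling. Units whose peak rate across both intervals
falls below `activityFloor` (default 0.2, i.e. 1% of the rate bound) are
unclassifiable: flat traces carry no timing information and their
correlations are numerically meaningless. The breakpoint scan has a
coarse-grid fast path (`tauStep`, e.g. 10 ms with local refinement at
1 ms) that is tested to agree with the exhaustive scan.

```{r prototypes}
proto <- makePrototype("scaling")
computeSSIPop(rateMatrix(proto, "short"), rateMatrix(proto, "long"))
table(classLabels(classifyUnits(proto, tauStep = 10)))
```

## Behavioral summaries

Crossing times are detected on the simulation grid (first sample at or
above 0.6; no interpolation — sub-step precision is irrelevant at the
analysis step). Generalization sweeps test 11 conditions (context levels
in steps of 0.05, or channel mixtures in steps of 0.1) with 50 trials
each; novel-condition trials use the long-interval trial length so late
crossings remain observable, and crossing times are measured from
stimulus onset. The sigmoid fit `y = b + (a − b)/(1 + exp(g (m − x)))`
is initialized from the extreme-condition means with the slope bounded
in [0, 1000]; conditions with no crossings contribute no point and are
logged. The noise sweep tests σ from 0.1 to 0.8 (50 trials per interval),
reporting mean error over all trials and crossing-time SD over correct
trials only.

## Lesions and geometry

Unit deletion zeroes the unit's recurrent rows and columns (input and
output weights retained); synapse-group deletion zeroes one of the four
sign-defined blocks E→E, E→I, I→E, I→I, which partition the off-diagonal
entries. Connectivity statistics use a presence floor of 1e-6 on the
clipped magnitudes: training drives silenced weights exactly to zero via
the rectifier while surviving weights are bounded away from it, so any
small floor separates the two; the floor is exposed as an argument.
Class-targeted deletions draw the deleted set from the class-by-
population pool 10 times and test 20 trials per interval per draw
(both counts configurable).

State-space geometry: PCA on the time-concatenated short and long mean
dynamics after per-unit mean centering over concatenated time (the
standard preprocessing; centering per condition would artificially align
the two trajectories), projection of trajectories and of the input and
output weight vectors onto the top three components, and angles between
250 ms segment vectors (end minus start) and each projected weight
vector, reported in [0°, 180°] so opposite directions remain
distinguishable. Weight vectors are not unit-normalized before
projection; angles are invariant to the norm.

## Problem sizes used by the shipped tests and acceptance script

The package's own validation runs at sizes a single desk CPU handles
comfortably, stated here as the package's choices: metric-oracle
comparisons run on 10 ms-downsampled prototypes (300 × 600 grids);
full-resolution (1 ms) prototype metrics run in the acceptance script;
trained-network claims use one network per task seed with the full
N = 200, dt = 20 ms training conditions and ensembles of three networks
per task where a claim is about task differences (the original analyses
used 20 networks per task; with three, only the direction of each
difference is meaningful, not its significance). Unit classification of
trained networks uses the 10 ms coarse-grid fast path with 1 ms
refinement, which the tests show matches the exhaustive scan.

## Known limitations

* Single-trial gradient descent with the published learning rate has
  run-to-run variance in trials-to-convergence; seeds are fixed
  everywhere reproducibility matters.
* The indices assume trial-averaged, time-locked rates; they are not
  defined for point-process (spike) data without prior smoothing.
* With three networks per task, across-task comparisons are directional
  checks, not hypothesis tests; no inferential statistics are computed.
* The alternative reference-matrix construction with the scaling factor
  fixed at 2 ("partial scaling") is exposed for completeness but is not
  validated against any reference values.
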
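---
title: "From trajectories to decision strategies: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From trajectories to decision strategies: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(foragedm)
```

This vignette is the package's account of its science: the choice model and
its assumptions, what each behavioral feature measures and how its edge cases
are resolved, what the bundled simulator does and does not emulate, and the
design decisions taken where more than one reasonable reading existed.

## The task and its data

A rat forages in a unit-square arena with one feeder per quadrant. Each trial
runs tone (4 s) → cue (one feeder's LED ring lights up) → approach window
(6 s) → consumption (7 s, accepted trials only) → inter-trial interval
(28 s). The offer pairs a sucrose concentration (0.5/2/5/9%, fixed per
feeder location) with an LED illuminance cost that varies across trials. An
*accept* means the animal's centre point is inside the cued reward zone at
the end of the approach window; the zone is a disc of radius 0.18 around the
feeder by default, switchable to full-quadrant membership (both definitions
are in active use for this kind of task; the disc is the stricter one).

Coordinates are normalised to $[0,1]^2$, origin at the arena's lower-left,
y up, quadrants numbered row-major from the bottom-left. Tracking is sampled
nominally every 0.1 s; trial logs carry per-trial offers, event times and
outcomes. `assemble_session()` cross-checks the two streams (index
continuity, interval coverage, coordinate range, time monotonicity) and
reports *all* failures, not the first. Where the logged outcome and the
outcome re-derived from tracking disagree, the tracking-derived outcome wins
and the disagreement is reported as a warning — the hardware log has no
access to position, so the spatial record is treated as authoritative.

## The choice model

Acceptance probability is a product of a reward logistic and a cost
logistic:

$$f(R, C) = \frac{1}{1+e^{-a_R R + b_R}}\cdot\frac{1}{1+e^{a_C C + b_C}}.$$

The multiplicative exponent form ($a_R R$, $a_C C$) is used for the
one-dimensional curves as well: an additive form ($-a_R + R + b_R$) leaves
the slope parameter unidentifiable (it collapses into the shift), so the
package treats the two-factor form as canonical throughout.

The model is separable by assumption: reward sensitivity does not depend on
the cost level offered. That is an approximation — context effects (e.g.
lower acceptance of a cheap offer in sessions that also contain expensive
ones) are real — and it is exactly the approximation that makes the decision
boundary closed-form:

$$R^*(C) = \frac{b_R - \ln(1/S_R - 1)}{a_R},\qquad
  S_R = \tfrac12\!\left(1 + e^{a_C C + b_C}\right),$$

valid where $S_R < 1$; elsewhere the cost factor alone keeps acceptance
below one half and `decision_boundary()` marks the cell nonexistent rather
than extrapolating.

Fits are least squares on per-level acceptance *proportions*, not binomial
maximum likelihood: with four levels and tens of trials per level the two
differ little, and least squares matches how such curves are normally
summarised and plotted. Optimisation runs from a fixed multistart lattice
(16 deterministic starts plus a linearised heuristic), each polished by
`nlminb` at tight tolerances with a Nelder–Mead fallback; the best SSE wins.
Parameter uncertainty comes from a seeded parametric bootstrap (200 draws by
default): binomial resampling when per-level counts are available, Gaussian
residual resampling otherwise, with 80% percentile intervals.

Curves are fit on ordinal levels 1–4 by default rather than physical units
(percent sucrose, lux): the levels are what the animal can discriminate, the
spacing of the physical values is arbitrary on the logistic scale, and
ordinal fitting keeps parameters comparable across task variants.

### Utility curvature

`fit_marginal_utility()` replaces $R$ by $g(R) = c\,R^2/2 + R$, the unique
quadratic utility with $g(0)=0$ and $g'(0)=1$. With $c=0$ this reduces
*exactly* to the linear-reward fit, so the free-curvature model nests it and
the SSE comparison is meaningful; $c<0$ bends the curve toward diminishing
marginal returns. The quadratic is deliberately the simplest curvature
family — the point is a one-parameter test of nonlinearity, not a flexible
utility estimator.

### Valuation, elasticity, sensitivity

From any fitted curve the package reports *valuation* (the half-maximum
crossing, located numerically on a grid wide enough that a logistic
effectively reaches both asymptotes), *elasticity* (the maximum slope of the
fitted curve; $a/4$ for a unit-height logistic), and *sensitivity* (two
diagnostics, neither privileged: the residual MSE of the fit, and the width
of the 80% bootstrap band of fitted values at the valuation point).

## Behavioral features

All features are per-trial, computed on the tracking slice from tone onset
to the start of the next trial.

* **Distance traveled** — summed Euclidean step lengths of the centre point.
* **Travel pixels** — distinct cells of a `grid_n` × `grid_n` partition
  (default 64, a coarse camera-pixel emulation) visited by the centre point;
  segments between samples are rasterised so fast movement cannot skip
  cells.
* **High-speed runs** — speed by forward difference, acceleration by central
  difference of the speed series (dividing by actual Δt, so irregular
  sampling is handled); a sample is an outlier when its acceleration exceeds
  the trial's median + `k_sd`·SD. The multiplier is not fixed by convention,
  so it is a parameter; the default is `k_sd = 2`. Consecutive outliers form
  one *run*: the run count is the headline number (raw outlier counts are
  also returned) and is additionally normalised by distance traveled. A
  strict-exceedance guard keeps float jitter on a constant-speed path from
  ever counting as an outlier.
* **Stopping points** — a sliding 3-s window is *stopped* when displacement
  stays below 0.1 normalised units in both axes across the window;
  overlapping and adjacent stopped windows merge into one event. Without
  merging, a single long stop would count once per sample, which cannot be
  the intended reading.
* **Rotation points** — head direction is the angle of the centre-to-head
  vector, unwrapped; an event is a 1.5-s window accumulating more than 180°
  of absolute heading change, and the scan restarts past each detected
  window so one physical turn is never double-counted. Sessions without head
  tracking report the feature as unavailable (`NA`) rather than guessing
  heading from velocity.
* **Approach time** — zone-entry latency from the tone; absent on rejects.
* **Reaction time** — the task defines no reaction time, so the package
  makes its definition explicit and configurable: movement onset is the last
  sample still within `eps_move` (default 0.05) of the position held at tone
  onset, before the first sample exceeding it.
* **Proportion outside reward zones** — the fraction of a trial's samples
  outside all four zones. This quantity is sometimes described as
  time-in-centre divided by trial count (units of seconds) yet plotted as a
  proportion; the per-trial proportion is implemented, whose session mean is
  the plotted quantity, and the unit inconsistency is simply noted here.

## The simulator

`simulate_session()` replicates the trial engine and drives an agent whose
accept/reject draws are Bernoulli with the two-factor logistic probability
at each trial's (reward, cost) ordinals, and whose locomotion is waypoint
pursuit: straight legs between random waypoints, a straight approach to an
orbit around the cued feeder on accepts, exclusion of the cued zone on
rejects (with an optional "hesitation" partial approach — whether real
rejected trials contain partial approaches is not knowable from the outcome
alone, so it is a probability, not an assertion). Head direction is
deliberately *decoupled* from locomotion: it is constant except during
scripted full rotations plus optional noise. None of this claims to model
rat kinematics; it is the simplest motion model that exercises every feature
extractor and keeps every scripted event (stop, rotation, zone entry)
exactly recoverable.

With speed and heading noise at zero, the scripted event logs are exact
oracles: stops are scheduled ≥ 8 s apart inside inter-trial wandering with
durations (4 s) exceeding the 3-s detection window, wandering legs are long
and fast enough that no unscripted 3-s window can stay within the stop
threshold, and rotations are 1-s 360° spins spaced ≥ 4 s so the restart rule
counts each exactly once. The test suite asserts feature = log equality on
this regime; with noise enabled the equality intentionally breaks, which is
what the noise parameters are for. Cost levels mix 50/50 between the low and
high illuminance by default, overridable, matching the standard two-level
battery. Each session's RNG stream is keyed by (seed, rat id, session
index), so cohorts are reproducible trial-by-trial and sessions are
independent of cohort composition.

What the simulator does **not** emulate: learning across sessions, satiety
within a session, context effects across cost regimes, pharmacological
condition effects (conditions differ only by the policy/kinematics
parameters you give them), or realistic rodent gait. Tests passing on
simulated data therefore validate the *computations*, not claims about real
rats.

## Shape classification and clustering

Per-session psychometric functions are fit to three sigmoid variants
($1/(1+be^{-cx})$, $a/(1+be^{-cx})$, $a/(1+be^{-c(x-d)})$) and a parabola
$a(x-b)^2+c$ (the parabola by exact linear least squares). A curve is
*sigmoidal* if any sigmoid reaches $R^2 \ge 0.4$ — when several do, the
three-parameter form is the reported model — otherwise *parabolic* if the
parabola reaches the threshold, otherwise *undefined*. Descriptors: sigmoid
shift $= d + \ln(b)/c$ (half-maximum location), slope $= ac/4$, max $= a$;
parabola shift $= b$ and max $= c$ (vertex), with upward-opening fits
($a>0$) labelled invalid since they have no interior maximum.

Two identifiability guards matter in practice. The sigmoid plateau is
bounded at three times the largest observed value — a plateau far above
every observation cannot be estimated, only capped, and unbounded fits
otherwise collect at the optimiser limit and masquerade as a distinct
cluster. And a fit whose half-maximum lies outside the sampled level range
is flagged `identified = FALSE`: its shift and max are extrapolations, and
such sessions are excluded from clustering exactly as invalid parabolas are.

Clustering runs fuzzy c-means (fuzzifier $m = 2$, the standard default;
tolerance $10^{-8}$ on the membership matrix; 10 seeded restarts per
candidate count keeping the best objective) on 2-D descriptor pairs,
(shift, max) by default, with axes standardised to zero mean and unit
variance — shift and slope live on incommensurate scales, and raw-scale FCM
would be dominated by whichever axis happens to be larger; a raw mode
remains available. The cluster count maximises the MPC over 2–8; a winning
MPC below 0.5 is flagged as "no cluster structure" (at 0.5 memberships are
still closer to uniform than crisp, which is not a partition worth
interpreting).

Condition comparisons freeze the baseline model and *project* condition
sessions onto its centres (`fcm_project()`), so "cluster A" means the same
thing in both conditions and migration is well-defined; refitting per
condition and matching centres is possible but makes cluster identity a
matching problem, so projection is the default. Per-rat strategy profiles
hard-assign each session to its maximum-membership cluster (ties to the
lowest index; a soft mean-membership mode exists) and record
sessions-in-cluster probabilities; rats absent from a feature's point set
have that feature omitted from their concatenated profile rather than
zero-filled. Shifts are per-rat Euclidean distances between profiles,
compared across conditions by the exact two-sample Kolmogorov–Smirnov test,
and per-cluster session-count migration uses 2×2 χ² tests without Yates
correction (raw and Holm-adjusted p-values reported).

One calibration fact worth knowing: the exact two-sample KS statistic is
discrete, so at cohort-sized samples (15–40 per group) its achievable size
at nominal α = 0.05 is roughly 0.027–0.038 even for continuous data. The
test suite's type-I calibration harness (500 null replicates of the full
distance-profile pipeline) asserts the rejection rate stays below nominal
and within that intrinsic range; expecting exactly 0.05 would be asking the
KS test for something it cannot do.

## Problem sizes and numerical choices

The test suite and acceptance script run everything at desk scale: sessions
of 40 trials (the task's daily standard), cohorts of six rats, 50-seed
recovery sweeps over per-cell trial counts {25, 100, 400}, and 500-replicate
null calibrations — sizes chosen so the full suite completes in a couple of
minutes while keeping every statistical assertion's standard error small
relative to its margin. Optimiser tolerances (SSE to ~1e-14) are tight
enough that noise-free model inversion reproduces $R^2 = 1$ to 1e-9, which
is asserted, not assumed. Degenerate inputs have defined behaviour
throughout: flat curves flag as degenerate instead of returning an infinite
shift silently, zero distance makes the per-distance run rate `NA`, a point
coincident with an FCM centre receives membership one split across the
coincident centres, and empty approach-rate cells are absent rather than
zero.

## Known limitations

* The separable choice model cannot express reward–cost interactions; its
  boundary inherits that assumption.
* Shape classification with four levels is coarse: the four-parameter
  sigmoid can interpolate most monotone 4-point curves, which is why the
  classifier prefers the three-parameter model and why the 0.4 threshold
  does real work.
* MPC-based count selection favours splitting off compact outlier groups;
  the identifiability exclusions mitigate but do not eliminate this.
* The simulator's ground-truth guarantees hold in the noise-off regime only;
  with noise on, feature counts are estimates, as they are for real data.
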
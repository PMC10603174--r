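---
title: "From ORN firing to walking statistics: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From ORN firing to walking statistics: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(odorwalk)
```

## The problem

A walking fly in a circular arena (radius 4 cm) experiences an
optogenetic "odor": a central light zone (radius 1.25 cm) that drives a
chosen class of olfactory receptor neurons (ORNs).  Because the fly
carries its own sensor through the stimulus field, its sensory
experience is a function of its own movement — entering the zone ramps
the ORN firing rate up, leaving ramps it down, and staying inside
adapts it back toward a plateau.  `odorwalk` implements the full
analysis chain that turns trajectories into a generative
sensorimotor model:

1. **Stimulus reconstruction** — the light intensity at the head, from
   the radial intensity profile of the arena.
2. **Neural encoding** — a two-stage linear filter cascade from
   intensity to local field potential (LFP) to firing rate.
3. **Locomotor segmentation** — four states (sharp turn, curved walk,
   stop, boundary) with per-state kinematic summaries.
4. **Sensorimotor mapping** — the conditional distribution of each
   kinematic parameter given the recent neural response, estimated by
   K-nearest neighbors over the plane spanned by the mean firing rate
   *f* and its mean rate of change *Δf* in the 200 ms before each state
   transition.
5. **Turn geometry** — whether turns are directed toward the arena
   center more often than chance.
6. **Integration rules** — a lognormal interaction model for how two
   co-activated ORN classes combine their effects on a kinematic
   parameter.
7. **Generative agent model** — virtual flies that sample their next
   state, kinematics, and turn direction from the fitted maps, closing
   the loop through the encoder.
8. **Spatial validation** — radial occupancy, turn density, and
   half-L1 discrepancies between cohorts.

Every stage is testable by recovery because the package ships a
synthetic-data generator with known ground truth.

## The encoder cascade

The firing rate is modeled as a linear–linear cascade

$$\mathrm{LFP} = k_1 * s, \qquad
  r = \max\!\big(0,\; k_2 * \mathrm{LFP} + r_0\big),$$

with stimulus $s$ in µW/mm², both finite impulse responses $k_1, k_2$
2 s long at 100 Hz by default, and baseline rate $r_0 = 4.7$ spikes/s.
Each filter solves a ridge problem $\min \lVert Sk - r\rVert^2 +
\lVert\lambda I k\rVert^2$, where $S$ is the lagged (Hankel) design
matrix with $(d-1)$ zeros padded before the first sample.  Fitting
several trials jointly stacks one design block per trial, each with its
own zero padding — concatenating trials into one series would couple
the end of one trial to the start of the next.

**Choosing λ.**  The regularization strength is selected at the elbow
of the L-curve (log residual norm against log solution norm).  "Elbow"
needs an algorithm, and a pointwise maximum-curvature rule on a coarse
λ grid is fragile: on the flat branches consecutive points nearly
coincide and finite differences amplify noise, and the bend where the
residual saturates at very large λ can masquerade as a corner.  The
rule used here evaluates both norms on a dense 400-point λ grid (cheap,
since the SVD of $S$ is already available), computes the *signed*
discrete curvature along the curve traversed with λ increasing — the
genuine elbow is a counterclockwise bend in this orientation — and
restricts the search to the part of the curve whose residual is within
a factor 2 of its floor, where the elbow lives by definition.  If no
counterclockwise corner exists (noise-free data has no vertical
branch), the smallest λ whose residual is within 0.1% of the minimum is
used.  The selected λ is snapped back to the user-visible grid, 30
values log-spaced over six decades scaled to the largest singular
value.

Recording preprocessing follows the standard recipe: the LFP is a
300-ms running median of the raw voltage, spikes are valleys of the
median-subtracted trace below −0.8 mV at least 5 ms apart (deeper
valleys win), and the rate is the Gaussian-kernel smoothed spike train
with 150 ms bandwidth; everything is carried at 100 Hz downstream.

## Kinematics and segmentation

Speed is the frame-to-frame centroid displacement over the frame
interval, in mm/s.  Curvature is the magnitude of the change of the
unit normal to the path, signed positive for leftward turns; at 30 Hz a
per-frame value of $2\sin(\delta/2)$ corresponds to a turning angle
$\delta$ per frame.  Zero-displacement frames leave the normal
undefined; such frames carry curvature 0, are flagged, and never seed
turn detection.

Segmentation is frame-wise with precedence: **boundary** when the
centroid is within 1.5 mm (0.0375 normalized) of the wall, then
**stop** when speed < 0.5 mm/s, then **sharp turn** around curvature
peaks, remainder **curved walk**.  Numerical choices that matter:

* The turn-peak threshold is the 95th percentile of pre-light
  |curvature| per fly (self-calibrating), floored at 0.05 rad/frame so
  numerically straight tracks cannot produce spurious peaks; detected
  peaks are expanded while |curvature| stays above half the peak.
* The boundary radius test carries a 0.04 mm tolerance: wall-following
  arcs sampled mid-chord at 30 Hz dip below the nominal band radius by
  less than tracking resolution, and without the tolerance a single
  wall visit fragments into dozens of one-frame segments.
* Segment durations are measured from the time stamps, not from a
  nominal frame rate, so irregular frame intervals cannot bias them.
* Curved-walk speed and curvature are averaged over the segment's
  interior frames (0.2 s trimmed per side when the segment is at least
  three trims long).  Frames bordering a transition carry the tail of
  the neighboring episode — most prominently the slow straight
  approach and recovery around a sharp turn — and the interior average
  is the cleaner estimate of the walk's own kinematics.  For the same
  reason, curved-walk fragments no longer than 0.25 s sandwiched
  against a sharp turn are absorbed into the turn episode.

## The (f, Δf) maps

Each post-entry state start is embedded at the mean firing rate *f* and
mean rate derivative *Δf* of the preceding 200 ms.  The grid spans
f = 0–55 spikes/s in steps of 1 and Δf = −150–150 spikes/s² in steps of
15.  Distances divide f by a = 10 and Δf by b = 30 (only the ratio
matters for the neighbor ordering; the ellipse semi-axes are aT and
bT), and each node collects its K nearest points within the elliptical
bound T.  Defaults follow the standard analysis configuration: K = 64, T = 1.5 for
sharp-turn and curved-walk kinematics, T = 1 for stops, and K = 128 for
transition probabilities.  A grid search of the mean per-cell standard
error against K locates the elbow as a diagnostic; the stated defaults
are retained as configuration.

Per node, the kinematic values of the neighborhood are fit by a
lognormal (mean and ML standard deviation of logs).  Nodes with 15 or
fewer in-bound points are masked; queries interpolate µ and σ
bilinearly inside the defined region and, where the simulator needs
total coverage, fall back to the nearest defined node with a flag.
Curvature magnitudes are clamped from below at 10⁻³ rad/frame before
the log transform: the value represents a measurement-resolution
floor, and without it a handful of numerically straight segments
dominates the log-scale variance and the fitted lognormal occasionally
generates absurd draws.

The time-resolved (adaptation) variant adds time since first entry as
a third dimension with weight c = 20 and 5-s increments, and a
permutation test (100 shuffles of the entry times) flags cells whose
empirical lognormal mean falls outside the central 95% band of the
shuffled maps.  Transition maps count non-self transitions per source
state, smooth each next-state plane with a uniform 5×5 kernel over
defined cells, and renormalize.

**Regions.**  The response plane is divided into five regions:
I (Δf > 20 spikes/s², entering), III (Δf < −20, leaving),
IV (f below the 4.7 spikes/s baseline, inhibition), II (f > 15, fully
inside), V (baseline to 15 spikes/s, border exploration).  Where the
definitions overlap the rate-of-change regions take precedence (I/III
over IV over II over V), matching the reading that entering and
leaving are defined by the rate dynamics; this is the one place the
classification needed a decision, and it is applied consistently by
classifier, summation model, and simulator.

**Firing-rate context.**  Points are also labeled `inhibition`
(f < 1 spikes/s), `baseline` (f within ±3 spikes/s of the baseline and
|Δf| ≤ 10 — operational bands chosen here), or `non_baseline`.  Baseline episodes are split into
the first two state instances after reaching baseline versus later
ones, which get separate lognormal fits; inhibition-period kinematics
get time-dependent fits (lognormal speed, beta curvature rescaled by
the empirical range, exponential duration) over 0.5-s windows sliding
by 0.2 s, with window-center parameters interpolated by a natural
spline.

## Turn geometry

With $\vec v = p_2 - p_1$ (position 200 ms before the transition to the
position at the transition) and $\vec u = -p_2$ the inward vector, the
directed angle is `atan2((v × u)·n, v·u)` with n the +z normal.  A
variant of this expression divides the first argument by
$\vec v \cdot \vec u$ as well; that form is singular when the motion is
tangential and algebraically redundant otherwise, so the standard
two-argument form — with identical sign semantics everywhere — is what
the package computes.  A turn is optimal when the sign of the next
state's total curvature matches the sign of θ; exact ties (zero net
curvature, θ = 0, |θ| = π) are excluded from both numerator and
denominator of the optimality ratio.

## Integration rules for ORN-class pairs

Within a region, log kinematics are normal with
$\mu_A = \mu_o + \mu_a$ for class A alone and
$\mu_{AB} = \mu_o + \mu_a + \mu_b + \alpha\,\mu_a\mu_b$ for joint
activation; variances add, with a covariance term $2\sigma_{ab}$ in the
joint arm.  Baseline terms come from each genotype's pre-entry values;
$(\alpha, \sigma_{ab})$ maximize the joint arm's likelihood, which for
the normal likelihood is available in closed form from the arm's log
moments (the closed form is verified against a grid-search MLE in the
tests).  Both a jointly-estimated and a zero-fixed $\sigma_{ab}$ mode are
provided; joint estimation is the default (the α estimate is identical either way).
When $|\mu_a\mu_b| < 0.01$, α is unidentifiable and reported as such,
and the interaction is judged from the confidence interval of the raw
joint-arm residual instead of a point estimate.

Exponentiating turns the terms into multiplicative gains
($e^{\mu_a}$, $e^{\mu_b}$, $e^{\alpha\mu_a\mu_b}$; a gain of 1.46 is a
46% increase).  Gains outside the band [0.9, 1.1] are notable:
concordant individual effects enhanced by the interaction are
*synergistic*, cut back *antagonistic*; opposing individual effects
resolved in one class's direction are *dominant*; a notable interaction
without individual effects is *other*; and an interaction gain inside
the band is *linear*.

## The agent model

Virtual flies start at the center heading +x in a curved walk and run
at 100 Hz for 6 min with light-on at 3 min.  At every state end the
next state, the kinematics, and the turn direction are sampled from the
policy — either the ground truth or the fitted maps.  Sharp turns move
straight for half the sampled duration, rotate by the sampled total
curvature in a single step, then move straight; stops do the same at
zero speed; curved walks hold constant speed and angular velocity;
reaching within 0.0375 of the wall enters the boundary state, an arc at
constant angular speed with bivariate-lognormal (angle, duration),
exited by reorienting toward the center into a curved walk or sharp
turn (50/50 by default, configurable).  Wall collisions mid-step clip the state at the
contact step.  The fly's own positions drive the stimulus, the cascade
produces the rate online, and first entry is the first time the rate
exceeds 10 spikes/s after light-on.  Cohorts keep flies whose first
entry falls within the 85th percentile of the reference distribution.

Border choice adds either an exponentially decaying extra
curved-walk→sharp-turn hazard after each |Δf| ≥ 15 spikes/s² crossing
(scale and decay are configuration) or, in filter mode, additive
corrections to speed and
curvature from 2-s filters of the recent rate history, active for at
most 2 s per crossing and reset by the next one.  Both reduce exactly
to the plain model when their parameters are null, which the tests
assert.

Tracks are emitted at a uniform 30 Hz by linear interpolation of the
piecewise-linear path (exact, and mirrors real tracking's uniform
frame clock), with per-state latent logs retained so estimators can be
tested by recovery.

## What the synthetic data does and does not emulate

The generator reproduces the structure the estimators assume: a
radially symmetric plateau-and-falloff light zone (logistic falloff of
width 0.05 normalized — a qualitative stand-in for a focused-LED field,
not a measured calibration); a two-stage encoder with baseline 4.7 spikes/s and
monophasic/mildly biphasic kernels; smooth lognormal-parameter
surfaces over (f, Δf) built from planar and Gaussian-bump terms so KNN
recovery has an analytic target; state transitions with more stops at
low rates and ~25% of stops leading to sharp turns; and a turn bias of
0.7 toward the center in the leaving region under the "attractor"
preset (the "null" preset switches every effect off).  Baseline
magnitudes (walk speed ≈ 12 mm/s, turn reorientation ≈ 1.5 rad, state
durations of 0.3–1 s, boundary visits of ≈ 2 s) were chosen once as
typical walking-fly values.

It does **not** emulate tracking noise, body orientation or
head/centroid disagreement, leg mechanics, inter-fly variability in
encoder gain, or plume-like stimulus dynamics.  Passing recovery tests
therefore demonstrates the correctness and self-consistency of the
estimators on data satisfying their assumptions, not robustness to the
full messiness of real recordings.

## Problem sizes and verification

The test suite and `scripts/acceptance.R` verify, among others:
encoder recovery from six 60-s trials at signal-to-noise 10 (normalized
RMSE of both filters < 0.1, held-out R² > 0.95); KNN map recovery from
20,000 synthetic points (µ within 3 SE of truth in ≥ 95% of cells,
neighbor sets identical to brute force on 5,000-point instances);
region classification against an exhaustive oracle; turn-optimality
null calibration over 10,000 unbiased turns; summation-model recovery
at n = 500 per arm with ≤ 10% false non-linear calls across 200 null
replicates; logistic-GLM coefficient recovery at 10⁵ steps; the full
closure loop at 2 × 150 flies (radial-occupancy discrepancy < 0.05);
and the adaptation permutation test's type-I rate at 100 shuffles.

One check is known to sit at the edge of its band: the BCa bootstrap's
true coverage for the mean of lognormal samples at n = 50 is ≈ 92.6–93%
(both for this implementation and for `boot::boot.ci`, which agree
interval-for-interval) — the characteristic mild under-coverage of
unstudentized bootstrap intervals at this sample size — so a 1,000-
replication coverage experiment lands within Monte-Carlo error of the
93% lower edge and can resolve to either side of it.

## Known limitations

* The sharp-turn execution of the agent (single-step rotation between
  straight flanks) is a deliberate simplification; re-segmentation of
  agent tracks assigns the flanks by the rules above rather than by
  latent state, which is the main residual term in the closure loop.
* KNN maps are estimated on segment-level points; no kernel-regression
  or Bayesian smoothing alternative is provided.
* The interaction model is pairwise; three-way terms are out of scope.
* Map serialization keeps plain-text JSON/CSV only.
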
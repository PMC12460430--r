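---
title: "Mapping cursor-tracking measures onto drift diffusion parameters: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mapping cursor-tracking measures onto drift diffusion parameters}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(traceddm)
```

## The scientific problem

In a two-alternative forced-choice task, two behavioral windows onto the
decision process are available. Choice frequencies and response-time (RT)
distributions can be fit with the drift diffusion model (DDM): noisy
evidence accumulates between two absorbing thresholds, and the model's
parameters — drift rate $v$ (accumulation speed), threshold separation $a$
(evidence required before committing), and non-decision time $t_0$
(encoding plus motor execution) — have established psychological readings.
Reliable fitting, however, needs on the order of 40 or more comparable
trials per participant. Mouse-cursor tracking offers a second window: the
cursor path recorded during each single trial, summarized into measures of
deviation, complexity, speed and timing. The measure zoo is large and
heavily intercorrelated, which makes it hard for newcomers to choose.

`traceddm` connects the two windows. It reduces the 18-measure battery by
correlational screening, maps the survivors onto per-participant DDM
parameters with partial least squares regression (PLSR), prunes each model
down to a minimal predictor set, and asks — by bootstrap trial
subsampling — whether cursor measures extracted from few trials predict the
parameters more stably than refitting the DDM on the same few trials.

## The DDM engine

The likelihood of a response time $t$ and boundary choice is the Wiener
first-passage density with the starting point fixed at the neutral
$z_r = 0.5$ and diffusion coefficient $s = 1$; inter-trial variability
parameters are fixed at 0, so exactly $(v, a, t_0)$ are free. The density
is evaluated by the standard dual series expansion — a small-time and a
large-time representation with automatic switching at a truncation error
of $10^{-7}$ — which is numerically stable over the task's RT range
(0, 2 s]. The lower-boundary density yields the upper boundary by the
reflection $v \to -v$, $z_r \to 1 - z_r$.

Per participant, `fit_ddm()` maximizes the summed log density with
box-constrained quasi-Newton optimization from at least five starting
points (three accuracy-informed starts using
$P(\text{correct}) = \mathrm{logistic}(v\,a)$, plus a coarse grid); $t_0$
is bounded above by the fastest response minus 1 ms. The fit index is the
mean log-likelihood per trial, a monotone transform of the ML criterion
that is comparable across participants with different trial counts.

The simulator is an Euler–Maruyama walk with step `dt = 1e-3` s by
default. A discrete walk misses within-step boundary excursions, which
biases choice probabilities and first-passage times; the simulator
therefore applies the Broadie–Glasserman–Kou continuity correction (both
boundaries pulled inward by $0.5826\,\sigma\sqrt{dt}$) and attributes the
crossing to the middle of its step. With the correction, simulated choice
probabilities and mean decision times agree with the closed forms within
Monte-Carlo error at $n = 10^5$; without it the bias is several standard
errors. `dt` remains a bias/variance knob: halving it roughly halves the
residual bias at double the cost.

Before fitting, RT outliers are trimmed per participant: the fastest
$\lceil 0.035\,n \rceil$ trials are discarded, then trials slower than the
mean plus twice the standard deviation of the remainder. Both rules are
relative to the current sample, so the filter is intentionally not
idempotent. Fit quality is screened against synthetic parameter sets:
1000 (by default) triples drawn from a trivariate normal with the mean and
covariance of the empirical fits (draws with $a \le 0$ or $t_0 < 0$
rejected), each simulated, truncated at the response ceiling, thinned to
90 trials, and refit. Empirical fit indices below the 5% quantile of the
pooled synthetic distribution are flagged. Calibration of this screen
assumes the fitting model matches the generating process; under heavy RT
truncation the fitted covariance understates the true parameter spread and
the screen over-flags, which is why the package's calibration checks run
in a regime where the response ceiling is not binding.

## The 18 cursor measures

Trajectories are used raw (no smoothing, no time normalization), restricted
to the stimulus phase, x-centered at the start, and mirrored so every
response points left. The optimal trajectory is the straight segment from
the first to the last sample; signed perpendicular deviation is positive
toward the non-chosen side. On this basis the package computes, per trial:
mean absolute deviation (AD), absolute area between path and chord (AUC,
trapezoid over the chord projection), maximum absolute deviation (MAD) and
its one-sided variant (MADabove), the closest horizontal approach to the
alternative response (minX, reported as the largest x attained), and
curvature (path length over chord length, $\ge 1$ by construction).

Velocity is two-dimensional path speed per inter-sample step, each step
attributed to its later endpoint (a velocity exists once the step
completes). From it derive maxVel, minVel, a time-weighted meanVel (total
path length over duration, robust to irregular sampling), maxAcc,
timeToPeakVel and timeToPeakAcc (first maximum, measured from stimulus
onset), motorPauses (summed duration of zero-displacement steps; the
strict-zero threshold is configurable) and motionTime (duration minus
pauses, so the two always sum to the trial duration). Counting measures:
xFlips (sign changes of consecutive nonzero horizontal steps, zero runs
skipped to avoid quantization artifacts), reversals (crossings of the
start line after first departure, a touch-and-return counting once), and
accChanges (sign changes of consecutive nonzero accelerations).

Sample entropy of the first-differenced x series (sampleEnX) uses
embedding dimension $m = 2$ and tolerance $r = 0.2 \times \mathrm{SD}$ of
the series — common practice where the source literature states no
values; both are arguments. SampEn is $-\ln(A/B)$ with $B$ the number of
$m$-template matches and $A$ the number of $(m{+}1)$-template matches at
Chebyshev distance $\le r$, self-matches excluded; a series with no
$m$-matches (or no $(m{+}1)$-matches, where the ratio is undefined) yields
a flagged missing value. Because $r$ scales with the series SD, the
measure is amplitude-invariant.

Participant-level vectors are arithmetic means over the retained trials —
correct and error trials alike — and all 18 means are taken over exactly
the same trial subset: a trial with any flagged-missing cell is excluded
from the aggregation entirely rather than per-column.

## Correlational reduction and the PLSR chain

Measures with $|r| \ge 0.9$ at the participant level are condensed
iteratively, always keeping the member that is cheaper to compute;
`measure_precedence()` ships the ranking (deviation extremes before
integrals and averages, velocity before acceleration, timing and
complexity last). RT and accuracy take part as retained partners — a
measure redundant with RT is dropped — but are never dropped themselves
and never enter the cursor-only predictor sets.

Each DDM parameter then gets its own PLS1 regression (NIPALS), with
predictors and criterion z-standardized — the measures live on wildly
different scales — and coefficients reported standardized. The component
count minimizes the leave-one-out RMSEP over $1 \ldots \min(p, n-2)$;
every fold refits the standardization as well, so the cross-validation is
honest. Reported $R^2$ is always $1 - \mathrm{PRESS}/\mathrm{TSS}$ from
leave-one-out.

Three pruning stages follow, each logged in a replayable trace:

1. *Sign consistency*: while any predictor's coefficient contradicts the
   sign of its Pearson correlation with the criterion (a suppressor
   configuration that resists substantive interpretation), the mismatching
   predictor with the weakest correlation is dropped and the model refit.
2. *VIP reduction*: all predictors with variable-importance-in-projection
   below 0.8 are dropped at once; afterwards the lowest sub-threshold
   predictor is dropped iteratively as long as the LOO RMSEP does not
   increase. VIP² always averages to 1 across predictors, which the test
   suite checks after every refit.
3. *Minimal-model probing*: removals are accepted greedily while the
   explained-variance loss stays within 0.01 and the RMSEP rise within
   0.002. The thresholds are arguments; the defaults are chosen to admit
   reductions of the size reported in comparable analyses
   (ΔR² ≈ −0.7 to −0.9 percentage points at ΔRMSEP ≈ +0.001) without
   waving through materially worse models.

Ties between equally weak sign-mismatched predictors break by the
precedence ranking, so the pipeline is invariant to predictor column order
up to that documented rule, and the whole mapping chain is deterministic
given its input.

## Trial-reduction bootstrap

Two resampling pipelines share one design: per participant, draw $s$
trials with replacement; repeat $B$ times per size (1000 by default;
smaller in the test profile). The cursor pipeline averages the per-trial
predictors over each draw and refits the family PLSR — cursor-only
(the minimal model's measures), RT/accuracy-only, or hybrid — against the
*fixed* full-data parameters, recording the LOO $R^2$. The DDM pipeline
refits the model by maximum likelihood on each draw (sizes start at the
10-trial fitting floor) and squares the across-participant correlation
between subsample and full-data parameters. Summaries are means with
percentile 2.5/97.5 intervals over iterations; the largest drawable size
is the smallest retained-trial count across participants, the only reading
under which every participant can contribute every size. Each
(size, iteration) cell gets its own RNG stream derived from the master
seed, so results are reproducible regardless of execution order. The
trial-order controls reuse the family definitions without resampling:
accumulated models use presentation-ordered prefixes, single-trial models
each position alone.

## The synthetic cohort generator

No raw cursor data ships with the package; a generator with known ground
truth stands in, emulating a 103-participant × 90-trial session sampled at
107 Hz with a 2-s response ceiling. Participant parameters come from a
truncated trivariate normal (rejection sampling, acceptance rate
reported). Defaults — mean $(v, a, t_0) = (0.65, 2.0, 0.35)$, SDs
$(0.35, 0.45, 0.13)$, diagonal correlation — were chosen once so that
accuracy spans roughly 0.5–0.95 around a mean near 0.8 and mean RTs sit
near 1.1 s, the performance envelope a perceptual two-choice task of this
difficulty produces. Choices, RTs and evidence paths come from the
package's own DDM simulator; trials beyond the ceiling are redrawn, which
mimics the task's time limit.

The motor model is the module's own construction — the source material
implies no generative trajectory model — and it is built so that each
planted cursor–parameter coupling runs through its own channel and can be
switched off independently:

- *Lateral complexity → drift rate.* Pre-decision lateral movement is a
  sequence of constant-magnitude impulses whose direction is a Bernoulli
  sign process: a smooth oscillation (weight $1-\omega$) mixed with
  randomness, with $\omega$ rising as drift rate falls, plus an
  evidence-tracking bias that pulls steps toward the currently favored
  side. Constant impulse size keeps the pre-decision speed exactly flat,
  so lateral complexity cannot leak into acceleration-based measures, and
  sample entropy — amplitude-invariant by design — picks up the
  structure-versus-randomness mix. This plants corr(sampleEnX, v) < 0.
- *Velocity-peak latency → threshold separation.* After the decision
  event, a ballistic segment with a beta-density velocity profile moves to
  the chosen box, its peak shortly after the decision. Since the decision
  time grows with $a$, so does the peak latency:
  corr(timeToPeakVel, a) > 0. The ballistic duration itself is an
  independent log-normal participant trait, which keeps the latency from
  collapsing onto total RT (the |r| ≥ 0.9 screen would then condense the
  measure into RT).
- *Peak speed and jerkiness → non-decision time.* The ballistic profile's
  sharpness falls with $t_0$ (fast responders flick, slow responders
  glide), so peak speed falls with $t_0$: corr(maxVel, t0) < 0. Speed
  jitter is multiplicative noise smoothed over a window that shrinks with
  $t_0$; white jitter flips the acceleration sign on most steps, smooth
  jitter rarely, so corr(accChanges, t0) > 0 without the count merely
  tracking trial duration.

Motor pauses freeze the cursor in geometric-length runs (at least one per
trial), grounding motorPauses and minVel. What the generator does *not*
emulate: pixel quantization, visual feedback coupling between display and
hand, learning or fatigue across trials, and any non-stationarity — so
passing tests demonstrate that the pipeline recovers known structure from
plausibly shaped data, not that real cursor data carries that structure.
Calibration of the coupling gains was done against the generator's own
retention metric (do the minimal models keep the planted measures?) and
then frozen; across repeated cohort draws the planted predictors survive
the full reduction chain in roughly 85% of draws, with the
threshold-separation race the tightest because several measures inherit
duration information once RT itself is excluded from the predictor set.

## Numerical choices and degenerate inputs

Zero-variance measure columns (for example minVel when every trial
contains a pause) are dropped before PLSR rather than propagated as NaN;
correlation screening treats them as correlating with nothing. Trials
whose trajectory starts and ends at the same point have no defined optimal
trajectory and surface as flagged missing deviation cells. Duplicate
timestamps are an error (zero-division in speeds); irregular sampling
around the nominal rate is tolerated and never resampled. PLSR folds that
lose a component to rank deficiency reuse the deepest available component
rather than failing. All stochastic stages require an explicit seed — the
package never seeds from the clock.

## Problem sizes used by the validation suite

The test suite runs the study-shaped conditions at desk scale: cohorts of
100 × 90 for planted-coupling recovery (50 draws), 40 × 90 for the
trial-reduction contrast at B = 100, 20 repetitions of 50 participants for
the fit-screen calibration at 200 synthetic sets, and 100 repetitions of
500-trial recovery for the estimator. These sizes were chosen so the whole
suite completes in well under half an hour on a single core while keeping
Monte-Carlo error small relative to the asserted margins.

## Known limitations

The measure battery is fixed at the 18 listed summary measures;
time-continuous analyses are out of scope. The likelihood ignores the
response ceiling (as does the reference fitting tool), so fits under heavy
truncation are biased and the fit-quality screen becomes conservative in
the flagging direction. The bootstrap treats the full-data parameters as
fixed ground truth, so its curves quantify stability of the cursor side
only. And the generator's couplings, while qualitatively faithful in sign,
are not calibrated to reproduce any particular dataset's correlation
magnitudes.
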
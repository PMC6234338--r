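---
title: "Engines, simulator and analysis methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Engines, simulator and analysis methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

cogbattery is a headless re-implementation of a five-task gamified
cognitive battery of the kind deployed in mobile research apps: a
four-choice vigilance task, a 2-back working-memory task, a 3x3-grid
mental-rotation task, a multiple-object-tracking task, and an
action-discovery task, together with the 5-item reduced
morningness-eveningness questionnaire (rMEQ), a synthetic cohort
simulator, and the cohort-analysis protocol used for such datasets.
This vignette documents the scoring models, the simulator's assumptions,
the numerical choices, and what the test suite does and does not
establish.

```{r setup}
library(cogbattery)
```

## The five engines and their scoring rules

All engines are pure functions of a responder callback and the state of
R's random number generator: under `set.seed()` a session replays
bit-identically. Responders are plain functions following per-engine
contracts (see each engine's help page); simulated responders may carry
two fast-path attributes, `itemwise` (the engine queries all items in
one vectorized call) and `needs_state = FALSE` (the object-tracking
engine skips motion simulation when taps cannot depend on
trajectories). The sequential and vectorized paths are
equivalence-tested.

**Vigilance (react).** Eight trials; one of four buttons turns "go"
after a uniform 2--7 s foreperiod; responses must land within a 600 ms
window. A correct press within the 100 ms grace period earns the full
per-trial maximum `s_trial`; points then decay linearly to zero at
600 ms. Premature and wrong-button responses score zero. The in-app
point scale is not publicly documented; the default `s_trial = 62.5`
(session maximum 500) was chosen so that realistic latencies
(~180--250 ms) produce session means around 400, the magnitude such
cohorts report. It is configurable.

**2-back (supersnap).** Shapes drawn i.i.d. uniformly from six symbols,
1.5 s exposure and 1.5 s inter-item delay; a tap claims that the current
shape equals the one two positions back. The session starts at 60 and
loses 6 points per false alarm or miss (floored at zero), ending when
10 matches have been presented or 10 taps have been made, whichever
comes first. The i.i.d.-uniform stream is the simplest defensible null
for the generator; it yields a 2-back match density of 1/6 from
position 3 onward.

**Mental rotation (spin).** The stimulus set is 18 patterns of filled
cells on a 3x3 grid, each with 1--3 four-connected groups and no
rotational symmetry. The historical stimulus set is not printed
anywhere we can reproduce it from, so the packaged set is a canonical
stand-in derived deterministically: enumerate all 512 grids in
lexicographic bit order, keep those with 2--6 filled cells
(operationalizing "neither trivially simple nor cluttered"), 1--3
groups, no rotational symmetry, and—one constraint the trial structure
itself forces—no axis reflection coinciding with any nonzero rotation
(otherwise a reflection foil could equal the rotated target); skip
grids rotation-equivalent to an earlier selection; stop at 18. The
fixture ships as a plain JSON list of nine-bit strings and
`derive_pattern_set()` regenerates it exactly; foil safety is
brute-force checked over all 18 x 3 rotations x 2 reflections. Each
trial rotates the target by 90/180/270 degrees and offers the rotated
target plus its vertical and horizontal reflections in shuffled order.
A session presents all 18 patterns without replacement in random order
within a 45 s budget: a trial is presented while elapsed time is under
the limit and its response counts only if it completes within it. The
in-app score uses `points_per_correct = 2.5`: reported session means
for such tasks exceed the 18-correct ceiling, so the app-side score
cannot equal the number correct; 2.5 aligns the maximum (45) with the
tracking task. `n_correct` is always reported alongside.

**Object tracking (track).** Six trials at set sizes 8, 8, 9, 9, 11, 11
(increasing order), three targets each, 3 s static preview, 5 s of
motion at 60 Hz, then up to three taps; each correctly tapped target
scores 2.5, maximum 45. Physics: per frame each ball's speed is
multiplied by a uniform factor in [0.9, 1.1] (clamped to
[0.1, 0.4] arena/s) and its heading jittered by up to ±10 degrees;
positions advance by `dt`; wall contacts reflect the position about the
boundary and point the velocity inward; overlapping pairs are separated
symmetrically along their center line with approaching normal velocity
components exchanged (equal-mass elastic collision). The
resolve-and-recheck loop iterates until no violation remains (at most
20 iterations; at these densities one or two suffice), so the
no-overlap and in-bounds invariants hold after every step — verified by
a sweep of 10^4 steps x 20 seeds. Only the qualitative behavior
("speed and direction adjusted randomly each frame, no overlap, no
escape") is externally specified; the jitter bounds and base speed
0.25 arena/s are package defaults, all configurable.

**Action discovery (hotspot).** Five attempts; each places a circular
target covering exactly 5% of the unit arena (radius `sqrt(0.05/pi)`,
analytic), with its center uniform over positions keeping it inside.
The ball covers half the target's area (radius `r/sqrt(2)`, kept as
metadata); "in target" is operationalized as ball center inside the
target circle. Feedback lags the in-target state by the 100 ms
difficulty delay. Success requires 500 ms of in-target time within a
sliding 1 s window; the phrase "500 ms of a 1-second window" is
ambiguous between cumulative and consecutive dwell, and the cumulative
reading was chosen (a consecutive reading would amount to shrinking the
window to 500 ms). Scoring: half the attempt maximum for discovery (ever
entering the target), the other half decaying linearly from attempt
onset to zero at the attempt time limit. The attempt maximum
(`a_max = 10`) and time limit (`t_limit = 15` s) are not publicly
documented and are package defaults; the decay-from-onset convention
(rather than from first entry) is the package's choice.

**Session wrapper.** `run_session()` shuffles the played games into a
fresh random order, records skipped games as absent, and attaches the
session questions: a mood rating (visual-analog slider mapped affinely
onto 1--10), and wake time plus hours slept on the first session of a
day. Demographics (age, gender, both refusable) and the rMEQ total are
echoed on session 1.

## Questionnaire scoring

The 5-item reduced morningness-eveningness questionnaire is scored by
summing the items; the standard key (item ranges 1--5, 1--4, 1--5,
1--5, 0--6) gives totals 4--25 and ships as a JSON config so an
alternative key can be swapped in without code change. Classification
uses the conventional cutoffs — definitely evening 4--7, moderately
evening 8--11, neither 12--17, moderately morning 18--21, definitely
morning 22--25 — which partition every attainable total exactly once
(checked exhaustively).

## The synthetic cohort generator

The simulator exists so the analysis pipeline can be exercised
end-to-end against known ground truth. Its defaults emulate the
qualitative structure of a large self-selected mobile cohort:

* **Ages** are 18 + Gamma(shape 1.8, scale 9), rounded, with a 7%
  spike at exactly 18 — mobile consent flows make 18 the lowest
  selectable age and real cohorts show a pile-up there. About 7.4% of
  participants decline to report age and 1.65% gender; 60% of
  reporters are female.
* **Chronotype** totals are drawn with mean 13.2, SD 4 and an age
  coupling targeting r = 0.298 (older participants more
  morning-oriented); rounding and clamping to [4, 25] attenuate the
  realized correlation by under 0.02. These defaults reproduce the
  familiar class split: roughly half "neither", a third evening types,
  the rest morning types.
* **Session counts** are 1 + negative binomial (size 1.4, mean 7)
  with the mean log-linear in age (coupling 0.18, residual noise
  SD 0.35), giving a heavy-tailed distribution with mean ~8, SD ~8 and
  corr(age, sessions) ~ 0.21 — engaged older users are a robust
  feature of such cohorts.
* **Abilities** are per-game standard normal latents. Gender effects
  are applied as ±d/2 shifts (defaults, in latent SD units: rotation
  0.39, action 0.31, vigilance 0.13, tracking 0.10, 2-back 0 — the
  male-advantage pattern reported for gamified spatial/attention
  tasks). Age applies a per-decade latent decline (strongest for the
  vigilance task). Practice follows
  `asymptote - deficit * exp(-rate * (play - 1))` with deficit 0.8 SD
  and rate 0.4 for every game except the vigilance task, whose rate
  and deficit are zero: a bare reaction-time task is learned on first
  contact and shows no practice curve. Rate 0.4 places play 10 within
  a fraction of a percent of the asymptote, matching the
  rise-then-stabilize shape expected of practice effects.
* **Response models** are deliberately minimal parametric forms — no
  behavioral model is externally specified, and these are the least
  structure that gives the analyses recoverable signal: shifted
  lognormal latencies with small premature/wrong-button rates
  (vigilance); lognormal decision latency and logistic accuracy in the
  latent skill (rotation); logistic hit and false-alarm probabilities
  (2-back); a per-target binomial tracking capacity with uniform
  guessing among untracked balls (tracking); and a lognormal search
  time followed by settling in the target (action task).
* **Mood** is AR(1) around a per-participant baseline and — by
  default — uncoupled from performance, mirroring the null
  mood-performance findings in such data; a coupling hook exists.
  Session timestamps follow a chronotype-dependent time-of-day
  preference, but performance is deliberately *not* time-of-day
  modulated by default: the time-of-day analysis is downstream future
  work, and the hook parameter is the only place it enters.

What the simulator does **not** emulate: real response-time
distributions' heavy tails and sequential dependencies, device and
platform effects, within-day session clustering, strategic or
inattentive responding, and selection effects by which improving
players keep playing (improvement here is practice only). Passing
parameter-recovery tests therefore shows the pipeline is correct and
calibrated for data of this structure — not that the behavioral models
are faithful to any particular human cohort.

## The analysis protocol

Analyses run on per-participant, per-game summaries: play count, mean
score over all plays, and the "early snapshot" (mean of plays 4--6,
defined only for participants with at least 6 plays).

* **Adherence filter:** at least 4 plays of a game, removing
  participants who played no more than a practice set.
* **Outlier trimming:** the most extreme 1% of average scores.
  "Most extreme" is direction-ambiguous, so the default removes
  `floor(n/200)` from each tail, with a median-absolute-deviation
  ranking available as a config switch; ties break by participant id
  so the selection is deterministic. Trimming marks its output and a
  second application is a no-op — recomputing the fraction on the
  already-trimmed set would remove ever more rows.
* **Gender ANCOVA:** `mean_score ~ gender + plays`, Type-II sums of
  squares, no interaction; the covariate defaults to plays *beyond* the
  adherence minimum (`n_plays - 4`), with raw coding available. Both
  the factor and the covariate are reported with F, `(1, n - 3)`
  degrees of freedom and partial eta-squared
  `SS_term / (SS_term + SS_residual)`.
* **Plays t-test:** pooled-variance two-sample t on play counts by
  gender (df `n1 + n2 - 2`), the standard confound check before the
  ANCOVA.
* **Age-stratified ANOVA:** because age and play count are themselves
  correlated, the age analysis controls plays by design instead of
  covariance: one-way ANOVA of the early snapshot across seven decade
  bins (`<20`, `20-29`, ..., `60-69`, `>70`; ages 70+ fall in the top
  bin, following the printed labels). Eta-squared is
  `SS_between / SS_total`. Standard denominator degrees of freedom
  `n - k` are computed; published reports of this design sometimes
  print an `n - 1` convention, so `df2_reported` echoes it explicitly.
* **Mood protocol:** among participants meeting the adherence cutoff,
  a group-level Pearson correlation of average mood with average
  score, plus per-participant Spearman correlations across sessions
  averaged over participants, skipping (and counting) participants
  with fewer than 3 mood-score pairs or zero variance.
* **Multiple testing:** none across games, matching the protocol being
  reproduced; p-values are reported raw.

Every statistic is verified against an independent brute-force oracle
(explicit normal equations, closed-form pooled t, covariance-formula r)
on small fixtures at 10^-8 relative tolerance.

## Problem sizes used in the verification suite

The suite verifies calibration and recovery at sizes chosen once for a
desk-scale run: type-I calibration of the gender ANCOVA from 200
simulated rotation-game cohorts of 250 participants (rejection rate
expected within 3--7% at alpha = 0.05); sign recovery and effect-size
ordering from 25 cohorts of 2,000 participants at configured gender
effects d in {0, 0.2, 0.4}; a physics sweep of 10^4 steps x 20 seeds;
and practice-curve checks on 800 simulated responders, comparing the
play-10 group mean against the play-28 asymptote within 2%. Note the
engine pipeline attenuates configured latent effects (a d = 0.2 latent
shift surfaces as roughly d = 0.14 in session scores), which is why
sign recovery is tested at cohort scale rather than on small samples.

## Known limitations

* The rotation stimulus fixture is a constraint-faithful synthetic
  stand-in, not the historical 18-pattern set; difficulty-level splits
  of that set are out of scope.
* Score scales that the app never documented publicly (vigilance
  per-trial maximum, action-task attempt maximum and time limit,
  rotation points per correct) are package defaults chosen for
  magnitude-consistency with reported cohort means, and configurable.
* The cumulative reading of the action-task dwell criterion, the
  decay-from-onset time bonus, and the center-in-circle in-target rule
  are documented interpretations of underdetermined rules.
* Rendering, audio, real-time input, notification and consent flows,
  and the normalized in-app feedback graphs are out of scope; feedback
  exists only as state traces.
* The simulator is not fitted to any real cohort's distributions, and
  the analysis suite's empirical claims are exactly those its tests
  compute — nothing more.
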
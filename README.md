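# cogbattery

Headless engines, a synthetic-cohort simulator, and the analysis
pipeline for a five-task gamified cognitive test battery of the kind
delivered through mobile research apps.

Gamified batteries trade laboratory control for scale: participants
decide which 1–2 minute games to play and how often, so the resulting
datasets have uneven play counts, steep attrition, practice effects and
self-reported demographics. cogbattery makes that whole measurement
chain reusable and testable without an app or a proprietary dataset:

* **Engines** — tick-based, scriptable implementations of the five
  tasks with exact scoring rules, each consuming a responder callback
  (a simulated player or a replayed human):
  * four-choice vigilance: 8 trials, uniform 2–7 s foreperiod, 600 ms
    response window, full points within a 100 ms grace period then a
    linear decay — premature or wrong presses score 0;
  * 2-back working memory: i.i.d. shapes from 6 symbols, score
    60 − 6 × (false alarms + misses), ending at 10 matches presented
    or 10 taps made;
  * mental rotation: 18 3×3-grid patterns without replacement in 45 s,
    target rotated 90/180/270°, foils are the vertical and horizontal
    reflections;
  * multiple object tracking: 6 trials at set sizes 8/8/9/9/11/11,
    3 targets, collision-safe jittered motion, 2.5 points per correctly
    tapped ball (max 45);
  * action discovery: unmarked circular target covering 5% of the
    arena, 100 ms delayed feedback, success = 500 ms in-target within a
    sliding 1 s window, half points for discovery plus a linear time
    bonus.
* **rMEQ** — scoring of the 5-item reduced morningness–eveningness
  questionnaire (totals 4–25) and the standard five-class chronotype
  partition (definitely/moderately evening, neither,
  moderately/definitely morning).
* **Simulator** — cohorts with age floored at 18 (plus a reporting
  spike there), refusable demographics, age-correlated chronotype
  (r ≈ 0.3) and engagement (r ≈ 0.2), heavy-tailed session counts,
  per-game latent abilities with gender/age effects, and
  rising-then-stable practice curves (flat for the vigilance task).
* **Analysis** — the cohort protocol: ≥4-plays adherence filter,
  extreme-1% trimming, gender ANCOVA (`score ~ gender + plays beyond
  4`, Type-II SS, partial η²), plays-by-gender t-tests, decade-binned
  age ANOVA on the mean of plays 4–6 (η² = SS_between/SS_total),
  correlations, the mood–performance protocol, and practice curves.
* **I/O and CLI** — a versioned JSONL/CSV session-record schema and a
  thin `Rscript` front end (`inst/cli/cogbattery`) with `simulate`,
  `analyze`, `report` and `selfcheck` subcommands.

## Worked example

```r
library(cogbattery)

cfg <- sim_config(n_participants = 500, seed = 2026)
records <- simulate_dataset(cfg)        # 3978 session records

s    <- summarize_by_participant(records, "spin")
kept <- trim_outliers(adherence_filter(s))   # 327 participants kept

gender_ancova(kept)
#>     term statistic  value df1 df2 p_value       effect effect_value   n
#> 1 gender         F 4.0533   1 320 0.04492 partial_eta2     0.012508 323
#> 2  plays         F 0.4716   1 320 0.49277 partial_eta2     0.001471 323
```

The rotation game's configured male–female latent effect surfaces as a
significant gender F with a small partial η², while the plays covariate
is included to absorb engagement differences (here nonsignificant).
The confound check and the age analyses:

```r
plays_t_test(kept)            # t(321) = 0.299, p = .76 - plays not confounded
age_stratified_anova(kept)    # F(6, 216) = 2.19, p = .045, eta2 = .057
ok <- !is.na(kept$age) & !is.na(kept$meq_total)
pearson_r(kept$age[ok], kept$meq_total[ok])
#> r = 0.352, n = 292, p < .001   (older participants more morning-typed)
```

Practice curves rise then stabilize (the simulator's learning-curve
ground truth), and chronotype classes split roughly half "neither",
a third evening types:

```r
practice_curve(records, "spin")   # mean 18.7 at play 1 -> ~23 by play 6
meq_summary(kept)                 # 49% neither, 35% evening, 16% morning
```

Deterministic engine checks from the shell:

```sh
Rscript inst/cli/cogbattery selfcheck
```

## Scope

The package is the measurement and analysis machinery only: no
rendering, audio, notifications, consent flows or in-app feedback
graphs, and no time-of-day × chronotype performance modeling (the
simulator deliberately leaves performance independent of time of day,
with a hook parameter for future work). See the methods vignette
(`vignettes/cogbattery-methods.Rmd`) for models, assumptions, numerical
choices and limitations.
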
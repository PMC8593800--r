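---
title: "A headless serious game for midline-crossing screening: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A headless serious game for midline-crossing screening: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(midcross)
```

## The clinical problem

Crossing the body's midline — spontaneously reaching an arm across to the
contralateral side — is a developmental milestone expected by about age five.
Children with midline-crossing inhibition *can* physically make the movement
but avoid it: they swap hands mid-task, rotate the trunk instead of reaching
across, and lose visual tracking around the centre. Screening is
traditionally observational and therefore subjective.

`midcross` implements, headlessly and reproducibly, a telehealth screening
game built around that deficit. The child controls a hat via a slider; balls
fall from the top of a screen whose x-axis runs from −7.5 to +7.5 game units
with the body midline at 0. The hat starts on the side *opposite* the
dominant hand (right-handed child: left edge), so a point — catch the ball,
then return the hat all the way home — always requires a full midline cross.
Sessions last exactly 2 minutes, short enough for a young child's attention
span.

## Stage difficulty rules

Four stages grade the challenge; the therapist sets the parameters
("grading" in occupational-therapy terms). With score $S$ (balls caught
*and returned* so far):

| Stage | Role | Spawn position | Fall speed |
|---|---|---|---|
| 1 | assessment | $X_0 + I \cdot S$ (clipped to the playfield) | constant |
| 2 | intervention | $X_0 + U(-DV, +DV)$ | constant |
| 3 | intervention | $X_0$ | $Sp_0 + Is_p \cdot S$ |
| 4 | maintenance | $U(-7.5, +7.5)$ | constant |

$X_0$ is the starting distance, $I$ the incremental distance per point, $DV$
the distance variance (half-width of the uniform jitter; start 1.5 and
variance 0.5 give spawns between 1 and 2), $Sp_0$ and $Is_p$ the initial and
incremental fall speed. Because spawning depends on the score, a missed ball
leaves the stage-1 and stage-3 positions unchanged — the child retries the
same distance until it is mastered. All rules are defined in the
right-handed frame; left-handed play is the exact mirror image (every x
negated), implemented by simulating canonically and negating the output.

Package defaults (`default_stage_config()`): stage 1 $X_0 = 1, I = 0.5$;
stage 2 $X_0 = 1.5, DV = 0.5$; stage 3 $X_0 = 1.5, Sp_0 = 2, Is_p = 0.1$;
constant fall speed 2 units/s; 120 s.

## Engine mechanics and numerical choices

The published game rules fix the difficulty equations but not the engine's
mechanical constants; the package chooses them once, documents them here,
and exposes them in `engine_params()`:

* **Fall geometry.** Balls spawn `y_top = 10` units above the hat line. At
  the default speed 2 that is a 5 s fall, so an engaged player completes
  roughly 16–18 ball cycles in 120 s — consistent with score-card thresholds
  of >14 catches and a sub-7.5 s mean inter-ball tempo.
* **Catch window.** A ball is caught iff the hat centre is within 0.5 units
  of the ball when it reaches the hat line (`catch_half_width`).
* **Return detection.** The hat counts as home within 0.25 units of the
  home edge (`return_tol`).
* **Serial loop, post-miss pause.** One ball is in play at a time. After a
  scored return the next ball spawns immediately; after a miss the next
  spawns after a 4 s inter-trial pause (`miss_respawn_pause_s`) during which
  the child withdraws the hat to the home side. The pause is a deliberate
  design choice: without it, a child who misses everything completes 5 s
  cycles and the "average time between balls < 7.5 s" criterion would
  *reward* total disengagement; with it, session tempo reflects engagement,
  and every ball is attempted as a fresh midline cross from the home edge.
* **Time base.** Hat motion is piecewise linear (constant speed toward a
  fixed target), so each cycle has a closed-form timeline; all event times
  are rounded up to a 0.02 s grid (`dt`). This is numerically identical to a
  0.02 s fixed-step simulation of the same trajectories, exactly
  reproducible, and fast enough for large property suites.
* **Clipping and session end.** Stage 1's unbounded recurrence clips at the
  screen edge. A ball still in the air at the 120 s whistle is abandoned
  (spawned, neither caught nor missed); a ball caught but not returned in
  time keeps its catch and earns no point.
* **Randomness.** One seeded generator per session drives spawn jitter,
  lapses and refusals; the seed is stored in the record, so any session
  replays exactly.

## The simulated players

Real gameplay data from children do not exist for this game, so the package
ships parametric players (`player_model()`, `make_profile()`) as test
instruments. The unimpaired reference child moves the hat at 6 units/s,
reacts in 0.3 s, and ignores 1% of balls (attention lapses). The impaired
profile adds two monotone deficit mechanisms, both scaled linearly by a
severity in [0, 1]:

* **hesitation**: +3.0 s (at severity 1) of delay whenever the reach crosses
  the midline — the child gets to distant contralateral balls too late;
* **refusal**: with probability $\min(1,\; 0.15 \cdot d)$ for a ball $d$
  units past the midline (at severity 1), the child refuses to cross and
  stops at the midline — the "uses the ipsilateral hand for the ipsilateral
  side" avoidance pattern.

The refusal form is the simplest monotone model that produces the observed
avoidance phenotype; it is a modelling choice, configurable, with no claim
of clinical fidelity. The numeric defaults were calibrated **once** with the
shipped script (`inst/scripts/calibrate_profiles.R`, 200 sessions per arm)
so the score-card thresholds separate the populations — unimpaired players
pass all three gameplay criteria in ≥95% of stage-1 sessions, severity-1
impaired players fail all three in ≥90% — and then frozen as regression
tests. The unimpaired lapse rate was set to 0.01 because at 0.02 the chance
of two lapses in one session (~4%) erodes the unimpaired pass-rate anchor
below its margin.

What the generator emulates: score separation, miss-versus-distance
gradients, hesitation-driven tempo loss, handedness mirroring. What it does
not: fatigue and learning within a session, trunk-rotation compensation
(visible to a caretaker, invisible in slider telemetry), motor noise in the
hat trajectory, and age effects. Passing tests therefore validate the
*machinery* — engine, score card, formats, dashboards — not any clinical
claim about real children, which the underlying system itself defers to
future clinical studies.

## The score card

Eight binary criteria per stage; a total of **≥ 4 points indicates no
midline-crossing pathology**, below that the child needs further assessment.
Criteria 1–3 come from gameplay telemetry, with the published thresholds
read as strict inequalities (the boundary earns no point):

1. balls caught > 14;
2. balls missed < 4;
3. average time between balls < 7.5 s (interpreted as the mean gap between
   successive spawn times, in seconds, per 120 s session);

Criterion 4 — "no pattern" of misses in the stage's difficulty variable
(spawn distance for stages 1, 2, 4; fall speed for stage 3) — is
observational in the source protocol, so by default it is read from the
notes page. Its content is nevertheless computable, and
`detect_distance_pattern()` offers an opt-in automated version: the
point-biserial correlation between per-ball challenge and the miss
indicator, with a one-sided permutation p-value
$(1 + \#\{r_{perm} \ge r_{obs}\})/(B+1)$; a pattern is declared at $r > 0$
and $p < 0.05$. It is a single pre-specified test per session (no
multiplicity correction); degenerate sessions (all caught, all missed,
constant challenge) return "no pattern, p = 1" — absence of evidence is
deliberately scored in the child's favour. Criteria 5–8 come from the
caretaker's notes page (instructions followed; visual focus maintained; no
gross body adjustments; no verbal cues). Every criterion's provenance
(gameplay / observation / automated) is recorded on the card; missing notes
zero the observational criteria and flag the card incomplete rather than
failing.

## Wire formats and dashboards

Sessions, notes and score cards travel as JSON with an embedded schema
version (current 1.1; 1.0 files, which stored one fall speed per session,
are migrated on read). Readers validate every structural invariant — event
ordering, playfield bounds, score monotonicity, count consistency — and
reject violations naming the field. Identifiers are pseudonymous opaque
strings; timestamps ISO-8601 UTC; no personal data is representable in the
schema. Flat exports (score cards, dashboard tables) are UTF-8 comma CSV
with a header row. The caretaker guidance script ships as static
documentation (`inst/guidance/`), not data.

Dashboard metrics are deliberately simple, documented operationalizations
of what a therapist-facing dashboard displays: per-session counts, catch
rate, tempo, the furthest contralateral distance at which a ball was caught
and returned, a miss-by-distance profile over six equal-width bins (the
panel on which "missed more as distance increased" is visible), and a
per-stage ordinary-least-squares trend of score-card total against session
ordinal (defined only with ≥2 sessions of a stage).

## Problem sizes and verification

The test suite verifies the worked spawn-rule examples and the playfield
bounds on 10⁴ draws; the score-card machinery by exhaustive enumeration of
all 256 criterion vectors; engine timelines against straight-line
recomputations of the stage recurrences; mirroring, determinism and
serialization round-trips on 500 randomized instances each; and the
population properties on 200 sessions per arm with the permutation test's
type-I error checked on simulated null sessions. Those sizes keep the full
suite around a minute on one CPU while leaving binomial noise well inside
the asserted margins.

## Known limitations

* The player profiles are synthetic by necessity; no parameter was fit to
  child data.
* Criterion thresholds are global — the source protocol itself notes that
  per-age-group standardization is future work, so no norm tables are
  provided.
* Multi-session clinical judgement is not modelled; the dashboard reports
  descriptive trends only.
* The physical input device, real-time graphics and any web backend are out
  of scope: this package is the measurement core, not the product.
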
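# midcross

A headless, deterministic R implementation of a telehealth **serious game
for screening midline-crossing difficulty in children**, for occupational
therapists, rehabilitation-gaming researchers and engineers who need the
game's measurement core — engine, score card, wire formats, dashboards —
without graphics or hardware.

Crossing the body's midline (spontaneously reaching an arm across to the
opposite side) is a developmental milestone; children with midline-crossing
inhibition avoid it even though they are physically able. The game makes
that measurable: a hat controlled by the child starts on the screen side
*opposite* the dominant hand, balls fall from the top of a playfield
spanning x ∈ [−7.5, +7.5] (midline at 0), and a point requires catching the
ball **and** returning the hat home — a full midline cross per point.
Sessions last exactly 2 minutes.

Four stages grade difficulty via the spawn/speed rules (score *S* = balls
caught and returned):

| Stage | Spawn position          | Fall speed          |
|-------|-------------------------|---------------------|
| 1     | X₀ + I·S                | constant            |
| 2     | X₀ + U(−DV, +DV)        | constant            |
| 3     | X₀                      | Sp₀ + Isₚ·S         |
| 4     | U(−7.5, +7.5)           | constant            |

An 8-criterion score card screens each session — three gameplay criteria
(caught > 14, missed < 4, mean inter-ball time < 7.5 s, all strict), a
miss-versus-distance "no pattern" criterion (observational by default, with
an opt-in permutation test), and four observational criteria from a
caretaker notes page. **Total ≥ 4 ⇒ no pathology indicated**; otherwise the
child should be assessed further.

Because no public gameplay data from children exist, the package also ships
parametric simulated players — an unimpaired reference child and an
impaired profile whose crossing hesitation and refusal probability scale
with a severity parameter — as calibrated test instruments for the whole
pipeline.

## Worked example

Simulate a severity-1 impaired child on the stage-1 assessment, score the
session against the caretaker's notes, and summarise for the dashboard:

```r
library(midcross)

cfg  <- default_stage_config(1)            # X0 = 1, I = 0.5, 120 s
sess <- run_session(cfg, handedness = "right",
                    player = make_profile("impaired", severity = 1),
                    seed = 42)
sess
#> <midcross session s42-stage1> child child-01, stage 1, right-handed, seed 42
#>   15 balls: 5 caught, 10 missed; final score 5 in 120 s
```

The child catches the first balls just past the midline, then stalls at
2.5 units — the score (and with it the spawn distance) stops advancing:

```r
head(sess$events, 4)
#>   index spawn_x spawn_time_s fall_speed outcome catch_time_s return_time_s score_after
#> 1     1     1.0         0.00          2  caught         5.00          6.38           1
#> 2     2     1.5         6.38          2  caught        11.38         12.84           2
#> 3     3     2.0        12.84          2  caught        17.84         19.40           3
#> 4     4     2.5        19.40          2  missed           NA            NA           3

card <- score_card(extract_stats(sess),
                   synthetic_notes(sess, "unfavorable"))
card
#> <midcross score card> session s42-stage1, stage 1
#>   1. [ ] balls caught > 14                (gameplay)
#>   2. [ ] balls missed < 4                 (gameplay)
#>   3. [ ] avg time between balls < 7.5 s   (gameplay)
#>   4. [ ] no miss-distance pattern         (observation)
#>   ...
#>   total 0/8 -> further_assessment_needed
```

Only 5 of 15 balls were caught, the session tempo dragged to 8.1 s per
ball, and the notes report the avoidance behaviours, so the card totals
0/8: the screen flags the child for further assessment. The dashboard
summary shows the telltale spatial signature — misses concentrated in the
far contralateral bins:

```r
summarize_session(sess, card)$miss_by_distance
#>   bin_lo bin_hi attempts misses
#> 4    0.0    2.5        3      0
#> 5    2.5    5.0       12     10
```

An unimpaired player on the same stage (`make_profile("unimpaired")`)
typically catches 16–17 balls at a sub-7.1 s tempo and, with favourable
notes, scores 7–8/8.

Batch use mirrors the same pipeline on files (`cmd_simulate()`,
`cmd_score()`, `cmd_dashboard()`), or from a shell via the thin front end
`inst/cli/midcross` — sessions, notes and score cards travel as versioned,
validated JSON (schemas in `inst/schemas/`).

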
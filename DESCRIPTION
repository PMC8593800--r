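Package: midcross
Title: Headless Serious-Game Engine and Score Card for Midline-Crossing Screening
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A headless, deterministic implementation of a four-stage
    ball-catching serious game used in paediatric occupational therapy to
    screen for and treat difficulty crossing the body's midline. Provides the
    stage difficulty equations (incremental, jittered, speed-graded and fully
    random spawning), seedable session simulation driven by parametric child
    player models (including a midline-crossing-impaired profile), the
    8-criterion screening score card with its 4-point pathology threshold, a
    permutation test for miss-versus-distance patterns, versioned JSON/CSV
    telemetry formats for telehealth exchange, and therapist-facing dashboard
    aggregates (per-session summaries, miss-by-distance profiles, cross-session
    progress trends).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    ggplot2,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
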
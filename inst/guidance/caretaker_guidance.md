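# Caretaker guidance script

Read this before the child plays. It tells you how to set up a session and
what to watch for, so that the notes page you complete afterwards is an
accurate record for the occupational therapist.

## Before the game

1. Seat or stand the child squarely in front of the screen, centred on it.
   The slider should sit directly in front of the child's body midline.
2. Select the stage and the settings the therapist prescribed. Do not change
   the difficulty values mid-session.
3. Explain the goal once, simply: "Catch the ball in the hat, then bring the
   hat all the way back to its side of the screen to score a point."
4. The game lasts two minutes. Let the child play without help unless they
   stop entirely.

## What to observe while they play

Watch the child, not the screen. The therapist needs to know:

- **Following instructions** — did the child keep catching and returning,
  or drift from the task?
- **Eye movements** — did the child track the ball across the screen, or
  lose it (blinking, refocusing, looking away) around the middle?
- **Body movement** — did the child rotate their trunk, lean their whole
  body, or swap hands instead of reaching across the middle of their body?
- **Verbal cues** — did you have to prompt the child to reach across or to
  bring the hat back?
- **Misses** — did the child seem to miss more as the balls fell further
  toward the far side?

## After the game

Complete every item on the notes page while the session is fresh. If you
could not judge an item, leave it blank rather than guessing — a blank is
flagged for the therapist, a guess is not. Use the free-text box for
anything unusual (frustration, fatigue, distractions in the room).
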
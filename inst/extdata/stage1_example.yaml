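# Example run configuration: stage 1 assessment at the default grading.
stage_id: 1
x0: 1.0          # starting distance (game units right of the midline)
incr_dist: 0.5   # distance added per point earned
constant_speed: 2 # fall speed, game units/second
duration_s: 120   # fixed two-minute session
handedness: right
seed: 1
profile: unimpaired
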
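sampling:
  fs: 64.0
  units: rad/s
  roll_axis: z
  roll_sign: 1.0
  max_gap_s: 0.5
filter:
  base_order: 2.0
  fc_decision: 0.5
  fc_fine: 3.0
labeling:
  min_switch_rate: 0.2
  min_gap: 0.3
  max_gap: 5.0
  low_rate_threshold: 0.1
  theta1: 0.05
  theta2: 1.0
fine_tune:
  p: 0.6
direction_convention: opening
evaluation:
  matching: greedy
  default_turn_duration: 2.0
simulator:
  seed: 1.0
  fs: 64.0
  segments:
  - style: carved_short
    n_turns: 16.0
    turn_duration: 1.04
    turn_duration_sd: 0.41
    edging_amplitude: 1.5
    edging_amplitude_sd: 0.3
    duration: 10.0
  - style: stop
    n_turns: 10.0
    turn_duration: 0.0
    turn_duration_sd: 0.0
    edging_amplitude: 0.0
    edging_amplitude_sd: 0.0
    duration: 10.0
  - style: carved_long
    n_turns: 9.0
    turn_duration: 2.97
    turn_duration_sd: 0.43
    edging_amplitude: 1.5
    edging_amplitude_sd: 0.3
    duration: 10.0
  noise_sd: 0.02
  saddle_probability: 0.15
  saddle_amplitude: 0.25
  saddle_period: 2.0
  stop_oscillation_amplitude: 0.04
  leg_asymmetry: 0.1
  edge_change_halfwidth: 0.8
  bumpy_noise_amplitude: 0.35
  inter_segment_gap: 2.0
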
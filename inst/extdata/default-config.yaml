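# Default pipeline configuration: 4 N target at 500 Hz recordings,
# 3-SD onset/offset bands, distance/volume correction exponents 1,
# composite-edge reporting at |weight| >= 0.4 (top 6), VIF warning at 10.
grip:
  baseline_window_s: 0.5
  threshold_sd: 3
  sustain_s: 0.02
  sd_floor_N: 0.001
  transient_s: 0.5
  max_latency_s: 5
  target_N: 4
  angle_floor_N: 0.1
  combine: mean
alpha: 1
beta: 1
first_args: {}
second_args: {}
edge_threshold: 0.4
top_n: 6
vif_warn: 10
seed: 1
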
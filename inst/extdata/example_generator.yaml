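# Example synthetic-session configuration for the CLI:
#   Rscript inst/cli/stimtune.R simulate --config example_generator.yaml --out session/ --seed 7
n_trials_per_target: 10
g0: 0.0
g1: 1.0
s: 0.3
isi_ms: 197
sampling_rate_hz: 2000
muscles:
  name: [ECR, FCR]
  pd_deg: [0, 180]
  b0: [20, 20]
  d: [0.5, 0.5]
  pull_x: [1, -1]
  pull_y: [0, 0]
  torque_gain: [0.01, 0.01]
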
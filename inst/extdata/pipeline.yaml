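out: pipeline_out
synth:
  drift: logistic
  r: 0.3
  K: 60
  process_noise: 2
  obs_noise: 2
  n_plots: 600
  mat_range: [-1, 1]
bins: {low: -1, high: 1, width: 2}
trend: {min_n: 50}
noise: {min_n: 10}
sim: {steps: 200}
seeds: {synthesize: 11, simulate: 12, observation: 13}
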
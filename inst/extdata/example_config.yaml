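# Example run configuration. Omitted keys fall back to the published
# operating point (learner, protocol) or package defaults (everything else).
plant: upper_limb_analog
fcm: ml
ml_sign: narrative   # stretch-activated slope; "as_printed" also available
layout: tiled
seed: 0
out_dir: out
learner:
  alpha_v: 0.3
  alpha_a: 0.11
  tau: 0.05
  kappa: 0.05
  c: 0.01
  sigma_r: 100.0
protocol:
  episode_length: 2.0
  dt: 0.01
  n_trials: 300
  report_trials: [1, 2, 3, 20, 300]
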
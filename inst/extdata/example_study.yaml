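# Example simulation config for `linetrend simulate --config` — a list of
# sim_config() argument sets, one per cell.
- m: 5
  n_per_group: 10
  structure: ind
- m: 5
  n_per_group: 10
  structure: ar1
- m: 5
  n_per_group: 10
  beta: [2.0, 0.35, 0.040, 0.0]
  structure: ind
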
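# Desk-scale example configuration for run_pipeline() / load_config().
master_seed: 1
generator:
  n_municipalities: 200
  master_seed: 20301
effects:
  duration_lag: 4
  gamma: -0.022
scenarios:
  decline_severity: 1.0
  mmp_termination_year: 2019
simulation:
  n_draws: 200
  sample_effects: true
  sample_baseline: true
  effect_scale: log
  strata: [acsc_total]
calibration:
  poverty_path: default
  undernotification: 1.0
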
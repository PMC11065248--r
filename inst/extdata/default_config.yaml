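# Default pipeline configuration.
# All randomness derives from `seed`; per-stage substreams are spawned from
# it so stages can be rerun in isolation reproducibly.
seed: 1
population:
  size: 4576
  lab_observed_fraction: 0.4235577    # 1938 / 4576
  imputation_chains: 5
  overrides: ~                        # optional population_spec() arguments
simulation:
  horizon_years: 10
  population_size: 10000
  discount_rate: 0.03
  replicates: 1
calibration:
  tolerance: 0.02
interventions:
  who_ids: ["1.4", "2.11", "2.13", "3.1", "3.2", "6.2", "6.3", "6.4", "7.3"]
  reach: 0.64
  ramp: linear_from_start
psa:
  enabled: no
  n_draws: 1000
output_dir: ncdsim-output
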
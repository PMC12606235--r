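# Demonstration run: 12 bats from 2 sites, 200 calls per recording session.
# Unspecified settings keep the package defaults (see default_config()).
seed: 42
out_dir: vc-demo
population:
  n_bats: 12
  n_sites: 2
  p_captive: 0.75
  calls_per_session: 200
convergence:
  delta_cohouse: 0.25
  delta_bond: 0.15
models:
  run: [1, 2, 3]
convergence_test:
  n_perm: 1000
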
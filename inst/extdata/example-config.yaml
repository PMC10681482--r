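# Example silvigen run configuration
stand:
  width: 105
  height: 105
  pixel_size: 15
  site_index: 20
  density: 2800
  age: 25
genetics:
  variation: true
  n_qtl: 50
  va: 0.0042
  h2: 0.3
scenario:
  name: U-long
  n_cycles: 4
disturbance:
  kind: none
rng:
  setup_seed: 11
  inventory_seed: 2
  dynamics_seed: 3
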
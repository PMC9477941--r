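# example run configuration: baseline single-vessel afterload, 2 coupled beats
network:
  fixture: single_vessel
  args:
    length: 0.126
    E: 250000
scheme:
  dt1D_s: 0.0001
  dt3D_s: 0.001
cavity:
  type: sphere
  period_s: 1.231
  preload_Pa: 1333.22
run:
  init_cycles: 20
  beats: 2
  output_dir: cardiowave_out
  seed: 1
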
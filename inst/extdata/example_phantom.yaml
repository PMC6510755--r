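# Example phantom specification (see ?read_phantom_config)
demographics:
  sex: male
  age: 63
  weight: 71
scanner: scanner2
seed: 7
signal_strengths:
  pelvis_mean: 0.05
body_length_mm: 1000
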
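# Default pipeline configuration: simulate a study-scale cohort and run
# every analysis stage with the documented defaults.
kappa_weighting: linear
selection_rule: baseline
alpha: 0.05
m: 66
seed: 1
cutoffs:
  ab: 0.10
  ptau: 72.0
kde:
  bandwidth_rule: scott
  min_class_size: 5
  grid_n: 512
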
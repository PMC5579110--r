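# Stochastic Cahn-Hilliard-Cook on the dumbbell, constant mobility,
# noise intensity 1e-5.
shape: dumbbell
grid:
  "N": 129
  lower: -2.25
  upper: 2.25
t_end: 10.0
params:
  Pe: 1.0
  Cn: 0.015
  sigma: 1.0e-5
  mobility_kind: constant
  mean_concentration: 0.3
  perturbation_amplitude: 0.01
output:
  stride: 50
fit:
  window: [0.1, 10.0]
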
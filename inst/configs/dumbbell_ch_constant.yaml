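# Deterministic Cahn-Hilliard on the dumbbell (spheres of radius 0.75 at
# (+-1.125, 0, 0) joined by a cylinder of radius 0.375), constant mobility.
# The deterministic dumbbell has two growth regimes; fit windows
# [0.02, 0.2] (early) and [1, 10] (late) are applied in analysis.
shape: dumbbell
grid:
  "N": 129
  lower: -2.25
  upper: 2.25
t_end: 10.0
params:
  Pe: 1.0
  Cn: 0.015
  sigma: 0.0
  mobility_kind: constant
  mean_concentration: 0.3
  perturbation_amplitude: 0.01
output:
  stride: 50
fit:
  window: [1.0, 10.0]
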
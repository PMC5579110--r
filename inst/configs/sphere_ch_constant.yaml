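# Deterministic Cahn-Hilliard on the unit sphere, constant mobility.
# Full production scale: 129^3 grid, integrated to t = 10.
# Intended use: 64-realization ensembles via
#   chcsurf ensemble --config sphere_ch_constant.yaml --n 64 --seed 1 --out out/
shape: sphere
grid:
  "N": 129
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
  window: [0.1, 10.0]
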
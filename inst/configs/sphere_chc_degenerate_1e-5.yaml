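# Stochastic Cahn-Hilliard-Cook on the unit sphere, degenerate mobility,
# noise intensity 1e-5 (the fastest-coarsening study case).
# The growth-rate fit window ends at t = 0.8 because this configuration
# reaches the slow late-stage regime sooner.
shape: sphere
grid:
  "N": 129
t_end: 10.0
params:
  Pe: 1.0
  Cn: 0.015
  sigma: 1.0e-5
  mobility_kind: degenerate
  mean_concentration: 0.3
  perturbation_amplitude: 0.01
output:
  stride: 50
fit:
  window: [0.1, 0.8]
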
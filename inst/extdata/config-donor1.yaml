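# Example run configuration: donor-1 reduced-variant simulation.
# Units: volumes ml, concentrations pmol/ml, time min; kappa values uL/min.
variant: reduced
geometry:
  V_m: 2.0
  n_cells: 1500000
  cell_diameter_um: 30
  initial_AS_m: 10000
parameters:
  ugt.rmax: 957
optimizer:
  mu: 8
  lambda: 4
  budget: 4000
  seeds: [1, 2, 3, 4, 5]
identifiability:
  rel_error: 100
  corr: 0.95
population:
  AS0: 50
  window: [0, 1200]
  n: 150
seed: 1
output_dir: results
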
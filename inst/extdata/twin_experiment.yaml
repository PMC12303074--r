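# Reduced-scale twin experiment: 20 mm domain, three sound-speed inclusions,
# four initial-pressure datasets, two-level multigrid reconstruction.
phantom:
  variant: three_inclusion
  n_datasets: 4
data_grid:
  n_interior: 64
  dx_um: 312.5
  n_sensor_margin: 4
  n_pml: 8
  dt_ns: 80
  nt: 250
levels:
  - {n_interior: 32, dx_um: 625.0,    n_sensor_margin: 2, n_pml: 6, dt_ns: 170, nt: 118}
  - {n_interior: 48, dx_um: 416.6667, n_sensor_margin: 3, n_pml: 7, dt_ns: 115, nt: 174}
optimizer:
  - {max_iter: 30, tol: 1.0e-4, memory: 20}
  - {max_iter: 25, tol: 1.0e-4, memory: 20}
sensor:
  count: 100
  inset_mm: 0.2
noise_level: 0.01
prior:
  sigma_p0: 2.5
  mean_p0: 5
  sigma_c: 37.5
  mean_c: 1505
  tau_mm: 1.5
bounds:
  c_lower: 1300
  c_upper: 1800
seed: 1
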
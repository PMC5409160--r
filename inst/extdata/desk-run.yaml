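# Desk-scale run configuration: 12 kPa spherical lesion in a 3 kPa
# background, reference excitation 1, ten seeded 25-dB noise realizations.
phantom:
  background: {E: 3, rho: 1, nu: 0.495}
  lesion: {E: 12, rho: 1, nu: 0.495}
  lesion_center: [5, 0, 21]
  lesion_radius: 2.5
excitation:
  A: 10
  sigma_x: 0.21
  sigma_y: 0.21
  sigma_z: 4.25
  z0: 21
  t_on: 0.08
grid:
  xlim: [0, 10]
  ylim: [-3, 3]
  zlim: [14, 28]
  spacing: 0.2
  prf_khz: 10
  duration_ms: 12
noise:
  snr_db: 25
  seeds: [0, 1, 2, 3, 4, 5, 6, 7, 8, 9]
filters:
  - {dim: 0}
  - {dim: 2, q: 2, boundary_value: 0.5}
  - {dim: 3, q: 2, boundary_value: 0.5}
  - {dim: 4, q: 2, boundary_value: 0.5}
estimator:
  p: 3
  w: 5
  working_prf_khz: 50
  median_mm: 0.5
  mode: image2d
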
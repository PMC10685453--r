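# Desk-scale demo: two-CV model membrane landscape, full pipeline
# (biased runs -> surfaces -> MFEP -> protomer combination -> D(z) -> P).
# Identical to default_config(); edit and rerun to explore.
seed: 1
outdir: memperm-run
thermo:
  temperature: 310.0
landscape:
  dimensionality: 2
  interfacial_min_depth: 12.0
  core_barrier_height: 5.0
  interfacial_min_position: 5.0
  widths:
    well: 2.0
    core: 2.5
    coupling: 4.0
  coupling_strength: 10.0
  z_max: 12.0
diffusion:
  form: constant
  D_bulk: 0.5
  D_core: 0.5
  transition_width: 8.0
metad:
  w0: 1.2
  sigma: 1.0
  pace: 0.5
  bias_factor: 15.0
  grid_spacing: 0.1
run:
  dt: 0.01
  n_steps: 400000
  stride: 10
fes:
  bin_width: 1.0
  burn_in: 0.1111111111111111
  n_blocks: 3
  bulk_cut: 9.5
mfep:
  n_images: 32
  tol: 1.0
  max_iter: 3000
protomer:
  enabled: true
  pKa: 10.4
  pH: 7.0
  core_penalty: 28.0
  core_width: 3.0
  bias_factor_charged: 25.0
permeability:
  window_centers: [-10.0, -7.5, -5.0, -2.5, 0.0, 2.5, 5.0, 7.5, 10.0]
  window_k: 10.0
  window_steps: 200000
  window_stride: 1
  bounds: 11.0
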
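# Bundled demo: three synthetic conditions emulating a nondisease control
# (long, homogeneous myotubes), a disease model (shorter, heterogeneous),
# and a treated intermediate. Scaled to 700x700 px / ~160 cells per well
# so the full pipeline runs in well under a minute; the well acceptance
# floor is lowered accordingly (a 700x700 field holds fewer cells than
# the full 4 mm^2 acquisition).
seed: 42
calibration: 2.0
synth:
  image_shape: [700, 700]
  n_cells: 160
  pixel_size: 2.0
  noise_sd: 4
  background_gradient_amplitude: 20
  halo_strength: 30
  halo_width_px: 1
  texture_strength: 25
  body_contrast: 40
  min_gap_px: 12
conditions:
  - name: AR-24Q+DHT
    n_wells: 3
    synth: {length_mean: 120, length_sd: 22, width_mean: 18, width_sd: 3}
  - name: AR-97Q+DHT
    n_wells: 3
    synth: {length_mean: 78, length_sd: 38, width_mean: 13, width_sd: 6}
  - name: AR-97Q+DHT+PG0.1
    n_wells: 3
    synth: {length_mean: 102, length_sd: 28, width_mean: 16, width_sd: 4}
profiling:
  sample_size: 200
  n_bootstrap: 10
  min_cells_per_well: 100
  max_cells_per_well: 5000
segmentation:
  background_kernel_px: 151
  texture_window_px: 5
  min_object_area_px: 80
  closing_radius_px: 2
analyze:
  umap: false
  heatmap: true
output:
  write_images: false
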
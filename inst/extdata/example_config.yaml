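# Example pipeline configuration overriding a few defaults; any key left
# out keeps its documented default (see default_config()).  Unknown keys
# are rejected at load.
seed: 42
phantom:
  shape: [48, 48, 48]
  voxel_size_mm: 2.5
  field_amplitude_hz: 50
  field_smoothness_vox: 8
  n_hotspots: 2
network:
  levels: 2
  base_channels: 8
training:
  epochs: 20
  folds: 5
field:
  lambda: 0.01
evaluate:
  mi_bins: 64
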
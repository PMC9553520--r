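# Default synthetic phantom: semi-transparent tube (dyed-water lumen) and
# transparent rod in an Intralipid-gelatin background, air gap above the
# surface, low-signal noise band at depth. Dimensions in micrometres.
volume_shape: [200, 187, 16, 24]
voxel_pitch: [7.5, 7.5, 3.75]
surface_depth: 150
noise_band_start: 1200
tube:
  center_depth: 600
  center_fast: 500
  inner_diameter: 305
  outer_diameter: 762
rod:
  center_depth: 600
  center_fast: 1100
  diameter: 400
seed: 0
region_models:
  air:
    base_scale: 1.0
    shift: -0.2
  noise:
    base_scale: 1.3
    shift: -0.2
  dyed_water:
    base_scale: 2.2
    shift: -0.22
    noise_floor_scale: 0.3
    rayleigh_purity: 1.0
  transparent_solid:
    base_scale: 2.8
    shift: -0.26
    noise_floor_scale: 0.15
    depth_attenuation: 2.0e-4
    rayleigh_purity: 0.92
    decorrelation: 0.9
  semi_transparent_solid:
    base_scale: 5.0
    shift: -0.2
    noise_floor_scale: 0.15
    depth_attenuation: 1.0e-3
    rayleigh_purity: 0.85
    decorrelation: 0.9
  intralipid:
    base_scale: 8.0
    shift: -0.3
    noise_floor_scale: 0.15
    depth_attenuation: 2.0e-3
    rayleigh_purity: 0.6
    decorrelation: 0.9
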
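# Two-spot time-lapse fixture: aptamer-functionalized grating vs
# non-aptamer control. 5 frames/min for 20 min, analyte added at 5 min.
# Injected steady-state response of the aptamer spot: +20% green intensity.
image_shape: [96, 128]
line_width_nm: 300.0
frame_rate_per_min: 5.0
duration_min: 20.0
analyte_time_min: 5.0
noise_sd: 0.01
scatter_fraction: 0.08
defect_fraction: 0.10
defect_offset_sd: 0.15
defect_noise_sd: 0.05
seed: 42
optics:
  c_F: 0.02
  c_D: 0.018
  bragg_green_red_contrast: 4.0
  background_level: 0.01
  scatter_level_range: [0.2, 0.6]
spots:
- label: aptamer
  composition: "DOPC:DOTAP 60:40"
  region:
    type: rect
    row: [17, 80]
    col: [9, 56]
  median_nm: 14.0
  sigma_log: 0.3
  functionalized: true
  response:
    amplitude_A: 0.2
    rate_k_per_min: 0.5
    height_scaling: false
- label: control
  composition: "DOPC:DOTAP 60:40 (non-aptamer DNA)"
  region:
    type: rect
    row: [17, 80]
    col: [73, 120]
  median_nm: 14.0
  sigma_log: 0.3
  functionalized: false
  response:
    amplitude_A: 0.0
    rate_k_per_min: 0.5
    height_scaling: false
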
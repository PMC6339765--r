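# Default end-to-end configuration: three-material breast phantom under a
# 5 kPa, 0.1 Hz sinusoidal surface load sampled at eight instants, imaged
# with a 3.5 MHz linear array at 100 MHz sampling.
geometry:
  axial_mm: 100
  lateral_mm: 60
  elev_mm: 20
  layers:
    fat: 20
    fibroglandular: 80
  tumor_axial: [65, 75]
  tumor_lateral_mm: 10
load:
  amplitude_pa: 5000
  frequency_hz: 0.1
  sample_times_s: [7.75, 8.00, 8.25, 8.50, 8.75, 9.00, 9.25, 9.50]
probe:
  center_frequency_hz: 3500000
  sampling_frequency_hz: 100000000
  n_lines: 512
  lateral_spacing_mm: 0.08
  pitch_mm: 0.44
  kerf_mm: 0.05
  element_height_mm: 5
  focus_depth_mm: 70
  fractional_bandwidth: 0.6
  beam_sigma_mm: 0.4
  depth_origin_mm: 45
  depth_span_mm: 50
tracking:
  window_axial_mm: 1.5
  window_lines: 5
  overlap: 0.8
  search_axial: 200
  search_lateral: 6
  guided: true
schedule:
  decay: 0.9
  jitter: 0
tolerances:
  max_iterations: 50
pipeline:
  n_points: 12
  scatterer_density: 10
  ladder_step_pa: 250
  seed: 1
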
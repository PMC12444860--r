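# Reference cohort conditions: the generator defaults calibrated to the
# in vivo estimates (pulse probability 12.4%, first-pulse latency
# 10.5 +/- 12.49 min, up to 18 pulses with mode near 4, dye-leak probability
# 20.1%, 1-25 phagosomes per neutrophil, 1.5 um z step) at SNR 8.
# The ring radius of 3 px matches the rendered 1 um membrane radius at the
# 0.33 um xy pixel convention.
sim:
  shape: {x: 68, y: 68, z: 12}
  voxel_size: {x: 0.33, y: 0.33, z: 1.5}
  frame_interval_s: 30
  n_frames: 120
  n_neutrophils: 4
  phagosome_mean: 3
  phagosome_range: [1, 25]
  p_pulse: 0.124
  pulse_count_mean: 4
  pulse_count_range: [1, 18]
  latency_mean_min: 10.5
  latency_sd_min: 12.49
  p_leak: 0.201
  snr: 8
  seed: 1
ring:
  radius: 3
  half_width: 1.5
  sectors: 21
  mode: annulus
  plane: nearest
lowpass_window: 5
pulse:
  prominence_min: 0.2
  fade_threshold: 0.4
  min_separation: 3
tracking:
  channel: prey
  max_displacement: 2
  max_gap: 2
  min_track_len: 20
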
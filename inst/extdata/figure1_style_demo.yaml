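# Three-path comparison demo: conventional 1D vs SSFP-FT vs SSFP-CRAFT
# of a synthetic six-compound 19F standard.  All quantities are
# simulation inputs; amplitudes are arbitrary intensity units.
name: figure1_style_demo
seed: 42
grid:
  dwell_s: 3.2e-5        # spectral width 31.25 kHz (~66 ppm at 470.4 MHz)
  n_points: 8192
  spectrometer_mhz: 470.4
  carrier_ppm: -95
fixture:
  name: six_compound_standard
  amplitude_per_f: 1
  t1_s: 1.0
  t2_s: 0.5
noise_sigma: 2.0
conventional:
  n_scans: 4
ssfp:
  flip_deg: 60
  tp_s: 0.05             # inter-pulse time, well under T2 = 0.5 s
  acq_window_s: 0.045
  total_time_s: 900      # 15 minutes -> 18000 scans
craft:
  detection_k: 3
vertical_scale: 0.6      # reconstruction scaled down 40 % for overlay
metrics:
  signal_window_ppm: [-78.5, -75.5]    # TFA
  noise_window_ppm: [-105, -100]
  peak_threshold: 0
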
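decoder:
  p_enter: 0.1
  p_remove: 0.15
  max_features: 60.0
  decim: 25.0
  band:
  - 2.0
  - 25.0
  n_sequences: 3.0
validator:
  window: 0.2
  band:
  - 55.0
  - 77.0
  threshold: 1500.0
  pattern:
  - 1.0
  - 1.0
  - 0.0
  - 0.0
  channel_name: FCz
camera:
  hfov_deg: 57.0
  mount_height: 1.5
  depression_deg: 10.0
  max_range: 4.5
erp:
  p300_amplitude: 5.0
  p300_latency: 0.3
  p300_width: 0.06
  noise_std: 10.0
emg:
  rest_inband_std: 4.0
  clench_inband_std: 400.0
seed: 1.0
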
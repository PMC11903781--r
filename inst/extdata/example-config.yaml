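# Example sdstrip configuration (see read_config())
preprocess:
  median_window_s: 600     # 10-min moving median; 1800 for display parity
  fir_cutoff_hz: 0.5
  target_rate_hz: 1
  feature_rate_hz: 0.1
detection:
  theta_p: 0.5             # probability threshold
  theta_d: 50              # duration threshold, seconds
generator:
  n_subjects: 2
  channels_per_subject: 6
  duration_s: 7200
  fs: 256
  sd_rate_per_hour: 2.5
  seed: 17
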
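seed: 1
fidelity: feature
arms:
  nutraceuticals:
    n_subjects: 42.0
    ca_mean: 54.100000000000001
    ca_sd: 13.0
    ca_range:
    - 25.0
    - 77.0
    female_fraction: 0.738
    p_older: 0.357142857142857
    gap_mean_older: 8.82
    gap_sd_older: 7.727999999999999
    gap_mean_younger: -17.126666666666672
    gap_sd_younger: 9.24
    effect_mean_older: -6.77
    effect_mean_younger: -0.64
    effect_sd: 2.5
    followup_mean: 13.0
    followup_sd: 1.13
    followup_range:
    - 6.0
    - 18.0
    symptom_rate_pre: 0.333
    symptom_rate_post: 0.047
  lifestyle:
    n_subjects: 47.0
    ca_mean: 45.200000000000003
    ca_sd: 7.3
    ca_range:
    - 25.0
    - 77.0
    female_fraction: 0.532
    p_older: 0.276595744680851
    gap_mean_older: 8.82
    gap_sd_older: 7.727999999999999
    gap_mean_younger: -13.726176470588237
    gap_sd_younger: 9.24
    effect_mean_older: 0.25
    effect_mean_younger: -0.13
    effect_sd: 2.5
    followup_mean: 13.5
    followup_sd: 1.1
    followup_range:
    - 6.0
    - 18.0
    symptom_rate_pre: 0.402
    symptom_rate_post: 0.32
eeg:
  duration_s: 360.0
  n_channels: 19.0
  fs_hz: 256.0
  alpha_age_slope: -0.03
  alpha_anchor_hz: 10.800000000000001
  alpha_amp_uV: 20.0
  alpha_amp_anterior_uV: 8.0
  am_depth: 0.3
  pink_noise_exponent: 1.0
  pink_noise_amp_uV: 5.0
  line_noise_amp_uV: 2.0
  line_freq_hz: 50.0
  artifact_rate_per_min: 2.0
  feature_noise_sd_hz: 0.075
  within_subject_corr: 0.6
reference:
  'n': 400.0
  ca_range:
  - 16.0
  - 100.0
band:
- 7.0
- 13.0
electrodes:
- O1
- O2
- P3
- P4
- Pz
- T5
- T6
age_range:
- 16.0
- 100.0
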
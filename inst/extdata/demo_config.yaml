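# Demo configuration: sham-like group on the standard acquisition.
grid:
  shape: [64, 64, 64]
  voxel_size: [0.5, 0.5, 0.5]
acquisition:
  TR: 1500          # ms
  TE: 3.7           # ms
  TI: 900           # ms
  flip_angle: 12    # degrees
  r1: 3.7           # 1/(mM s)
  T1_baseline: 1400 # ms
  S0: 1000
  time_points: [0.5, 1, 1.5, 2, 3, 4, 5, 6, 7, 8]  # h post-injection
scenario:
  name: sham
  D_star: 2.770e-4  # mm^2/s
  k_prime: 0.648e-4 # 1/s
  Q: 20             # nmol (10 mmol/L x 2 uL)
  alpha: 0.2
  infusion_duration: 600  # s
  between_subject_cv: 0.15
  snr: 20
  n_subjects: 3
thresholds:
  mask_snr: 3
  k_sigma: 3
D_free: 3.8e-4      # mm^2/s
alpha: 0.2
seed: 42
alpha_level: 0.05
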
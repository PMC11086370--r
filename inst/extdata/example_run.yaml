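# Example end-to-end run: simulate a two-class GC-IMS cohort with three
# discriminative peaks, preprocess, cross-validate, report.
seed: 42
simulation:
  n_class0: 20
  n_class1: 20
  n_retention: 32
  n_drift: 32
  noise_sd: 0.1
  peaks:
    - {retention_center: 0.15, drift_center: 0.30, retention_width: 0.03,
       drift_width: 0.03, base_amplitude: 1.0, class_effect: 2, amplitude_cv: 0.4}
    - {retention_center: 0.35, drift_center: 0.45, retention_width: 0.03,
       drift_width: 0.03, base_amplitude: 1.0, class_effect: 2, amplitude_cv: 0.4}
    - {retention_center: 0.25, drift_center: 0.60, retention_width: 0.03,
       drift_width: 0.03, base_amplitude: 1.0, class_effect: 2, amplitude_cv: 0.4}
    - {retention_center: 0.45, drift_center: 0.65, retention_width: 0.03,
       drift_width: 0.03, base_amplitude: 1.5, class_effect: 1, amplitude_cv: 0.4}
  rip:
    drift_position: 0.12
    amplitude: 10
preprocess:
  crop_window: [0, 60, 5, 80]
cv:
  k: 10
  n_top_features: 50
  classifier: sparse_logistic
report:
  ci_method: delong
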
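# Demo run: a small simulated two-marker cohort that finishes in well
# under five minutes on one CPU.
mode: simulate
seed: 20
log_level: info
cohort:
  n_pairs: 6
  cores_per_patient: 2
  image_side: 96
  core_diameter: 80
markers:
  - name: marker_a
    dab_fraction_hr: 0.35
    dab_fraction_lr: 0.12
  - name: marker_b
    dab_fraction_hr: 0.28
    dab_fraction_lr: 0.16
training:
  n_hr: 6
  n_lr: 6
  seed: 3
  grid_step: 5
pretest_p: 0.005
combination:
  - [marker_a, marker_b]
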
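# End-to-end demonstration workflow: charges -> FRC ensemble -> PRE profile
# -> synthetic titrations -> binding fits -> binding trajectory -> K_D.
seed: 20
stages:
  - name: sequence_charge
    params:
      window: 5
  - name: frc_ensemble
    params:
      n_residues: 68
      n_frames: 2000
  - name: pre_profile
    params:
      label_site: 10
  - name: anisotropy_titration
    params:
      name: tar
      kd: 0.67
  - name: anisotropy_titration
    params:
      name: ru30
      kd: 1.9
  - name: binding_fits
  - name: binding_trajectory
    params:
      f_star: 0.5
      n_frames: 50000
  - name: sim_kd
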
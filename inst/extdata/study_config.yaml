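# Packaged study configuration: a chronic type-B aortic dissection case
# with grouped minor-branch WK3 outlets. Units are embedded in key names.
study:
  id: tbad-chronic-01
  heart_rate_bpm: 94
  brachial_systolic_mmHg: 138
  brachial_diastolic_mmHg: 81
solver:
  dt_s: 0.001
  convergence: 0.01
  max_cycles: 50
metrics:
  wss_sampling_s: 0.005
  ecap_threshold_per_Pa: 1.4
  normal_orientation: bulk-systolic-forward
viscosity:
  mu0_Pa_s: 0.056
  mu_inf_Pa_s: 0.00345
  lambda_s: 3.313
  a: 2.0
  n: 0.3568
  density_kg_m3: 1056
seeds:
  synth: 1
# Minor-branch groups: number of individual branches and the literature
# (Doppler-derived) group flow. Per-branch flow is distributed equally
# within each group.
minor_groups:
  S1: {lumen: FL, n_branches: 7, group_flow_mL_s: 5.50}
  S2: {lumen: TL, n_branches: 11, group_flow_mL_s: 7.97}
  S3: {lumen: FL, n_branches: 2, group_flow_mL_s: 2.11}
  S4: {lumen: FL, n_branches: 8, group_flow_mL_s: 4.29}
  IMA: {lumen: TL, n_branches: 1, group_flow_mL_s: 1.93}
# Proximal-fraction defaults by outlet class.
rho_defaults:
  supra_aortic: 0.030
  renal: 0.280
  other: 0.056
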
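phenotypes:
- label: Inactive
  log_nc_mean: -0.22314355131420971
  log_nc_sd: 0.12
  conc_mean: 85.0
  conc_sd: 21.5
  conc_nc_corr: 0.29999999999999999
  lamp1_conc_mean: 100.0
  lamp1_conc_sd: 20.0
  mcp_mean: 0.68999999999999995
  mcp_sd: 0.20000000000000001
- label: Medium
  log_nc_mean: 0.40546510810816438
  log_nc_sd: 0.12
  conc_mean: 100.0
  conc_sd: 21.5
  conc_nc_corr: 0.29999999999999999
  lamp1_conc_mean: 100.0
  lamp1_conc_sd: 20.0
  mcp_mean: 0.61499999999999999
  mcp_sd: 0.20000000000000001
- label: Active
  log_nc_mean: 1.02961941718115813
  log_nc_sd: 0.12
  conc_mean: 125.0
  conc_sd: 21.5
  conc_nc_corr: 0.29999999999999999
  lamp1_conc_mean: 117.0
  lamp1_conc_sd: 20.0
  mcp_mean: 0.52000000000000002
  mcp_sd: 0.20000000000000001
trajectories:
- treatment: FM
  times:
  - 0.0
  - 0.5
  - 1.0
  - 1.5
  - 3.0
  - 5.0
  - 15.0
  weights:
  - - 0.45000000000000001
    - 0.46000000000000002
    - 0.09
  - - 0.93999999999999995
    - 0.06
    - 0.0
  - - 0.84999999999999998
    - 0.14000000000000001
    - 0.01
  - - 0.75
    - 0.23000000000000001
    - 0.02
  - - 0.55000000000000004
    - 0.41999999999999998
    - 0.03
  - - 0.40000000000000002
    - 0.56999999999999995
    - 0.03
  - - 0.20999999999999999
    - 0.76000000000000001
    - 0.03
- treatment: Torin1
  times:
  - 0.0
  - 0.5
  - 1.0
  - 1.5
  - 3.0
  - 5.0
  - 15.0
  weights:
  - - 0.45000000000000001
    - 0.46000000000000002
    - 0.09
  - - 0.20000000000000001
    - 0.45000000000000001
    - 0.34999999999999998
  - - 0.08
    - 0.42999999999999999
    - 0.48999999999999999
  - - 0.02
    - 0.40999999999999998
    - 0.56999999999999995
  - - 0.14999999999999999
    - 0.45000000000000001
    - 0.40000000000000002
  - - 0.29999999999999999
    - 0.46000000000000002
    - 0.23999999999999999
  - - 0.46999999999999997
    - 0.45000000000000001
    - 0.08
- treatment: ND
  times:
  - 0.0
  - 0.5
  - 1.0
  - 1.5
  - 3.0
  - 5.0
  - 15.0
  weights:
  - - 0.80000000000000004
    - 0.17000000000000001
    - 0.03
  - - 0.40000000000000002
    - 0.45000000000000001
    - 0.14999999999999999
  - - 0.17999999999999999
    - 0.56000000000000005
    - 0.26000000000000001
  - - 0.29999999999999999
    - 0.55000000000000004
    - 0.14999999999999999
  - - 0.45000000000000001
    - 0.5
    - 0.05
  - - 0.59999999999999998
    - 0.40000000000000002
    - 0.0
  - - 0.34999999999999998
    - 0.5
    - 0.14999999999999999
n_cells_per_timepoint: 2000
n_replicates: 3
replicate_jitter_sd: 0.14999999999999999
image_mode: no
image_size: 64
pixel_size_um: 0.5
seed: 1
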
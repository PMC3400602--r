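name: sys4-default
system_id: 4.0
tier: langevin
omega: 300.0
T: 600.0
dt: 0.1
dt_out: 2.0
burn_in: 0.5
seed: 1.0
lattice:
  nrow: 25.0
  ncol: 25.0
  h: 1.0
params:
  k_U: 1.0
  K_U: 0.8
  n_U: 3.0
  k_V: 1.0
  K_V: 0.8
  n_V: 3.0
  k_T: 0.5
  d_T: 0.5
  K_T: 0.5
  n_T: 4.0
  k_W: 0.4
  a_A: 2.2
  b_A: 0.09
  d_A: 0.9
  K_AA: 0.35
  K_R: 0.37
  a_R: 0.05
  d_R: 0.033
  K_AR: 0.45
  n_osc: 4.0
  K_gate: 0.35
  n_gate: 4.0
  s3: 0.3
  K_act: 0.4
  n_act: 2.0
  K_rep: 0.5
  n_rep: 2.0
  s1: 0.1
  s2: 0.1
  D1: 2.0
  D2: 2.0
  D3: 2.0
  kdeg1: 0.02
  kdeg2: 0.02
  kdeg3: 0.2
  k_div: 0.05
  k_kill: 0.02
  theta_G: 2.0
  n_G: 4.0
  c_commit: 0.5
  debounce: 3.0
version: '1'
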
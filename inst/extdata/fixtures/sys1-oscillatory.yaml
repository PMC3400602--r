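name: sys1-oscillatory
system_id: 1.0
tier: ode
params:
  k_div: 0.0583
  k1: 0.4447
  k2: 0.0061
  k3: 0.0053
  k_death: 0.0052
  k_c: 0.1
  k_kill: 0.01
  theta_S: 100.0
  theta_B: 35.0
  theta_C: 300.0
  theta_G: 170.0
  n_S: 4.0
  n_B: 10.0
  n_C: 2.0
  n_G: 6.0
T: 12000.0
dt_out: 1.0
omega: 300.0
dt: 0.1
burn_in: 0.5
seed: 1.0
lattice:
  nrow: 25.0
  ncol: 25.0
  h: 1.0
version: '1'
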
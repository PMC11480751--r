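# Standard escape-motility protocol: 150 colonies released at the
# oxygenated interface, fitted motility parameters, 17 s record.
engine: point
seed: 1
environment:
  oxygen:
    C0_uM: 250
    D_C_um2_s: 2000
    c_star_uM: 2.5
    enabled: true
  magnetic:
    phi_B_rad: 2.7
    k_per_s: 10
motility:
  v_jump_um_s: 26.6
  v_return_um_s: 7.6
  lambda_minus_per_s: 0.0413
  lambda_plus_per_s: 0.4186
clock:
  dt_s: 0.001
  t_final_s: 17
init:
  n_colonies: 150
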
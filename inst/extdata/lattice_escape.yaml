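# Escape through a lattice: strong field (k = 50 s^-1) holds an n x 10
# hexagonal lattice at the wall; aerotaxis on.  Sweep lattice.n_layers
# (or use protocol_lattice_escape()) for the depth dependence.
engine: squirmer
seed: 1
environment:
  magnetic:
    phi_B_rad: 3.141592653589793
    k_per_s: 50
lattice:
  n_layers: 2
  n_per_layer: 10
clock:
  dt_s: 0.0005
  t_final_s: 60
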
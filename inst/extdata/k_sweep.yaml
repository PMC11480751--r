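# One run of the dispersal-condensation protocol: 100 uniformly aligned
# squirmers at the wall, aerotaxis off.  Sweep environment.magnetic.k_per_s
# (or use protocol_k_sweep()) to map <Phi>(k) and s(k).
engine: squirmer
seed: 1
environment:
  oxygen:
    enabled: false
  magnetic:
    phi_B_rad: 3.141592653589793
    k_per_s: 0
lattice:
  n_layers: 10
  n_per_layer: 10
clock:
  dt_s: 0.0005
  t_final_s: 60
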
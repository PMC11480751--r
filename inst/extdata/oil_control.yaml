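# Oil-interface control: no oxygen enters the drop, the reversal response
# is silent, colonies stay pressed against the interface.
engine: point
seed: 1
environment:
  oxygen:
    enabled: false
clock:
  t_final_s: 17
init:
  n_colonies: 150
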
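description: Let-7 present, high growth factor (oscillations recovered)
initial: NT
t_end: 600
overrides:
  V_SLET7: 0.5
  GF: 10.0
events: []
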
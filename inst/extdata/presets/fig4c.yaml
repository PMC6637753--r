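description: strong cyclin overexpression (V_SMCYC 1.5 -> 12 at t = 100 h), fast switch
initial: NT
t_end: 600
overrides: []
events:
- t_start: 100
  t_end: Inf
  overrides:
    V_SMCYC: 12.0
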
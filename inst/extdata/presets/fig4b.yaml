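description: mild cyclin overexpression (V_SMCYC 1.5 -> 2.5 at t = 100 h), slow Let-7 down-regulation
initial: NT
t_end: 1000
overrides: []
events:
- t_start: 100
  t_end: Inf
  overrides:
    V_SMCYC: 2.5
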
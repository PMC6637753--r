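description: cyclin overexpression from quiescence (V_SMCYC 1 -> 4 at t = 100 h)
initial: NT
t_end: 600
overrides:
  V_SLET7: 0.25
  V_SMCYC: 1.0
  GF: 0.2
events:
- t_start: 100
  t_end: Inf
  overrides:
    V_SMCYC: 4.0
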
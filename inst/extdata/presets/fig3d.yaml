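description: transient PTEN overexpression (V_SMPTEN 0.001 -> 10 for 500 < t < 1000 h)
initial: T
t_end: 1500
overrides: []
events:
- t_start: 500
  t_end: 1000
  overrides:
    V_SMPTEN: 10.0
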
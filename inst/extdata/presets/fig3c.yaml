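description: transient NF-kB inhibition (all three activation constants zero for 500 < t < 1000 h)
initial: T
t_end: 1500
overrides: []
events:
- t_start: 500
  t_end: 1000
  overrides:
    k_AA1NFKB: 0.0
    k_AA2NFKB: 0.0
    k_AA3NFKB: 0.0
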
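description: transient Src pulse (100-105 h) flips the epigenetic switch and starts cycling
initial: NT
t_end: 800
overrides: []
events:
- t_start: 100
  t_end: 105
  overrides:
    Src: 0.5
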
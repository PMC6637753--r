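description: 100-cell population at 50 percent jitter, cyclin/Let-7 scatter structure
initial: NT
t_end: 1000
overrides:
  Src: 1.0e-7
events: []
population:
  n_cells: 100
  jitter_fraction: 0.50
  start: NT
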
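description: heterogeneous population (0.10 uniform jitter) from the T state, CPI vs NTSI scatter
initial: T
t_end: 1000
overrides: []
events: []
population:
  n_cells: 500
  jitter_fraction: 0.10
  start: T
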
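description: heterogeneous population (0.50 uniform jitter) from the NT state, CPI vs NTSI scatter
initial: NT
t_end: 1000
overrides: []
events: []
population:
  n_cells: 500
  jitter_fraction: 0.50
  start: NT
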
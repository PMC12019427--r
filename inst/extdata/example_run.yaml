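# Example run configuration: one point in the middle of the first
# plateau of the two-segment AT-GC fragment, desk-scale statistics.
fragment:
  preset: poly(dA-dT)-poly(dG-dC)
protocol:
  x_grid: [1.275]
  t_equil_ns: 50
  t_prod_ns: 300
  n_replicas: 3
engine:
  dt_fs: 100
  temperature: 300
seed: 103
output_dir: out
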
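# Example ionpmf sweep: one weakly and one strongly coupled state point.
# Values omitted here fall back to the standard model parameters
# (eps = 78, radii 10/2 A, k = 9 nN/A, x_ref = 40 A, T = 298.15 K).
physical:
  temperature: 298.15
mc:
  n_equil: 20000
  n_prod: 80000
  frame_stride: 25
pb:
  final_h: 0.5
sweep:
  Z: [12, 24]
  z: [2]
  c0: [0.01]
  x_values: [22, 24, 26, 28, 30, 32, 34, 36, 38, 40]
output_dir: ionpmf-results
seed_base: 20260927
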
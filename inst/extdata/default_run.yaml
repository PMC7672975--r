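# Default capsule run: one 50 um cancer spheroid, fibroblasts biased to the
# outer ring, no collagen fibers; reference transport constants.
schema: capsim/1
seed: 42
grid:
  nodes_per_side: 200
  side_length: 1000
  capsule_radius: 350
transport:
  D_medium: 0.15
  cell_ratio: 100
  C_inj: 13
saturation:
  a: 1
  n: 1
  p: 1
simulation:
  total_time: 180
  frame_interval: 2
placement:
  n_spheroids: 1
  spheroid_radius: 50
  n_fibro_single: 30
  n_fibro_cluster: 8
  n_fibers: 0
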
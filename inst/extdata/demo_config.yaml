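# Demonstration run: two conditions of random-tree phantoms differing in
# target segment count, three gels each, compared on the number of vessels.
seed: 42
conditions:
  - name: sparse
    n_gels: 3
    phantom:
      topology: random_tree
      n_segments: 5
      tube_radius_um: 3
  - name: dense
    n_gels: 3
    phantom:
      topology: random_tree
      n_segments: 15
      tube_radius_um: 3
preprocess:
  sigma_um: 1
  filter: median
  threshold: otsu_global
  min_object_voxels: 27
skeleton:
  prune_um: 3
stats:
  metric: total_length_um
  alpha: 0.05
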
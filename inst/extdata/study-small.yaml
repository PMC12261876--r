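# Small two-center study configuration (fixture scale): 2 subjects per
# center on a 16^3 grid with 8 respiratory phases. Unspecified fields are
# filled from the package defaults.
seed: 42
grid:
  dim: [16, 16, 16]
  voxel_size: [10, 10, 10]
n_phases: 8
demographics:
  lung_semiaxes: [32, 38, 56]
  tv_range: [280, 450]
centers:
  - name: Center1
    n: 2
    profiles: [Center1-1.5T, Center1-3T]
  - name: Center2
    n: 2
    profiles: [Center2-3T]
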
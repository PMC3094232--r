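seed: 20
arm_lengths: synthetic_arm_lengths.tsv
markers: synthetic_markers.tsv
regions: synthetic_inversions.tsv
sharing_pairs:
- species1: gambiae_like
  arm1: 2R
  species2: stephensi_like
  arm2: 2R
block_triples:
- label: 2R
  ref: spA
  others:
  - spB
  - spC
  arms:
    spA: 2R
    spB: 2R
    spC: 2R
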
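# Toy profile: small dimensions, runs in well under a minute on one CPU.
model:
  n_feat: 16
  n_heads: 2
  n_blocks: 3
  kernel_sizes: [7, 9, 11]
  threshold: 0.5
train:
  margin: 1.0
  phase1_epochs: 4
  phase1_batch: 40
  phase1_lr: 5.0e-4
  phase2_epochs: 150
  phase2_batch: 4096
  phase2_lr: 1.0e-3
  beta1: 0.9
  beta2: 0.999
  triplets_per_epoch: 80
  seed: 1
synth:
  branching: [2, 2, 2, 2]
  proteins_per_leaf: 6
  length_range: [12, 18]
  n_feat: 16
  separation: 4.0
  noise: 1.0
  rho: 0.7
  motif_length: 7
  motif_strength: 2.0
  multi_label_prob: 0.1
  parent_dep: 1.0
  seed: 1
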
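# Published training recipe: constant-rate contrastive phase, then a
# large-batch cosine-annealed head phase on frozen features. The feature
# width must match the embeddings actually supplied.
model:
  n_feat: 64
  n_heads: 4
  n_blocks: 3
  kernel_sizes: [7, 9, 11]
  threshold: 0.5
train:
  margin: 1.0
  phase1_epochs: 1000
  phase1_batch: 40
  phase1_lr: 5.0e-4
  phase2_epochs: 150
  phase2_batch: 50000
  phase2_lr: 1.0e-3
  beta1: 0.9
  beta2: 0.999
  seed: 1
synth:
  branching: [7, 3, 3, 3]
  proteins_per_leaf: 20
  length_range: [50, 120]
  n_feat: 64
  separation: 3.0
  noise: 1.0
  rho: 0.7
  motif_length: 9
  motif_strength: 2.0
  multi_label_prob: 0.1
  parent_dep: 1.0
  seed: 1
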
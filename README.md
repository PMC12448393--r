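# ecfusion

Enzyme Commission (EC) number prediction from two per-residue protein
embedding modalities — a sequence language-model embedding and a 3Di
structural-alphabet embedding — with a dual-pathway fusion network and an
autoregressive, hierarchy-aware prediction head.

EC numbers are four-level hierarchical codes (`class.subclass.sub-subclass.
serial`, e.g. `2.7.7.7`); one enzyme may carry several. The 3Di alphabet is a
20-letter discretization of local backbone geometry that lets 3D structure be
handled as a sequence, so a protein enters the model as two aligned `L x N`
matrices (one row per residue). `ecfusion` is aimed at method developers who
want a fully testable, CPU-scale implementation of this architecture: every
stage — from embedding containers to the ablation harness — runs end-to-end
on a bundled synthetic-embedding generator, with no pre-trained embedder or
external database required. Producing the embeddings themselves (e.g. from
ESM-2 or ProstT5) is deliberately out of scope; the embedding container is
the adapter point.

## The model

**Feature extraction.** Two pathways run over the paired streams
F<sup>seq</sup>, F<sup>3Di</sup> ∈ ℝ<sup>L×N</sup>:

- *Global pathway* — three stacked cross-attention blocks. In each block the
  3Di stream is updated first, attending over the sequence stream, then the
  sequence stream attends over the updated 3Di stream:

  Att(Q, K, V) = Softmax(QKᵀ/√d<sub>k</sub>) V,
  with h heads of width N/h (per-head projections W<sup>Q</sup><sub>i</sub>,
  W<sup>K</sup><sub>i</sub>, W<sup>V</sup><sub>i</sub>), concatenated,
  projected, residual-added to the query stream and layer-normalized.

- *Local pathway* — three blocks of parallel 1-D convolutions with kernel
  sizes 7, 9 and 11 over the channel-stacked pair (2N channels per residue),
  concatenated and fused by a per-position MLP back to width N. Block *i* > 1
  stacks the global sequence output of block *i−1* with the local output of
  block *i−1*, so the two pathways interleave.

The final fusion F<sub>fuse</sub> = [F̂<sup>seq</sup><sub>3</sub>,
F<sup>out</sup><sub>local,3</sub>] ∈ ℝ<sup>L×2N</sup> is mean-pooled over
residues into one protein vector.

**Prediction.** Four MLPs predict the four EC levels as multi-label sigmoid
vectors over the observed label vocabularies; MLP *j* > 1 additionally
consumes the previous level's prediction vector (ground-truth multi-hot under
teacher forcing, predicted probabilities at inference) — an autoregressive
head that exploits the hierarchy. Decoding keeps every level-4 label whose
whole ancestor chain clears a threshold τ (confidence = chain minimum), with
a greedy root-to-leaf fallback so every protein gets at least one EC.

**Training** is two-phase: phase 1 fits the feature extractor alone with a
triplet loss Σ max(0, d(a,p) − d(a,n) + margin) on pooled features (positives
share a full EC, negatives share none, with hard negatives drawn from the
anchor's own sub-subclass); phase 2 freezes the extractor, caches pooled
features once, and fits the head with summed binary cross-entropy over all
levels. The combined loss is λ₁·L<sub>triplet</sub> + λ₂·L<sub>BCE</sub> with
λ = (1, 0) then (0, 1). The network, its analytic backpropagation and Adam
are implemented in plain R matrix code — no deep-learning framework is
required.

## Worked example

```r
library(ecfusion)

# synthetic cohort: 24 leaf EC classes under a 3x2x2x2 hierarchy,
# 25 proteins per class, planted functional-site motifs
synth <- generate_dataset(synth_config(branching = c(3, 2, 2, 2),
                                       proteins_per_leaf = 25,
                                       separation = 5, seed = 7))
split <- split_dataset(synth$dataset, test_fraction = 0.2, seed = 7)

fit <- train_model(split$train,
                   model_config(n_feat = 16, n_heads = 2),
                   train_config(phase1_epochs = 10, phase2_epochs = 500,
                                phase2_batch = 4096, triplets_per_epoch = 200,
                                seed = 7))
fit
#> <ecfusion_fit> N=16 h=2 blocks=3 | label levels 3/6/12/24 | 510 training epochs

preds <- predict_dataset(split$test, fit)
head(preds, 4)
#> # A tibble: 4 × 4
#>   protein_id ec      confidence fallback
#>   <chr>      <chr>        <dbl> <lgl>
#> 1 synthP0002 1.1.1.1      0.821 FALSE
#> 2 synthP0007 1.1.1.1      0.720 FALSE
#> 3 synthP0010 1.1.1.1      0.852 FALSE
#> 4 synthP0015 1.1.1.1      0.799 FALSE

per_digit_metrics(preds, split$test$labels, mode = "macro")
#> # A tibble: 4 × 6
#>   level mode  precision recall    f1 n_proteins
#>   <int> <chr>     <dbl>  <dbl> <dbl>      <int>
#> 1     1 macro     1      1     1            109
#> 2     2 macro     1      1     1            109
#> 3     3 macro     1      1     1            109
#> 4     4 macro     0.931  0.917 0.914        109
```

Level-1 predictions (the EC class) are perfect on held-out proteins; the
hardest, fully resolved four-level label still reaches macro F1 0.914. The
per-residue attention importance concentrates on the planted functional-site
windows (mean score 0.593 inside vs 0.385 outside on the same held-out set):

```r
imp <- importance_table(split$test, fit$params, fit$config)
plot_importance(imp, motifs = synth$motifs)
```

`tidy(fit)` returns the per-epoch loss trace, `glance(fit)` a one-row model
summary, and `autoplot(fit)` the two-phase training curves. The ablation
harness (`run_ablation()`) retrains variants with the global pathway, local
pathway, autoregression, or one input modality disabled.

## Command-line interface

`exec/ecfusion` wraps the same functions:

```sh
ecfusion synth    --config inst/config/test.yaml --out fixtures/
ecfusion train    --config inst/config/test.yaml --data fixtures/ --checkpoint model.rds
ecfusion predict  --checkpoint model.rds --data fixtures/ --out pred.tsv --importance imp.tsv
ecfusion evaluate --pred pred.tsv --truth fixtures/labels.tsv \
                  --train-labels fixtures/labels.tsv --out metrics.json
```

Two configuration profiles ship under `inst/config/`: `paper.yaml` (the
published training recipe: triplet batches of 40 for 1000 epochs at constant
5e-4, then head batches of 50 000 for 150 epochs at cosine-annealed 1e-3)
and `test.yaml` (a toy profile that runs in seconds).

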
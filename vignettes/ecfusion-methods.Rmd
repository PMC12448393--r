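---
title: "Dual-pathway sequence-structure fusion for EC number prediction: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dual-pathway sequence-structure fusion for EC number prediction: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

This vignette documents the models, assumptions, tunable parameters and
numerical choices behind `ecfusion`. It states no empirical result beyond
what the test suite and `scripts/acceptance.R` themselves compute.

## Problem and inputs

An Enzyme Commission (EC) number is a four-level hierarchical code
(`class.subclass.sub-subclass.serial`); an enzyme may carry several, and
multi-EC enzymes typically differ only in the serial digit. The package
predicts the full EC set of a protein from two per-residue embedding
matrices of equal shape `L x N`: a sequence embedding (in practice from a
protein language model) and a 3Di embedding (from a structure-aware model
over Foldseek's 20-letter discretization of local backbone geometry).
Computing those embeddings is out of scope: `write_embeddings()` /
`read_embeddings()` define a single-file container (one entry per protein
id, float matrices `seq` and `tdi`, shape- and finiteness-checked) and any
embedder can fill it. Embedding rows must align 1:1 with residues; a length
mismatch is an error rather than a truncation, because a silent off-by-one
would corrupt every attention map downstream.

## Label encoding

The level-*k* label space is the set of distinct *k*-level *prefixes*
observed in the training labels, sorted numerically on the digit tuple for
deterministic indexing. This is the only encoding under which per-digit
metrics and a prefix-constrained decoder are well defined; encoding bare
digit values (so that `1.1.1.1` and `2.1.1.1` would share a level-2 label
"1") was considered and rejected, since second-level digit values have no
meaning detached from their class. Targets are per-level multi-hot vectors:
the actives at level *k* are exactly the *k*-prefixes of the protein's EC
set, so actives are ancestor-closed by construction. Placeholder labels
("-", "n1") are rejected at parse time; the model works with fully resolved
four-level codes.

## Architecture

Let `N` be the feature width (`n_feat`) and `h` the head count (`N/h` per
head). Defaults: `N = 16`, `h = 2`, 3 blocks per pathway, kernel sizes
(7, 9, 11), chosen so that the full pipeline trains in seconds to minutes on
one CPU while preserving every structural property of the architecture.

**Global pathway (cross-attention).** Each of the three blocks applies two
multi-head cross-attention layers with scaled dot-product attention: first
the 3Di stream is the query and the sequence stream supplies keys/values
(updating the 3Di stream), then the sequence stream queries the freshly
updated 3Di stream (updating the sequence stream). The written multi-head
definition elsewhere orders its subscripts the other way; the prose around
it, and the second layer's symmetry, both indicate that the *updated* stream
is the one named in the output, so the query-stream-is-output convention is
the default here, with `model_config(paper_subscripts = TRUE)` selecting the
literal subscript order. Each layer adds the attention output (after
concatenation and an output projection) residually to the query stream and
layer-normalizes. The residual and normalization are an implementation
choice — a six-layer unnormalized attention stack is untrainable in
practice — and no position-wise feed-forward sublayer is added because the
architecture description includes none.

**Local pathway (multi-kernel convolution).** Each block applies three
parallel same-padded 1-D convolutions (kernels 7, 9, 11) along the residue
axis to a 2-channel stack flattened to `2N` input channels, each producing
`N` channels; the concatenated `3N` features pass through a per-position MLP
(one hidden layer of width `3N`, rectifier) back to `N`. The first block
consumes the raw (sequence, 3Di) stack — the natural choice keeping the
2-channel contract uniform, as the chaining rule only specifies later
blocks; block *i* > 1 consumes the global sequence output of block *i−1*
stacked with the local output of block *i−1*.

**Fusion and pooling.** The final global sequence stream and the final local
output are concatenated per residue (`L x 2N`) and mean-pooled over residues
into one protein vector. Unweighted mean pooling is the simplest choice
consistent with proteins of varying length; the pooled width `2N` is what
the prediction head and the triplet distance operate on.

**Prediction head.** Four two-layer MLPs (hidden width = input width,
rectifier, sigmoid outputs), one per EC level, over the per-level
vocabularies. MLP *j* > 1 receives the previous level's full prediction
*vector* alongside the pooled features — a single decoded digit would break
multi-EC enzymes, which need several active parents. Training uses teacher
forcing (ground-truth multi-hot as the previous level); inference feeds the
predicted probabilities. Scheduled sampling is deliberately not implemented;
teacher forcing is the standard stabilization and the phase-2 loss surface
is convex enough at these scales.

**Decoding.** A level-4 label is emitted when its probability and its whole
ancestor chain's probabilities reach the threshold τ (default 0.5,
configurable); its confidence is the chain minimum. If nothing survives, a
single EC is produced by walking the label tree greedily root to leaf,
restricted to the observed child map — so every protein receives at least
one prediction, decoded sets are always prefix-consistent, and raising τ
never adds predictions. Alternative inference rules (max-separation over a
learned embedding, top-k) were considered; τ-thresholding with a greedy
fallback is the documented choice because it is monotone, calibratable and
trivially auditable.

## Training

Phase 1 trains the feature extractor alone by contrastive learning: triplets
(anchor, positive, negative) where the positive shares at least one full EC
with the anchor and the negative shares none, hinge loss
`max(0, d(a,p) − d(a,n) + margin)` with Euclidean distance on pooled fused
features and margin 1 by default (the distance function and the mining
space are unstated in the source architecture; pooled fused features are
chosen because they are exactly what the head later consumes). Half of the
negatives are *hard*: drawn from the anchor's own sub-subclass when such
proteins exist. Without hard negatives, uniformly sampled negatives almost
always differ already at the class level and the serial-digit distinction
receives essentially no gradient at small scale. Phase 2 freezes the
extractor, pools the whole training set once (this cache is what makes very
large head batches cheap), and minimizes the summed multi-level binary
cross-entropy (probabilities clamped to `[1e-7, 1 − 1e-7]`; the sum — not
the mean — is the written form, with per-protein means used only for
logging). Both phases use Adam (0.9/0.999); phase 1 a constant learning
rate, phase 2 cosine annealing. The reference profile (`paper.yaml`)
carries the published recipe — batch 40 for 1000 epochs at 5e-4, then batch
50 000 for 150 epochs at 1e-3 — while tests and examples use scaled-down
profiles (4–10 phase-1 epochs, 150–500 phase-2 epochs, a few hundred
proteins) selected so the whole suite runs in minutes on one CPU.

All computation is double precision, single-threaded and seeded: dataset
generation, splits, initialization (variance-scaled uniform weights, zero
biases, unit layer-norm gains), triplet mining and shuffling all derive from
explicit integer seeds, and two identical forwards are bit-identical. The
backpropagation is hand-derived per layer and verified against central
finite differences at tolerance 1e-4 in the test suite; layer forwards are
verified against straight-line loop oracles at 1e-6.

## Attention importance

Per-residue importance is the attention weight matrix of the final global
block's second layer (the layer that refreshes the sequence stream by
attending over the updated 3Di stream), averaged over heads and query
positions, then min-max normalized over residues. When every residue
receives identical attention — including the degenerate `L = 1` protein —
the normalization is undefined and all scores are reported as 0.

## The synthetic-data generator

The generator produces the statistical structure the model assumes, so that
training, evaluation, ablation and importance analysis are all exercisable
without any external data:

- a 4-level label tree with configurable branching; digit values assigned
  deterministically;
- per-leaf prototype pairs: tree nodes at levels 1–3 contribute Gaussian
  class directions at strength `separation` to a residue-wide background;
  the 3Di background is a `rho`-mixture of a fixed orthogonal transform of
  the sequence background and an independent family-level signal, so the
  modalities are correlated yet complementary;
- one planted functional-site window per protein (length `motif_length`,
  default 7), whose residues receive a strong motif direction shared by the
  protein's sub-subclass family — modelling conserved catalytic motifs —
  plus the *serial-digit increment*: the level-4 identity signal, scaled by
  `parent_dep`, lives only inside this window, enters the structural channel
  at full weight and the sequence channel at one tenth (fine substrate
  specificity is mostly structural), and its direction is shared per digit
  value with a *sign that flips per sub-subclass*. The sign contextuality
  mirrors real EC semantics — a serial digit has no meaning detached from
  its sub-subclass — and is precisely what makes conditioning on coarser
  predictions informative for the autoregressive head;
- i.i.d. Gaussian residue noise (`noise`), uniform lengths, optional second
  leaf labels sharing the level-3 prefix (multi-EC enzymes; the protein's
  signal is then the average of the two leaves'), and 3Di strings derived
  deterministically from the 3Di embeddings.

What the generator does **not** emulate: the geometry of real language-model
embeddings (anisotropy, position-dependent statistics), realistic length
distributions, sequence-composition signal (amino-acid strings are random),
or label imbalance. Passing tests therefore demonstrate that the
implementation learns the structures it claims to learn — hierarchical
class signal, local functional sites, cross-modal complementarity — not
that it would reach any particular accuracy on real proteome-scale data.

Two fixtures are fixed for the acceptance checks and documented here as the
package's study conditions. The *label-recovery fixture* — branching
(3,2,2,2), 25 proteins per leaf, lengths 20–30, `N = 16`,
separation/noise = 5 — is the regime where pooled class signal is strong,
and full two-phase training (10 phase-1 epochs, 500 phase-2 epochs) is
expected to recover the hierarchy on held-out proteins and to concentrate
attention inside the planted windows. The *directional-ablation fixture* —
branching (2,2,2,3), 14 proteins per leaf, lengths 12–18, `N = 8`,
separation 2, `rho = 0.5`, `parent_dep = 1` — deliberately starves the
serial digit: its signal is window-local, structural-channel-heavy and
sign-contextual, so disabling the autoregressive head or zeroing the 3Di
channel should cost held-out level-4 F1, averaged over five retraining
seeds. Only the *ranking* of variants is asserted, never absolute values:
at this scale the autoregressive input is a deterministic function of the
same features, so its benefit is sample- and optimization-efficiency, which
a sufficiently long training run on an easy fixture would erase.

## Numerical choices and degenerate inputs

- Softmax rows are max-shifted before exponentiation; attention weight rows
  sum to 1 within 1e-6 everywhere.
- Layer normalization uses population variance with epsilon 1e-5.
- Triplet gradients guard zero distances with epsilon 1e-12.
- Vocabulary order, and hence index assignment, is the numeric digit-tuple
  order — stable across runs and input permutations.
- `L = 1` proteins flow through every stage (same-padded convolutions,
  attention, pooling); only importance scores degenerate to 0 by the
  min-max rule.
- Frequency-binned evaluation uses half-open-left bins `(e, e']` of default
  width 5; an EC never predicted and never true contributes to no bin, and
  ECs unseen in training are either an error or assigned frequency 0 into
  the first bin, per `missing_freq`.
- Macro metrics average per-protein precision/recall/F1; micro metrics pool
  counts. The averaging convention is ambiguous in much of the EC-prediction
  literature, so both are always computed and labelled.

## Known limitations

- No real-embedder integration is bundled; the container is the interface.
- Confidences are raw chain-minimum sigmoids, not calibrated probabilities.
- There is no non-enzyme rejection class: every input receives an EC.
- Training is single-threaded R; the design target is correctness and
  auditability at desk scale, not throughput. The published-scale recipe in
  `paper.yaml` is faithful but would be impractically slow in this
  implementation on proteome-scale data.
- Scheduled sampling, distributed training and mixed precision are out of
  scope.
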
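---
title: "methFusion: model, training procedure, and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{methFusion: model, training procedure, and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

DNA methylation marks (4mC, 5mC, 5hmC, 6mA) can be predicted from the
sequence surrounding a candidate site: benchmark datasets in this area are
balanced sets of fixed-length windows (41 bp is the common convention;
11/71/101 bp variants exist) centered on the candidate base, labeled
methylated or not.  methFusion treats the window as a sentence of
overlapping k-mer "words" and classifies it with a dual-scale transformer:

1. **Tokenization.** The window is tokenized twice, with overlapping 3-mers
   and overlapping 6-mers (stride 1, so an L-bp window yields L − k + 1
   tokens per scale).  Each vocabulary contains all 4^k k-mers plus five
   special tokens (`[PAD]`, `[UNK]`, `[CLS]`, `[SEP]`, `[MASK]`), 4^k + 5
   ids in total.  Short k-mers give smooth, local features; long k-mers give
   sparse, specific ones — the two scales are complementary.
2. **Encoding.** Each scale has its own transformer encoder (token embedding
   plus learned absolute position embedding; then per layer: multi-head
   scaled-dot-product attention, residual + LayerNorm, GELU feed-forward,
   residual + LayerNorm — the post-norm arrangement).  The final-layer
   `[CLS]` row pools the sequence.
3. **Fusion.** The two pooled vectors h1, h2 are combined by a
   dimension-wise sigmoid gate: F = sigmoid(h1 W1 + h2 W2),
   h = F ⊙ h1 + (1 − F) ⊙ h2, a per-dimension convex combination, so each
   fused coordinate lies between the two scale values.
4. **Classification.** A two-layer fully connected head
   (d_m → d_m/2 → 1, ReLU, dropout 0.1 in training) and a sigmoid give the
   methylation probability p; the label is 1 iff p ≥ 0.5 (threshold
   configurable).

Training minimizes binary cross-entropy, optionally augmented by
**FGM adversarial training**: after the clean backward pass, the gradient g
of the loss at the token-embedding output s is renormalized to
r = ε · g / ||g||₂ (a one-step, worst-case, loss-increasing perturbation;
||r||₂ = ε exactly), s + r is re-forwarded, and the optimizer minimizes the
sum of the clean and perturbed cross-entropies.  The perturbation is built
with the parameters held constant — no gradient flows through its
construction — and is applied independently to both scale branches.  With
ε = 0 the code path is the plain loop, bit for bit.

## Tunable parameters

| parameter | default | meaning |
|---|---|---|
| scale pair (k1, k2) | 3, 6 | the best-performing k-mer combination |
| encoder profile | desk: L=2, d_m=64, h=4, ffn=128, dropout 0.1 | trains in minutes on one CPU |
| full profile | L=12, d_m=768, h=12, ffn=3072 | BERT-base geometry, for pretrained checkpoints |
| pooling | CLS row | masked mean pooling selectable |
| ε (FGM norm) | 1.0 | 0 disables adversarial training |
| optimizer | AdamW, lr 1e-3 (desk) | use ~2e-5 with the full profile |
| clipNorm / warmup | 1.0 / 20 steps | post-norm stacks need both to start stably |
| early stopping | validation MCC, patience 5 | metric selectable (`auc`, `acc`, `loss`) |
| decision threshold | 0.5 | label metrics only; AUC/AP are threshold-free |

Units: ε is in embedding-space L2 norm over the batch tensor; learning rate
per AdamW convention; all coordinates 0-based half-open internally, 1-based
only in GRanges containers (their native convention) and display strings.

## Numerical and design choices

* **Hand-written forward/backward.** No autodiff framework is available in
  this stack, so the encoder, gate, head, and their gradients are written
  out (R for the glue, compiled C++ for the per-layer hot path).  The test
  suite validates every gradient against central finite differences on a
  tiny architecture — the strongest correctness check such code can have.
* **FGM sign.** The perturbation is oriented *along* the gradient
  (loss-increasing).  One printed formulation of this method negates both
  the perturbation and the batch average, which would train on the
  easiest rather than the worst-case neighborhood and contradicts the
  method's stated goal; we implement the ascent direction.
* **Initialization.** Xavier for projections; embedding tables are scaled so
  per-token embedding norms are O(1) regardless of d_m.  This keeps the
  *relative* size of an ε = 1 FGM perturbation comparable between the desk
  profile and BERT-base-sized models; with tiny embeddings, ε = 1 would
  drown the signal.
* **Stabilizers.** Global gradient-norm clipping (1.0) and a 20-step linear
  warmup; without them the post-norm desk profile shows the classic
  cold-start stall (ranking improves while the loss sits at log 2) followed
  by calibration blow-ups.
* **Encoder dropout.** The desk profile keeps the BERT-standard 0.1; with a
  two-layer model on a few hundred training windows, regularization is what
  separates a ~0.95 from a ~0.85 validation AUC.  We also observe that
  adversarial training itself acts as a strong regularizer here: ε = 1
  visibly beats ε = 0 on the synthetic benchmark, consistent with the
  ablation reported for the full-scale model.
* **Pooling.** CLS-row pooling (the BERT convention).  The source
  publication never states the pooling; masked mean pooling is provided as
  an option and performs comparably at desk scale once dropout is enabled.
* **MCC convention.** A zero factor in the MCC denominator yields MCC = 0;
  SN/SP with empty classes are NaN with a warning.  AP uses step
  interpolation (the modern definition), AUC the trapezoid rule with tied
  scores grouped.
* **Tokenizer edge rules.** Stride is 1 (the worked tokenization example
  implies it); any k-mer containing a non-ACGT character maps to `[UNK]`;
  input is upper-cased so soft-masked genome sequence is treated as normal;
  over-long inputs are truncated symmetrically around the central token
  (benchmark windows are site-centered) with a warning.
* **Degenerate inputs.** Empty motif lists export a valid header-only MEME
  file; an importance track that is constant normalizes to all zeros; a
  vanishing FGM gradient yields a zero perturbation; scanning a poly-A
  region returns an empty candidate set, not an error.

## The synthetic data generator

Real benchmark sets cannot be bundled, so `generateDataset()` emulates their
*shape*: balanced classes of 41-bp windows (length configurable), uniform
background composition, and a 6-wide CG-rich planted motif
(consensus GCCGCG, 0.85 consensus probability per column ≈ 1.15
bits/column) placed at the window center ± 2 bp of uniform jitter in
positives only (a leakage rate can plant it in negatives too).  The plant
position of every motif instance is recorded as ground truth.  With the
default placement the motif's internal C/G pair falls on the window center,
so the same motif serves the CpG/CHG/CHH context fixtures
(`centerContext` forces the center dinucleotides).  `generateGenome()`
plants such sites into a background contig (default 5 kb, 20 sites,
non-overlapping at window distance) and returns the truth coordinates.

Two packaged study designs mirror the full-scale experiments:
`transferFixture()` (abundant CpG-context source task; scarce CHG-context
target task whose motif shares the 4-base core CCGC but differs in the
flanks) and `conservationFixture()` (conditions A and B share the planted
motif, C carries a disjoint AT-rich one), used to demonstrate the transfer
and cross-condition-conservation trends.

What passing these tests shows — and does not.  The generator produces
i.i.d. backgrounds with a single planted motif; real methylation
neighborhoods have correlated composition (CpG islands), multiple motifs,
and class overlap.  Synthetic recovery therefore validates the machinery
(optimization, fusion, interpretation, scanning), not field performance on
real genomes; the published benchmark numbers require the external
pretrained encoder and the real datasets, both out of scope here.

## Problem sizes

The packaged experiments are sized for a single CPU: n = 500/class, 41 bp,
desk profile for the main recovery run (converges in ~10 epochs,
~2 minutes); n = 200/class targets for the transfer comparison; 300/class
for the conservation grid; a 5-kb contig with 20 planted sites for the
scanner.  The full profile accepts externally pretrained checkpoints via
`loadPretrained()` but is not exercised by the tests.

## Known limitations

* Forward-strand scanning only by default (reverse-complement scanning is a
  flag); the scan considers the reference as written.
* The two encoders never share parameters (their vocabularies differ), so
  memory scales with both vocabularies; k ≤ 8 is enforced.
* Masked-language-model pretraining is out of scope: `loadPretrained()`
  consumes checkpoints produced elsewhere (or by this package), it does not
  create them from genome corpora.
* Attention-derived importance is a model explanation, not a statistical
  motif test; exported PWMs are meant for downstream comparison tools that
  compute enrichment statistics.  Empirically the two scales divide the
  labor: the 3-mer branch produces a sharp importance peak (good for site
  localization), the 6-mer branch wide high-importance runs (good for
  motif-window extraction at the default threshold 0.6 / width 6) — use
  `scale = 1` for peaks and `scale = 2` for window extraction.  The
  attention reduction (last layer, head mean, CLS row) is a documented
  default, not a claim about how any published heatmap was produced;
  column-mean and diagonal-band policies are selectable.
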
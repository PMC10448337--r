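---
title: "Methods: a convolution-augmented protein language model for missense deleteriousness"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: a convolution-augmented protein language model for missense deleteriousness}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(mutformer)
```

## The problem and the model

A missense variant substitutes a single amino acid in a protein. Whether
that substitution is deleterious depends on the sequence context: a change
inside a conserved functional site usually matters, the same change in an
unconstrained region usually does not. This package implements a protein
language model for that judgment: a BERT-style bidirectional transformer
over amino-acid tokens, optionally augmented with a convolutional block,
trained in two phases — self-supervised masked-residue pre-training on a
proteome, then supervised fine-tuning on labeled benign/deleterious
variants.

The encoder input is the sum of three embeddings — token, learned
absolute position, and a label (segment) embedding distinguishing the
reference from the mutated sequence in paired input — followed by layer
normalization. The label term is used only for paired input; for single
sequences the embedding is exactly token + position. Position index 0 is
always assigned to the first retained token of a cropped input, so
positions are relative to the crop, not the protein.

Each of `num_layers` encoder layers is standard post-LN BERT: multi-head
self-attention, residual connection, layer norm, position-wise
feed-forward (GELU), residual, layer norm. Padded positions are excluded
from attention by an additive mask, and the convolution input/output is
zeroed at padded rows, so hidden states at real positions are invariant to
the amount of right padding (tested to 1e-5; in practice exact in double
precision).

### The convolutional "learned vocabulary" block

Whereas word-piece models fix a vocabulary before training, here kernel-3
stride-1 convolutions between the embeddings and the transformer body
learn short sequence patterns ("words") during training. Four convolution
layers are grouped into two operations of two stacked convolutions with a
GELU between. Two wirings are supported:

* `sequential` — the transformer body sees only the convolution output;
* `integrated` — skip connections are added before both operations, so
  the body receives `E + op1(E) + op2(E + op1(E))`, i.e. the embedding
  output plus both operation outputs.

The grouping of "four layers into two operations" and the placement of
the second skip are genuinely underdetermined by the source description;
the wiring above is the package's reading and is pinned by tests: with all
conv weights zero, `integrated` reproduces the conv-free model bit-exactly
and `sequential` produces a constant (zero) body input. Conv weights train
in both phases.

### Boundary sentinels and cropping

Because long proteins must be cropped, a cropped end is ambiguous with a
real end. The sentinels `B` (true start) and `J` (true end) — letters
absent from the amino-acid code — are attached iff the crop touches the
corresponding protein edge. Nonstandard residues (U, O, ambiguity codes)
map to `X`.

Fine-tuning and inference crops are centered on the mutation site, which
is always retained. Pre-training tiles long sequences with overlap
`window/2` and a right-aligned final tile (the original supplementary
segmentation protocol is not public; this substitute preserves full
coverage). The per-sequence capacity counts residues plus `B`/`J`;
`[CLS]`/`[SEP]` are charged to the aggregate budget, which keeps the
arithmetic "512 per sequence, 1,024 aggregate" exact for the paired
layout `[CLS] ref [SEP] mut [SEP]`.

## Pre-training

The objective is to reconstruct corrupted residues. Per sequence of L
residues, `max(1, min(floor(0.15 L), 20))` positions are selected
uniformly; 15% with `floor` and a minimum of one are package choices (the
source gives neither the rounding nor the degenerate-short-sequence
rule). Each selected position is replaced by `[MASK]` (probability 0.8,
configurable) or by a different random amino acid; there is no
keep-original mode. Masking is dynamic: plans are re-drawn per epoch,
seeded by `(seed, epoch)` so runs are exactly reproducible. Loss and
accuracy are computed on corrupted positions only; 5% of sequences (by id
hash) are held out for evaluation. The optimizer is decoupled
weight-decay Adam with linear learning-rate decay and global-norm
gradient clipping at 1.0 (clipping existed in the source's pre-training;
the value is unstated — 1.0 is the package default and is disabled in
fine-tuning).

## Fine-tuning

Three task formats share one pre-trained encoder:

* **per-residue** — single mutated sequence; every residue is labeled
  benign except the mutation site, which carries the example's class;
  loss and gradients touch only the site logit (tested: non-site rows of
  the loss gradient are exactly zero);
* **single sequence** — whole-sequence classification from the pooled
  final-layer `[CLS]` vector (dense + tanh pooler, the BERT convention —
  the source names only "the [CLS] embedding");
* **paired** — reference and mutated sequence concatenated with segment
  ids 0/1, classified from `[CLS]`.

Schedules follow the published convention: linear decay between initial
and end learning rates, weight decay 0.01, no gradient clipping,
independently shuffled epochs, optional layer freezing (freezing n > 0
encoder layers also freezes embeddings and convolutions; heads stay
trainable), and checkpoint selection by best held-out ROC AUC among the
requested evaluation steps.

Training-time augmentation trims a datapoint with probability 0.5 to a
uniform length in `[ceil(0.5 L), L]`. The window is placed so the site
keeps its original *relative* position (a plain center crop would drive
the mean relative position to 0.5, contradicting the stated "on average
stayed in the same location"); boundary sentinels are recomputed from the
crop. The uniform length distribution and the per-epoch (rather than
once-per-datapoint) alteration draw are package choices.

## External-score fusion and evaluation

Raw scores from external predictors are mapped per method onto `[1, 2]`
(affine over the observed or a supplied reference range), with missing
predictions exactly 0 — so "missing" is disjoint from every real score.
A dense layer lifts the external vector to width H; its output is
concatenated with the pooled sequence vector (width H + H), and a final
dense layer yields the probability, capping sequence-vs-external capacity
at about 1:1. `weighting_analysis()` reports the normalized split of the
output layer's absolute weights at the concatenation boundary (the
source's "weighting sum over both layers" has no formula; an all-zero
combining layer forces the external share to zero).

For comparing methods, scores are standardized to `[0, 1]` against a
reference distribution, missing = 0, and each method's orientation
(higher = deleterious vs. inverted) is chosen by training-set ROC AUC
with ties keeping the non-inverted identity.

Statistics: ROC AUC via the Mann-Whitney statistic with tied-score
grouping; precision-recall-gain curves with
`pg = (prec - pi)/((1 - pi) prec)`, `rg = (rec - pi)/((1 - pi) rec)`,
trapezoid area over `rg` in `[0, 1]` (raw value may be negative; display
value clipped at 0); the DeLong test in placement-value form with a
two-sided normal p (degenerate variance returns p = 1 with a warning);
and, for negatives-only evaluation sets, specificity at the threshold
closest to the ROC corner (0, 1) on labeled training data. Tie handling
and the PRG integration grid are standard choices not fixed by the
source; all four statistics are verified against independent brute-force
oracles in the test suite.

## The synthetic world

`generate_proteome()` and friends produce the smallest world with the
statistical structure the method assumes: sequences i.i.d. from a
background residue distribution (default uniform over the 20 amino
acids), one conserved motif (default `WDWDW`) planted per protein at a
recorded position, common benign variation only outside motifs (2% of
off-motif residues in the tests), and labeled variants under a
deterministic, sequence-local rule — deleterious iff the substitution
falls inside the motif. The rule is local by design so a small-context
model can learn it at desk scale, and its Bayes AUC is 1, so a held-out
AUC near 1 is attainable in principle. External scores are Gaussian
class-conditional with separation `signal` (AUC = `pnorm(signal/sqrt 2)`)
on method-specific raw scales with controllable missingness.

What a green end-to-end test establishes: the encoder, both training
loops, and the heads can extract a planted sequence-local signal
(held-out AUC at or above 0.9 with a 2-layer, H = 32 model after ~2k
pre-training and 1k fine-tuning steps). What it does not establish:
performance on real proteomes, long-range structural effects, realistic
allele frequencies, or the published AUC levels — those require the
restricted databases and accelerator-scale models that are explicitly out
of scope.

## Numerical choices and limitations

* Everything is double precision, pure R, seeded through R's RNG; fixed
  seeds give bit-identical metric traces on one machine.
* Layer-norm epsilon 1e-12; GELU is the exact Gaussian form; weight decay
  applies to matrices only; initialization is truncated normal (sd 0.02,
  clipped at 2 sd), the BERT convention (the source does not state one).
* Head count defaults to 12 at H = 768 (BERT-Base convention; unstated in
  the source) and must divide H.
* Softmax attention masks pads with an additive -1e9; at double precision
  the padded probabilities underflow to exactly zero.
* Tiny-scale schedules in tests (lr 1e-3, batch 8) are deliberate: the
  published 1e-5 rates belong to H = 768 models and would not move an
  H = 32 model in 1k steps.
* The quadratic cost of attention (and R-level loops over batch and
  heads) limits practical capacity to a few hundred tokens on one CPU;
  paper-scale pre-training is out of scope.
* Parameter accounting reproduces the published MutBERT sizes (58M at 8
  layers, 72M at 10 layers, H = 768); the published totals for the
  conv-bearing variants are not recoverable from the stated convolution
  shapes and are checked against this package's own closed form instead.
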
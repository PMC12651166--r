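---
title: "Model and methods behind dtifuse"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Model and methods behind dtifuse}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The prediction problem

`dtifuse` models drug–target interaction (DTI) as binary classification: given
a small molecule (a SMILES string) and a protein (an amino-acid sequence), it
predicts the probability that the pair interacts. The architecture combines
three ideas: *coordinate attention* on the protein map, so that positional and
directional information along the chain (its N-to-C orientation) survives the
encoding; *multi-scale feature fusion* on both branches, so that local motifs
and broader context are mixed before the two modalities meet; and
*cross-attention*, so that each modality's representation is conditioned on
the other before classification.

## Drug branch

A SMILES string is parsed (via OpenBabel, through ChemmineR/ChemmineOB) into a
molecular graph. Every atom receives a 74-dimensional feature vector laid out
as: atom-type one-hot (43 = 42 element symbols + "other"), heavy-atom degree
one-hot (0–10), implicit-valence one-hot (0–6), formal charge, radical
electron count, hybridization one-hot (SP, SP2, SP3, SP3D, SP3D2), an
aromaticity flag, and total hydrogen count one-hot (0–4). This is the
canonical atom featurizer used throughout the graph-DTI literature; the block
widths are the only decomposition of 74 consistent with those feature
families. Aromaticity and hybridization come from OpenBabel's own perception
(SYBYL atom types in MOL2 output); implicit hydrogen counts are derived from
standard valence rules on the kekulized bond list, because an SDF cannot carry
them explicitly. The supported chemistry is organic small molecules; exotic
elements fall into the "other" atom-type bit.

The padded node-feature matrix `M_d` (capacity `n_d` atoms; larger molecules
are *rejected*, never truncated) passes through three graph-convolution
layers `H^(l+1) = ReLU(A H^(l) W^(l) + b^(l))`, where `A` is the self-loop
adjacency, by default symmetrically degree-normalized
(`normalize_adjacency`); the literal unnormalized form is available as a
configuration flag. Padding rows are re-zeroed after every layer, which is
what makes the padding-invariance property below hold exactly. The node set
is then laid out row-major on an `H x W` grid (square by default,
`grid_w_drug` configurable) so the same spatial fusion block can serve both
branches.

## Protein branch

Sequences are tokenized over a 22-symbol vocabulary: the 20 standard
residues, `X` for anything else, and a dedicated pad token whose embedding
contribution is forced to zero. A learnable `22 x D` table embeds the
sequence; the result is reshaped row-major to a `D x H x W` map
(`theta_p = H*W` positions). An optional stack of sigmoid-gated 1-D
convolutions (`gated_conv`, off by default) can pre-mix neighboring residues;
it is disabled in the minimal path because its internal design is
architecturally underdetermined, and the switch lets both readings be tested.

Coordinate attention then pools the map along each spatial direction
(masked means, so padding never contributes), concatenates the two pooled
profiles, reduces channels by `r = ca_reduction` through a shared 1x1
transform with ReLU, splits the result back into the two directions, and
produces per-direction sigmoid gates. Every cell is re-weighted by the
product of its row gate and column gate. Because the gates are strictly
inside (0,1), the output is always attenuated (`|y| <= |x|`), and because
pooling groups positions by grid rows/columns, permuting residues along the
sequence does change the output — the block is position-aware by
construction, which the test suite asserts as an inequality.

## Multi-scale fusion

The shared fusion block splits channels into `G` contiguous groups and, per
group: (a) a 1x1 path driven by the concatenated directional average pools
produces sigmoid gates whose re-weighted map is group-normalized (statistics
over the group's valid cells only); (b) a parallel 3x3 convolution captures
spatial context; (c) the two branches exchange attention — each branch's
per-channel spatial-mean descriptor is softmax-normalized and contracted
against the other branch's map — and the summed cross-responses pass through
a sigmoid that gates the input. The layout follows the efficient multi-scale
attention design with grouped 1x1/3x3 branches; where the block's publication
lineage leaves the exact count and order of normalization layers open, we
fixed the arrangement above and froze it with regression tests. `G` defaults
to 4 on the drug grid and 8 on the protein map (4 in the desk profile so the
32-channel maps keep 8 channels per group).

## Interaction fusion and head

With drug features `F_D` and protein features `F_P`, queries and keys are
linear projections of width `d_k`, and attention is scaled dot-product with
padding keys masked to -inf before the softmax. As printed in the formulation
this work follows, the softmax output would be a `N_d x theta_p` weight
matrix that cannot be added to `F_D`; the only shape-consistent reading maps
the weights through a value projection of the opposite modality
(`Z_D = softmax(Q_D K_P^T / sqrt(d_k)) (F_P W_P^v)`, and symmetrically
`Z_P`), which is the standard attention form and is what `dtifuse`
implements. The fused representations are the *equal-weight* residual mixes
`D_f = 0.5 Z_D + 0.5 F_D` and `P_f = 0.5 Z_P + 0.5 F_P` — forcing the
attention output to zero halves the representation exactly, a constant the
acceptance suite checks. Global max-pooling over valid positions and
concatenation (drug first) give the pair vector, which feeds a ReLU MLP
(hidden widths `head_dims`, dropout 0.1 during training) ending in a single
sigmoid unit. Training minimizes mean binary cross-entropy; the loss is
computed on logits for numerical stability, and the exported
`bce_loss()` clips probabilities at 1e-7.

## Ablation variants

Three variants rewire the architecture (never the data handling):

* `Noco` — coordinate attention replaced by a position-independent linear
  layer of matching shape;
* `single` — both multi-scale fusion blocks removed (no fusion parameters
  exist in the checkpoint);
* `NoCross` — cross-attention removed; the pooled branch outputs are
  concatenated directly, so the variant has strictly fewer parameters.

## Training and evaluation

Optimization is Adam (`lr`, `batch_size`, epoch cap, early stopping on
validation AUROC with `patience`), fully seeded: initialization, the
stratified 8:1:1 split, batch shuffling and dropout all derive from
`config$seed`, and repeated runs are bit-identical. Gradients flow through a
reverse-mode differentiation tape written in base R (no deep-learning
framework is required at run time); every primitive's backward pass and the
assembled model's gradients are validated against central finite differences
in the test suite, so training optimizes exactly the architecture the
forward pass defines. Metrics are AUROC (rank statistic), AUPRC (step-wise
average precision), and thresholded accuracy, F1 and MCC; all are checked
exactly against pair-enumeration and confusion-matrix oracles. With
single-class labels the ranking metrics are reported as `NA`, never 0.

## Synthetic study conditions

Because public DTI benchmarks require large downloads and long training, the
package ships a planted-rule generator that emulates their *shape* offline:
drugs are random C/N/O trees (optionally with benzene rings) from a fragment
grammar capped at 40 heavy atoms, a carboxylic-acid motif is attached to a
controlled fraction; proteins are uniform-random 50–60-mers with a short
residue motif (`HKH`) spliced into a controlled fraction. A pair is positive
iff *both* motifs are present (so both encoders, and their fusion, carry
signal), labels are flipped independently at `noise_rate`, and pairs are
sampled to hit the target class balance exactly. The reference conditions
used by the acceptance suite are 2,000 pairs, 5% label noise, balanced
classes. What passing these tests shows is that the architecture can extract
and fuse a two-sided signal through every module; it does not show benchmark
performance on real chemistry — the generator has no binding physics, no
realistic chemical diversity, and motif detection is far easier than binding
prediction.

## Problem sizes and profiles

The `"paper"` profile mirrors benchmark-scale capacities (molecules to 290
atoms, proteins to 1,024 residues, 128-dimensional features, head 512/256,
Adam at 1e-4). The `"desk"` profile is the package's own choice of problem
size for the bundled synthetic conditions: capacities 49 atoms / 64 residues
(the generator never exceeds them), 32-dimensional features, head 64/32, and
Adam at 2e-3 for at most 25 epochs — on these small, strongly-signaled
datasets the larger step converges in a handful of epochs and the full
learnability run completes in minutes on one CPU. All tests and the
acceptance script use the desk profile; nothing in the architecture differs
between profiles.

## Numerical choices and degenerate inputs

* Attention masking uses an additive -1e30 on padded keys; after the softmax
  those weights are exactly 0 in double precision.
* Group normalization uses eps = 1e-5 and masked statistics; fully-masked
  pooling rows/columns yield 0 rather than NaN.
* Max-pooling ties take the first (lowest-index) maximizer.
* Interpretation flags, per response dimension, the `ceiling(0.3 * L)`
  highest-activation residues; ties break toward the lower position index.
  The response tensor is the fused protein representation `P_f` (the
  protein-side features that have absorbed drug conditioning); a raw
  cross-attention scorer (`source = "crossattn"`) ships behind a flag for
  comparison, since either reading of "response" is defensible.
* Degenerate requests error loudly: empty sequences, unparsable SMILES,
  molecules over capacity, all-masked attention keys, single-class AUROC.

## Known limitations

* The 74-dimensional featurization covers atom identity and local valence
  state only — no bond features, chirality or 3-D conformers.
* Reshaping a 1-D sequence to a 2-D grid is a modeling device; the grid axes
  have no direct biological meaning, and the package implements the literal
  reshape (row-major, fixed width) for reproducibility.
* The base-R training loop is adequate for desk-scale experiments (thousands of
  pairs, tens of epochs); benchmark-scale corpora would need a compiled or
  GPU backend behind the same interfaces.
* Hybridization/aromaticity reflect OpenBabel's perception model, which can
  differ from other toolkits on unusual ring systems.
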
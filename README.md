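# dtifuse

Drug–target interaction (DTI) prediction in R: molecular-graph drug encoding,
coordinate-attention protein encoding, multi-scale feature fusion on both
branches, cross-attention interaction fusion, and a sigmoid classification
head — trained end to end with a built-in reverse-mode differentiation tape
and Adam, with no deep-learning framework dependency.

## Who this is for

Computational chemists and method developers who want a fully inspectable,
pure-R reference implementation of an attention-based DTI architecture: every
layer is a few lines of matrix algebra, every gradient is finite-difference
validated, and the whole pipeline (data generation → training → evaluation →
interpretation) runs offline in minutes.

## The model

A pair (SMILES `s`, sequence `P`) is scored as follows:

* **Drug branch.** `s` is parsed into a molecular graph; each atom gets a
  74-dimensional feature vector (atom type, degree, implicit valence, formal
  charge, radicals, hybridization, aromaticity, hydrogen count). Three graph
  convolutions `H^(l+1) = ReLU(Ã H^(l) W^(l) + b^(l))` over the self-loop
  (degree-normalized) adjacency produce node states `F_D`, refined by a
  grouped multi-scale fusion block on a 2-D node grid.
* **Protein branch.** `P` is tokenized over a 22-symbol vocabulary
  (20 residues + unknown + pad) and embedded via a learnable `22 × D` table;
  the `θ_p × D` sequence map is reshaped to `D × H × W` and re-weighted by
  coordinate attention — directional average pooling, a shared 1×1 reduction,
  and per-direction sigmoid gates `y_c(i,j) = x_c(i,j) · g_h(c,i) · g_w(c,j)`
  — then passed through the same fusion block, giving `F_P`.
* **Interaction fusion.** Scaled dot-product cross-attention in both
  directions (`Z_D = softmax(Q_D K_P^T / √d_k) V_P`, symmetrically `Z_P`),
  equal-weight residual mixes `D_f = 0.5·Z_D + 0.5·F_D`,
  `P_f = 0.5·Z_P + 0.5·F_P`, masked global max-pooling, concatenation, and a
  ReLU MLP ending in `p = σ(W f + b)`, trained with mean binary
  cross-entropy.
* **Ablations.** `Noco` (coordinate attention → linear layer), `single` (no
  multi-scale fusion), `NoCross` (no cross-attention) rewire the graph for
  controlled comparisons.
* **Interpretation.** Per response dimension of `P_f`, the top 30% of residue
  positions are flagged; per-residue intensities and contiguous high-response
  runs export as TSV/BED.

See `vignettes/dtifuse-methods.Rmd` for assumptions, defaults and
limitations.

## Worked example

```r
library(dtifuse)

## a planted-rule synthetic dataset: label = 1 iff the drug carries a
## carboxylic acid AND the protein contains the HKH motif, 5% label noise
pairs <- synth_pairs(2000, seed = 11)
head(pairs, 3)
#>                 smiles                                                   sequence label
#> 1           OC(=O)O(C)        VVIIDTHEMTRVNKFHMERTSPWAGRINLERTTKHLAGKRLTRVAHREKDG     0
#> 2 OC(=O)C(c1ccccc1)(N) CLNFHPTRQGDKNLMEVILKHDFMARYEGHIVFKCMWTLICEKDMAKELFQMEYVQCQ     0
#> 3              OC(=O)C        DRVQWIKYAWHKHEYHEITSDSISMAYTVEAAVNWHTWMLMSGPASMCNTH     1

cfg <- dti_config(profile = "desk", seed = 1)   # desk-scale: D = 32, <= 25 epochs
fit <- dti_fit(pairs, cfg, verbose = TRUE)
#> epoch   1 | loss 0.5829 | val AUROC 0.7753
#> epoch   2 | loss 0.4710 | val AUROC 0.7705
#> ...
#> epoch  10 | loss 0.2598 | val AUROC 0.9118
#> ...
#> epoch  15 | loss 0.2257 | val AUROC 0.9061

print(fit)
#> Drug-target interaction model (full variant, desk profile)
#>   19429 parameters in 37 tensors; trained 15 epoch(s), best epoch 10
#>   test: n = 200 (threshold 0.50): AUROC 0.9626 | AUPRC 0.9621 | Acc 0.8900 | F1 0.8972 | MCC 0.7878
```

The test AUROC (here 0.963) is the held-out ranking quality on the 10% test
split: the trained model separates interacting from non-interacting pairs
almost perfectly despite the injected label noise. Accuracy/F1/MCC use the
0.5 threshold.

```r
## score a new pair, inspect where the protein responds
p <- predict(fit, smiles = "OC(=O)CCN", sequence = pairs$sequence[1])
rmap <- response_map(fit, "OC(=O)CCN", pairs$sequence[1])
export_regions(rmap, "intensity.tsv", "regions.bed")

## ablation comparison on identical splits and seed
noco <- run_ablation("Noco", pairs, cfg)
```

A thin CLI wraps the same functions
(`Rscript inst/cli/dtifuse.R synth|train|eval|predict|ablate|regions ...`).

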
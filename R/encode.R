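# User-facing encoder entry points and the array-interface wrapper of the
# multi-scale fusion block. All three run the same tape code the trained
# model uses, evaluated without gradients.

#' Encode a drug molecule
#'
#' Runs the drug branch of a fitted model (three GCN layers and, unless the
#' `"single"` variant is configured, multi-scale fusion on the node grid) and
#' returns the node feature map `F_D`.
#'
#' @param model A fitted `dti_model` (or a list with `theta` and `config`).
#' @param smiles A single SMILES string.
#' @return Matrix `P x D` of node states (grid positions as rows; only the
#'   first `n_atoms` rows are real, see `attr(, "n_atoms")`).
#' @export
encode_drug <- function(model, smiles) {
  cfg <- model$config
  prep <- prepare_records(data.frame(smiles = smiles, sequence = "A",
                                     label = 0L), cfg)[[1]]
  tp <- ad_tape(0L, grad = FALSE)
  out <- ad_value(tape_drug_branch(tp, model$theta, prep, cfg))
  attr(out, "n_atoms") <- length(prep$std$valid)
  out
}

#' Encode a protein sequence
#'
#' Runs the protein branch of a fitted model (embedding, optional gated
#' convolutions, coordinate attention, multi-scale fusion) and returns the
#' residue feature map `F_P`.
#'
#' @param model A fitted `dti_model`.
#' @param sequence A single amino-acid string.
#' @return Matrix `P x D` of residue states; only the first
#'   `attr(, "length")` rows correspond to real residues.
#' @export
encode_protein <- function(model, sequence) {
  cfg <- model$config
  prep <- prepare_records(data.frame(smiles = "C", sequence = sequence,
                                     label = 0L), cfg)[[1]]
  tp <- ad_tape(0L, grad = FALSE)
  out <- ad_value(tape_protein_branch(tp, model$theta, prep, cfg))
  attr(out, "length") <- length(prep$stp$valid)
  out
}

#' Initialize multi-scale fusion parameters
#'
#' Glorot-uniform weights for one fusion block operating on groups of
#' `cg = C / G` channels: the 1x1 transform consuming the concatenated
#' directional pools (`hw_w`, `hw_b`), the 3x3 convolution (`conv_w`,
#' `conv_b`) and the group-norm affine (`gn_g`, `gn_b`).
#'
#' @param cg Channels per group.
#' @return Named list of parameter matrices.
#' @export
fusion_params <- function(cg) init_fusion_params(cg)

#' Multi-scale feature fusion
#'
#' The shared fusion block applied to a `(C, H, W)` map: channels are split
#' into `G` contiguous groups; within each group two 1x1 paths driven by
#' directional average pooling produce sigmoid gates whose re-weighted map is
#' group-normalized, a parallel 3x3 convolution captures spatial context, and
#' the two branches exchange attention through softmax-normalized per-channel
#' descriptors before a final sigmoid-gated multiplication with the input.
#' Output dimensions equal input dimensions.
#'
#' @param x `(C, H, W)` array.
#' @param params Parameters from [fusion_params()] (per-group, shared across
#'   groups).
#' @param G Number of channel groups; `C` must be divisible by `G`.
#' @return `(C, H, W)` array.
#' @export
fuse <- function(x, params, G = 1L) {
  d <- dim(x)
  stopifnot(length(d) == 3)
  if (d[1] %% G != 0) stop("channel count not divisible by G")
  if (d[2] < 3 || d[3] < 3) {
    stop("3x3 convolution kernel exceeds the spatial extent ",
         d[2], "x", d[3])
  }
  X <- matrix(aperm(x, c(3, 2, 1)), d[2] * d[3], d[1])
  st <- grid_structures(d[2], d[3], d[2] * d[3], G)
  th <- params
  names(th) <- fusion_param_names("f")
  tp <- ad_tape(0L, grad = FALSE)
  out <- ad_value(tape_fusion(tp, X, th, "f", st))
  aperm(array(out, c(d[3], d[2], d[1])), c(3, 2, 1))
}
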
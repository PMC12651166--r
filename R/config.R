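#' Model configuration
#'
#' Collects every architecture and training hyperparameter of the predictor in
#' one list, with validated defaults. Two profiles are provided: `"paper"`,
#' sized for benchmark-scale corpora (proteins up to 1024 residues, molecules
#' up to 290 atoms, 128-dimensional features), and `"desk"`, a small
#' configuration sized for the bundled synthetic datasets (proteins up to 64
#' residues, molecules up to 49 atoms, 32-dimensional features) so that a full
#' training run completes in seconds to minutes on one CPU.
#'
#' @param profile Either `"paper"` or `"desk"`; selects the default sizes
#'   before `...` overrides are applied.
#' @param ... Named overrides for any configuration key, e.g. `n_d = 100`,
#'   `ablation = "Noco"`.
#'
#' @details Keys (defaults for the `"paper"` profile in parentheses):
#' \describe{
#'   \item{n_d}{maximum atoms per molecule; larger molecules are rejected (290).}
#'   \item{theta_p}{maximum protein length in residues; longer sequences are
#'     truncated with a warning (1024).}
#'   \item{grid_w_drug, grid_w_protein}{width W of the 2-D map each branch is
#'     reshaped to before spatial attention; the height is
#'     `ceiling(positions / W)` and the map is zero-padded and masked. Defaults
#'     are the square roots of the padded sizes (18 and 32).}
#'   \item{d_model}{feature width D shared by both branches after encoding (128).}
#'   \item{d_k}{query/key width of cross-attention (equal to `d_model`).}
#'   \item{normalize_adjacency}{symmetric degree normalization of the
#'     self-loop-augmented adjacency before graph convolution (TRUE).}
#'   \item{groups_drug, groups_protein}{channel groups G of the multi-scale
#'     fusion block on each branch (4 and 8).}
#'   \item{ca_reduction}{channel reduction ratio r of the shared 1x1 transform
#'     inside coordinate attention (8).}
#'   \item{gated_conv, gated_conv_depth}{optional stack of sigmoid-gated 1-D
#'     convolutions applied to the embedded sequence before the spatial
#'     reshape (disabled, depth 2).}
#'   \item{head_dims}{hidden widths of the classification MLP (512, 256).}
#'   \item{dropout}{dropout rate in the head during training (0.1).}
#'   \item{ablation}{one of `"full"`, `"Noco"` (coordinate attention replaced
#'     by a position-independent linear layer), `"single"` (multi-scale fusion
#'     removed), `"NoCross"` (cross-attention removed; pooled features are
#'     concatenated directly).}
#'   \item{lr, batch_size, epochs, patience}{Adam learning rate (1e-4), batch
#'     size (32), epoch cap (50) and early-stopping patience on validation
#'     AUROC (10).}
#'   \item{threshold}{probability cutoff for accuracy/F1/MCC (0.5).}
#'   \item{split}{train/validation/test fractions (0.8, 0.1, 0.1).}
#'   \item{seed}{integer seed controlling initialization, batching and dropout.}
#' }
#'
#' @return A list of class `"dti_config"`.
#' @export
#' @examples
#' cfg <- dti_config(profile = "desk", ablation = "Noco")
#' cfg$d_model
dti_config <- function(profile = c("paper", "desk"), ...) {
  profile <- match.arg(profile)
  cfg <- list(
    profile = profile,
    n_d = 290L,
    theta_p = 1024L,
    grid_w_drug = NA_integer_,     # NA -> square grid
    grid_w_protein = NA_integer_,
    d_model = 128L,
    d_k = 128L,
    normalize_adjacency = TRUE,
    groups_drug = 4L,
    groups_protein = 8L,
    ca_reduction = 8L,
    gated_conv = FALSE,
    gated_conv_depth = 2L,
    head_dims = c(512L, 256L),
    dropout = 0.1,
    ablation = "full",
    lr = 1e-4,
    batch_size = 32L,
    epochs = 50L,
    patience = 10L,
    threshold = 0.5,
    split = c(train = 0.8, valid = 0.1, test = 0.1),
    seed = 1L
  )
  if (profile == "desk") {
    cfg$n_d <- 49L
    cfg$theta_p <- 64L
    cfg$d_model <- 32L
    cfg$d_k <- 32L
    cfg$groups_protein <- 4L
    cfg$head_dims <- c(64L, 32L)
    cfg$lr <- 2e-3
    cfg$epochs <- 25L
    cfg$patience <- 5L
  }
  dots <- list(...)
  unknown <- setdiff(names(dots), names(cfg))
  if (length(unknown)) {
    stop("unknown configuration key(s): ", paste(unknown, collapse = ", "))
  }
  cfg[names(dots)] <- dots
  validate_config(structure(cfg, class = "dti_config"))
}

validate_config <- function(cfg) {
  stopifnot(cfg$n_d >= 1, cfg$theta_p >= 1, cfg$d_model >= 1, cfg$d_k >= 1)
  if (!cfg$ablation %in% c("full", "Noco", "single", "NoCross")) {
    stop("ablation mode must be one of full, Noco, single, NoCross; got ",
         cfg$ablation)
  }
  if (abs(sum(cfg$split) - 1) > 1e-8) stop("split fractions must sum to 1")
  if (cfg$d_model %% cfg$groups_drug != 0 || cfg$d_model %% cfg$groups_protein != 0) {
    stop("d_model must be divisible by both group counts")
  }
  if (cfg$d_model %/% max(1L, cfg$ca_reduction) < 1) {
    stop("ca_reduction too large for d_model")
  }
  cfg
}

#' @export
print.dti_config <- function(x, ...) {
  cat("Drug-target interaction model configuration (profile: ",
      x$profile, ")\n", sep = "")
  cat(sprintf("  molecule capacity    : %d atoms (grid W = %d)\n",
              x$n_d, grid_dims(x$n_d, x$grid_w_drug)["w"]))
  cat(sprintf("  protein capacity     : %d residues (grid W = %d)\n",
              x$theta_p, grid_dims(x$theta_p, x$grid_w_protein)["w"]))
  cat(sprintf("  feature width        : %d, cross-attention d_k = %d\n",
              x$d_model, x$d_k))
  cat(sprintf("  fusion groups        : drug %d / protein %d\n",
              x$groups_drug, x$groups_protein))
  cat(sprintf("  ablation             : %s\n", x$ablation))
  cat(sprintf("  optimizer            : Adam lr %.2g, batch %d, <=%d epochs, patience %d\n",
              x$lr, x$batch_size, x$epochs, x$patience))
  invisible(x)
}

# Resolve the (H, W) spatial factorization for `n` positions. W defaults to
# ceiling(sqrt(n)); H = ceiling(n / W). The map holds H*W >= n cells, the tail
# masked out.
grid_dims <- function(n, w = NA_integer_) {
  if (is.na(w)) w <- as.integer(ceiling(sqrt(n)))
  if (w < 1 || w > n) stop("grid width must be in [1, n]")
  h <- as.integer(ceiling(n / w))
  c(h = h, w = as.integer(w))
}

#' Read or write a configuration as YAML
#'
#' @param path File path.
#' @return `read_config()` returns a `dti_config`; `write_config()` its path,
#'   invisibly.
#' @export
read_config <- function(path) {
  raw <- yaml::read_yaml(path)
  profile <- raw$profile %||% "paper"
  raw$profile <- NULL
  raw$split <- unlist(raw$split)
  do.call(dti_config, c(list(profile = profile), raw))
}

#' @rdname read_config
#' @param cfg A `dti_config` object.
#' @export
write_config <- function(cfg, path) {
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
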
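# Protein sequence handling: 22-symbol vocabulary (20 standard residues,
# unknown 'X', pad), token encoding, embedding lookup, and the row-major
# reshape of the embedded sequence to a 2-D channels x H x W map.

AA_LETTERS <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
                "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

#' Amino-acid vocabulary
#'
#' The 22-symbol protein vocabulary: the 20 standard residues, `"X"` for any
#' unknown letter, and a padding token. Token indices are 1-based; the pad
#' token is index 22 and always maps to a zero embedding.
#'
#' @return Character vector of length 22 (`"<pad>"` last).
#' @export
aa_vocabulary <- function() c(AA_LETTERS, "X", "<pad>")

AA_UNKNOWN <- 21L
AA_PAD <- 22L

#' Token-encode an amino-acid sequence
#'
#' @param sequence A single amino-acid string (case-insensitive). Letters
#'   outside the 20 standard residues map to the unknown token.
#' @param theta_p Fixed encoded length; longer sequences are truncated with a
#'   warning, shorter ones padded with the pad token.
#' @return A list with `tokens` (integer, length `theta_p`), `valid_mask`
#'   (0/1, length `theta_p`) and `length` (residues kept).
#' @export
tokenize_sequence <- function(sequence, theta_p = 1024L) {
  stopifnot(length(sequence) == 1)
  sequence <- toupper(trimws(sequence))
  if (!nzchar(sequence)) stop("empty protein sequence")
  letters_ <- strsplit(sequence, "")[[1]]
  if (length(letters_) > theta_p) {
    warning("sequence of length ", length(letters_), " truncated to theta_p = ",
            theta_p)
    letters_ <- letters_[seq_len(theta_p)]
  }
  tok <- match(letters_, AA_LETTERS)
  tok[is.na(tok)] <- AA_UNKNOWN
  n <- length(tok)
  list(tokens = c(tok, rep(AA_PAD, theta_p - n)),
       valid_mask = c(rep(1, n), rep(0, theta_p - n)),
       length = n)
}

#' Embed a protein sequence
#'
#' Looks up each token of the encoded sequence in a learnable `22 x D_p`
#' embedding table. Padding positions always receive a zero embedding
#' regardless of the table's pad row.
#'
#' @param sequence Amino-acid string.
#' @param table Numeric `22 x D_p` embedding matrix.
#' @param theta_p Fixed encoded length.
#' @return A list of class `"protein_tensor"`: `tokens`, `valid_mask`,
#'   `sequence_features` (`theta_p x D_p`), `embedding_matrix`, `length`.
#' @export
#' @examples
#' pt <- embed_sequence("ACDEFG", diag(22), theta_p = 9)
#' rowSums(pt$sequence_features)  # 6 one-hot rows, 3 zero pad rows
embed_sequence <- function(sequence, table, theta_p = 1024L) {
  if (nrow(table) != 22L) {
    stop("embedding table must have exactly 22 rows, got ", nrow(table))
  }
  enc <- tokenize_sequence(sequence, theta_p)
  feats <- table[enc$tokens, , drop = FALSE] * enc$valid_mask
  structure(list(tokens = enc$tokens, valid_mask = enc$valid_mask,
                 sequence_features = feats, embedding_matrix = table,
                 length = enc$length),
            class = "protein_tensor")
}

#' Read protein sequences from a FASTA file
#'
#' @param path Path to a FASTA file.
#' @return Named character vector of sequences.
#' @export
read_fasta <- function(path) {
  if (!requireNamespace("Biostrings", quietly = TRUE)) {
    stop("reading FASTA requires the Biostrings package")
  }
  set <- Biostrings::readAAStringSet(path)
  stats::setNames(as.character(set), names(set))
}

# Position p (1-based, along the sequence) maps row-major to grid cell
# (h, w) = ((p-1) %/% W + 1, (p-1) %% W + 1). These helpers build the
# constant matrices that express directional pooling and gate broadcasting
# as matrix products on a P x C activation (P = H*W positions as rows).

# H x P averaging matrix along the width direction, weighted by the mask;
# fully-masked rows give zero.
pool_rows_matrix <- function(h, w, mask = NULL) {
  P <- h * w
  if (is.null(mask)) mask <- rep(1, P)
  M <- matrix(0, h, P)
  hidx <- (seq_len(P) - 1L) %/% w + 1L
  M[cbind(hidx, seq_len(P))] <- mask
  rs <- rowSums(M)
  M[rs > 0, ] <- M[rs > 0, , drop = FALSE] / rs[rs > 0]
  M
}

# W x P averaging matrix along the height direction.
pool_cols_matrix <- function(h, w, mask = NULL) {
  P <- h * w
  if (is.null(mask)) mask <- rep(1, P)
  M <- matrix(0, w, P)
  widx <- (seq_len(P) - 1L) %% w + 1L
  M[cbind(widx, seq_len(P))] <- mask
  rs <- rowSums(M)
  M[rs > 0, ] <- M[rs > 0, , drop = FALSE] / rs[rs > 0]
  M
}

# P x H / P x W broadcast (0/1) matrices: expand per-row / per-column gates
# to every position.
expand_rows_matrix <- function(h, w) {
  P <- h * w
  M <- matrix(0, P, h)
  M[cbind(seq_len(P), (seq_len(P) - 1L) %/% w + 1L)] <- 1
  M
}

expand_cols_matrix <- function(h, w) {
  P <- h * w
  M <- matrix(0, P, w)
  M[cbind(seq_len(P), (seq_len(P) - 1L) %% w + 1L)] <- 1
  M
}

# P x K neighbor table of the 3x3 stencil on an h x w grid (row-major
# positions); 0 marks cells outside the grid (zero padding).
neighbors_3x3 <- function(h, w) {
  P <- h * w
  hh <- (seq_len(P) - 1L) %/% w + 1L
  ww <- (seq_len(P) - 1L) %% w + 1L
  offsets <- expand.grid(dh = -1:1, dw = -1:1)
  nbr <- matrix(0L, P, 9L)
  for (k in seq_len(9L)) {
    nh <- hh + offsets$dh[k]
    nw <- ww + offsets$dw[k]
    ok <- nh >= 1 & nh <= h & nw >= 1 & nw <= w
    nbr[ok, k] <- (nh[ok] - 1L) * w + nw[ok]
  }
  nbr
}

# P x 3 neighbor table of the 1-D stencil along the sequence.
neighbors_1d3 <- function(P) {
  nbr <- cbind(seq_len(P) - 1L, seq_len(P), seq_len(P) + 1L)
  nbr[nbr < 1L | nbr > P] <- 0L
  nbr
}
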
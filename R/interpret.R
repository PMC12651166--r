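# High-response region extraction: which residues of a protein respond most
# strongly to a drug under a trained model. Per response dimension, the top
# 30% (configurable) of residue positions are flagged; a residue's intensity
# is the fraction of dimensions flagging it.

#' Per-residue response map of a protein to a drug
#'
#' Runs the forward pass for one (drug, protein) pair, captures the fused
#' protein-side representation `P_f` on the valid residues (or, with
#' `source = "crossattn"`, the raw cross-attention output `Z_P`), and flags,
#' independently in each of the `D` response dimensions, the
#' `ceiling(q * L)` residues with the highest activation. Ties break toward
#' the lower position index. A residue's intensity is the fraction of
#' dimensions in which it is flagged, so intensities lie in `[0, 1]` and a
#' residue dominant in every dimension scores exactly 1.
#'
#' @param model A fitted `dti_model`.
#' @param smiles Drug SMILES string.
#' @param sequence Protein sequence (must fit within `config$theta_p`).
#' @param q Top quantile flagged per dimension (default 0.30).
#' @param source `"fused"` for `P_f` (default) or `"crossattn"` for `Z_P`.
#' @return Object of class `"response_map"`: `response` (`L x D`),
#'   `high_flags` (logical `L x D`), `intensity` (length `L`), `q`,
#'   `sequence`.
#' @export
response_map <- function(model, smiles, sequence, q = 0.30,
                         source = c("fused", "crossattn")) {
  source <- match.arg(source)
  cfg <- model$config
  if (nchar(sequence) > cfg$theta_p) {
    stop("sequence of length ", nchar(sequence),
         " exceeds the configured capacity theta_p = ", cfg$theta_p)
  }
  if (q <= 0 || q > 1) stop("q must be in (0, 1]")
  preps <- prepare_records(data.frame(smiles = smiles, sequence = sequence,
                                      label = 0L), cfg)
  p <- predict_prepared(model$theta, preps, cfg, capture = TRUE)
  cap <- attr(p, "captured")[[1]]
  resp_full <- if (source == "fused") cap$p_f else cap$z_p
  if (is.null(resp_full)) {
    stop("cross-attention responses are unavailable for the ",
         cfg$ablation, " variant")
  }
  L <- length(preps[[1]]$stp$valid)
  resp <- resp_full[seq_len(L), , drop = FALSE]
  flags <- flag_top_positions(resp, q)
  structure(list(response = resp, high_flags = flags,
                 intensity = rowSums(flags) / ncol(flags),
                 q = q, source = source, sequence = sequence,
                 probability = as.numeric(p)),
            class = "response_map")
}

# Flag the ceiling(q * L) largest entries of each column; ties prefer the
# lower row index.
flag_top_positions <- function(resp, q) {
  L <- nrow(resp)
  k <- ceiling(q * L)
  flags <- matrix(FALSE, L, ncol(resp))
  for (d in seq_len(ncol(resp))) {
    ord <- order(-resp[, d], seq_len(L))
    flags[ord[seq_len(k)], d] <- TRUE
  }
  flags
}

#' @export
print.response_map <- function(x, ...) {
  cat(sprintf(
    "response map (%s source): %d residues x %d dimensions, q = %.2f\n",
    x$source, nrow(x$response), ncol(x$response), x$q))
  top <- order(-x$intensity)[seq_len(min(5, length(x$intensity)))]
  cat("  highest-intensity residues:",
      paste(sprintf("%d (%.2f)", top, x$intensity[top]), collapse = ", "), "\n")
  invisible(x)
}

#' Export high-response regions
#'
#' Writes (1) a tab-separated per-residue table (1-based `position`,
#' `residue`, `intensity`, `high` flag) and (2) contiguous runs of residues
#' with intensity at or above `cutoff` as a 3-column BED file (0-based,
#' half-open intervals).
#'
#' @param map A [response_map()].
#' @param intensity_path Output path of the per-residue table.
#' @param bed_path Output path of the interval file.
#' @param cutoff Intensity threshold defining high-response runs.
#' @param name Region name used in the BED chrom column.
#' @return Invisibly, the data.frame of 1-based inclusive runs.
#' @export
export_regions <- function(map, intensity_path, bed_path, cutoff = 0.5,
                           name = "protein") {
  stopifnot(inherits(map, "response_map"))
  L <- length(map$intensity)
  res <- strsplit(map$sequence, "")[[1]][seq_len(L)]
  tab <- data.frame(position = seq_len(L), residue = res,
                    intensity = map$intensity,
                    high = as.integer(map$intensity >= cutoff))
  utils::write.table(tab, intensity_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  high <- map$intensity >= cutoff
  runs <- rle(high)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  keep <- runs$values
  iv <- data.frame(start = starts[keep], end = ends[keep])
  bed <- data.frame(chrom = rep(name, nrow(iv)), start = iv$start - 1L,
                    end = iv$end)
  utils::write.table(bed, bed_path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(iv)
}

#' Read back an exported interval file
#'
#' @param bed_path A BED file written by [export_regions()].
#' @return Data.frame of 1-based inclusive `start`, `end` runs.
#' @export
read_regions <- function(bed_path) {
  if (file.size(bed_path) == 0) return(data.frame(start = integer(0),
                                                  end = integer(0)))
  bed <- utils::read.table(bed_path, sep = "\t",
                           col.names = c("chrom", "start", "end"))
  data.frame(start = bed$start + 1L, end = bed$end)
}
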
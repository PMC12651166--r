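# Planted-rule synthetic data: parseable drug SMILES from a small fragment
# grammar, random protein sequences with an insertable residue motif, and
# pair labeling by the AND rule (drug substructure AND protein motif) with
# independent label noise. Stands in for benchmark corpora so the whole
# pipeline runs offline.

#' Define a planted decision rule
#'
#' @param drug_motif SMARTS pattern the positive-class drugs carry
#'   (default: carboxylic acid).
#' @param protein_motif Residue string inserted into positive-class proteins.
#' @param noise_rate Independent label-flip probability, in `[0, 0.5)`.
#' @param positive_fraction Target positive-class fraction of emitted pairs.
#' @return List of class `"planted_rule"`.
#' @export
planted_rule <- function(drug_motif = "[CX3](=O)[OX2H1]",
                         protein_motif = "HKH",
                         noise_rate = 0.05,
                         positive_fraction = 0.5) {
  if (noise_rate < 0 || noise_rate >= 0.5) {
    stop("noise_rate must be in [0, 0.5)")
  }
  if (positive_fraction <= 0 || positive_fraction >= 1) {
    stop("positive_fraction must be in (0, 1)")
  }
  structure(list(drug_motif = drug_motif, protein_motif = protein_motif,
                 noise_rate = noise_rate,
                 positive_fraction = positive_fraction),
            class = "planted_rule")
}

# One random molecule from the fragment grammar: a tree over C/N/O with an
# occasional benzene leaf; no double bonds, so the carboxyl motif can only
# come from explicit attachment.
random_tree_smiles <- function(max_heavy) {
  budget <- max_heavy
  build <- function(depth, max_children) {
    if (budget <= 0) return("")
    if (budget >= 6 && depth > 0 && stats::runif(1) < 0.12) {
      budget <<- budget - 6
      return("c1ccccc1")
    }
    atom <- sample(c("C", "C", "C", "N", "O"), 1)
    budget <<- budget - 1
    cap <- switch(atom, C = 3L, N = 2L, O = 1L)
    cap <- min(cap, max_children)
    n_child <- sample(0:cap, 1, prob = rev(seq_len(cap + 1L)))
    subs <- character(0)
    for (i in seq_len(n_child)) {
      if (budget <= 0) break
      s <- build(depth + 1L, 3L)
      if (nzchar(s)) subs <- c(subs, s)
    }
    if (length(subs)) {
      paste0(atom, paste0("(", subs, ")", collapse = ""))
    } else {
      atom
    }
  }
  s <- build(0L, 2L)
  if (!nzchar(s)) "C" else s
}

#' Generate synthetic drug molecules
#'
#' Emits valid, parseable SMILES assembled from a fragment grammar (random
#' trees over C/N/O plus occasional benzene rings; no double bonds), with a
#' carboxylic-acid motif (`OC(=O)-`) attached to exactly
#' `floor(with_motif * n)` of them. All molecules stay within `max_atoms`
#' heavy atoms.
#'
#' @param n Number of molecules.
#' @param seed Integer seed.
#' @param with_motif Fraction carrying the drug motif.
#' @param max_atoms Heavy-atom cap.
#' @return Character vector of SMILES with a logical attribute
#'   `"has_motif"`.
#' @export
generate_drugs <- function(n, seed = 1L, with_motif = 0.5, max_atoms = 40L) {
  stopifnot(n >= 1)
  set.seed(seed)
  k <- floor(with_motif * n)
  flags <- sample(c(rep(TRUE, k), rep(FALSE, n - k)))
  out <- character(n)
  for (i in seq_len(n)) {
    base <- random_tree_smiles(max_atoms - if (flags[i]) 3L else 0L)
    out[i] <- if (flags[i]) paste0("OC(=O)", base) else base
  }
  attr(out, "has_motif") <- flags
  out
}

#' Generate synthetic protein sequences
#'
#' Uniform-random sequences over the 20 standard residues; the designated
#' fraction receives the motif spliced in at a random valid offset, and the
#' remainder are rejection-sampled to be motif-free.
#'
#' @param n Number of sequences.
#' @param seed Integer seed.
#' @param length_range Length bounds (inclusive).
#' @param with_motif Fraction carrying the motif.
#' @param motif Residue string.
#' @return Character vector with logical attribute `"has_motif"`.
#' @export
generate_proteins <- function(n, seed = 1L, length_range = c(50L, 60L),
                              with_motif = 0.5, motif = "HKH") {
  stopifnot(n >= 1)
  if (nchar(motif) > min(length_range)) {
    stop("motif longer than the minimum sequence length")
  }
  set.seed(seed)
  k <- floor(with_motif * n)
  flags <- sample(c(rep(TRUE, k), rep(FALSE, n - k)))
  rand_seq <- function(len) {
    paste(sample(AA_LETTERS, len, replace = TRUE), collapse = "")
  }
  out <- character(n)
  for (i in seq_len(n)) {
    len <- sample(length_range[1]:length_range[2], 1)
    if (flags[i]) {
      body <- rand_seq(len - nchar(motif))
      at <- sample(0:(nchar(body)), 1)
      out[i] <- paste0(substr(body, 1, at), motif,
                       substr(body, at + 1, nchar(body)))
    } else {
      repeat {
        s <- rand_seq(len)
        if (!grepl(motif, s, fixed = TRUE)) break
      }
      out[i] <- s
    }
  }
  attr(out, "has_motif") <- flags
  out
}

#' Label drug-protein pairs by the planted rule
#'
#' Samples pairs from the drug and protein pools so that the positive-class
#' fraction matches `rule$positive_fraction` (within 2 percent), labels each
#' pair 1 iff the drug carries the drug motif AND the protein carries the
#' protein motif, then flips every label independently with probability
#' `rule$noise_rate`.
#'
#' @param drugs SMILES vector from [generate_drugs()] (or any SMILES vector;
#'   motif status is recomputed if the `"has_motif"` attribute is absent).
#' @param proteins Sequence vector from [generate_proteins()].
#' @param rule A [planted_rule()].
#' @param seed Integer seed.
#' @param n_pairs Number of pairs to emit (default: `length(drugs)`).
#' @return Data.frame with `smiles`, `sequence`, `label` and the pre-noise
#'   label in `attr(, "clean_label")`.
#' @export
label_pairs <- function(drugs, proteins, rule = planted_rule(), seed = 1L,
                        n_pairs = length(drugs)) {
  stopifnot(length(drugs) >= 1, length(proteins) >= 1)
  dm <- attr(drugs, "has_motif")
  if (is.null(dm)) dm <- has_substructure(drugs, rule$drug_motif)
  pm <- attr(proteins, "has_motif")
  if (is.null(pm)) pm <- grepl(rule$protein_motif, proteins, fixed = TRUE)
  if (!any(dm) || !any(pm)) {
    stop("positive_fraction unreachable: no motif-bearing drugs or proteins")
  }
  if ((!any(!dm)) && (!any(!pm)) && rule$positive_fraction < 1) {
    stop("negative pairs unreachable: every drug and protein carries its motif")
  }
  set.seed(seed)
  n_pos <- round(rule$positive_fraction * n_pairs)
  want_pos <- sample(c(rep(TRUE, n_pos), rep(FALSE, n_pairs - n_pos)))
  di <- integer(n_pairs)
  pi_ <- integer(n_pairs)
  idx_dm <- which(dm); idx_dn <- which(!dm)
  idx_pm <- which(pm); idx_pn <- which(!pm)
  for (i in seq_len(n_pairs)) {
    if (want_pos[i]) {
      di[i] <- resample(idx_dm)
      pi_[i] <- resample(idx_pm)
    } else {
      # violate the AND rule: pick which side (or both) lacks its motif,
      # among the feasible cases
      cases <- c(if (length(idx_dn)) "d", if (length(idx_pn)) "p",
                 if (length(idx_dn) && length(idx_pn)) "b")
      case <- if (length(cases) == 1) cases else sample(cases, 1)
      di[i] <- if (case %in% c("d", "b")) resample(idx_dn) else resample(idx_dm)
      pi_[i] <- if (case %in% c("p", "b")) resample(idx_pn) else resample(idx_pm)
    }
  }
  clean <- as.integer(dm[di] & pm[pi_])
  achieved <- mean(clean)
  # deterministic count, so the miss is at most the rounding granularity
  if (abs(achieved - rule$positive_fraction) > 0.02 + 0.5 / n_pairs) {
    stop(sprintf("achieved positive fraction %.3f misses the target %.3f by more than 0.02",
                 achieved, rule$positive_fraction))
  }
  flip <- stats::runif(n_pairs) < rule$noise_rate
  out <- data.frame(smiles = drugs[di], sequence = proteins[pi_],
                    label = as.integer(ifelse(flip, 1L - clean, clean)),
                    stringsAsFactors = FALSE)
  attr(out, "clean_label") <- clean
  out
}

resample <- function(x) if (length(x) == 1) x else sample(x, 1)

#' Generate a complete synthetic interaction dataset
#'
#' Convenience wrapper: drug pool, protein pool and labeled pairs under one
#' seed and one planted rule.
#'
#' @param n Number of pairs.
#' @param seed Integer seed.
#' @param rule A [planted_rule()].
#' @param motif_fraction Motif prevalence in each pool.
#' @param length_range Protein length bounds.
#' @param max_atoms Heavy-atom cap for drugs.
#' @return Data.frame of labeled records (see [label_pairs()]).
#' @export
synth_pairs <- function(n, seed = 1L, rule = planted_rule(),
                        motif_fraction = 0.6, length_range = c(50L, 60L),
                        max_atoms = 40L) {
  drugs <- generate_drugs(n, seed = seed, with_motif = motif_fraction,
                          max_atoms = max_atoms)
  proteins <- generate_proteins(n, seed = seed + 1L,
                                length_range = length_range,
                                with_motif = motif_fraction,
                                motif = rule$protein_motif)
  label_pairs(drugs, proteins, rule, seed = seed + 2L, n_pairs = n)
}
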
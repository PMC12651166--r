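# Reading, writing and splitting labeled (SMILES, sequence, label) pair
# files in the tab- or comma-separated dialect used by common DTI benchmark
# distributions.

#' Read labeled drug-target pairs
#'
#' Reads a delimited text file with columns (SMILES, protein sequence, 0/1
#' label). The delimiter (tab or comma) and the presence of a header row are
#' auto-detected; with a header, columns may appear in any order under names
#' matching `smiles`, `sequence`/`protein`/`target`, `label`/`y`. Malformed
#' rows (non-binary label, empty fields) are dropped with a warning that
#' lists their line numbers; duplicated pairs are kept but reported.
#'
#' @param path Path to the pair file.
#' @param sep Field separator; `NULL` (default) auto-detects.
#' @return A data.frame with character columns `smiles`, `sequence` and an
#'   integer `label`.
#' @export
read_pairs <- function(path, sep = NULL) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) stop("no records in ", path)
  if (is.null(sep)) sep <- if (grepl("\t", lines[1], fixed = TRUE)) "\t" else ","
  fields <- strsplit(lines, sep, fixed = TRUE)
  widths <- lengths(fields)
  if (any(widths < 3)) {
    first_bad <- which(widths < 3)[1]
    stop("line ", first_bad, " has ", widths[first_bad],
         " fields; expected at least 3 (SMILES, sequence, label)")
  }
  head_fields <- tolower(trimws(fields[[1]]))
  name_map <- c(smiles = "smiles", compound = "smiles", drug = "smiles",
                sequence = "sequence", protein = "sequence", target = "sequence",
                label = "label", y = "label", interaction = "label")
  has_header <- all(c("smiles", "sequence", "label") %in%
                      stats::na.omit(name_map[head_fields]))
  if (has_header) {
    cols <- name_map[head_fields]
    idx <- list(smiles = which(cols == "smiles")[1],
                sequence = which(cols == "sequence")[1],
                label = which(cols == "label")[1])
    fields <- fields[-1]
    offset <- 1L
  } else {
    if (!head_fields[3] %in% c("0", "1")) {
      stop("cannot interpret file: no recognized header (found: ",
           paste(fields[[1]], collapse = ", "),
           ") and first row's third field is not a 0/1 label")
    }
    idx <- list(smiles = 1L, sequence = 2L, label = 3L)
    offset <- 0L
  }
  smiles <- trimws(vapply(fields, `[`, "", idx$smiles))
  sequence <- toupper(trimws(vapply(fields, `[`, "", idx$sequence)))
  label_raw <- trimws(vapply(fields, `[`, "", idx$label))
  ok <- nzchar(smiles) & nzchar(sequence) & label_raw %in% c("0", "1")
  if (any(!ok)) {
    warning("dropped ", sum(!ok), " malformed row(s) at line(s) ",
            paste(which(!ok) + offset, collapse = ", "))
  }
  out <- data.frame(smiles = smiles[ok], sequence = sequence[ok],
                    label = as.integer(label_raw[ok]),
                    stringsAsFactors = FALSE)
  dup <- duplicated(paste(out$smiles, out$sequence, sep = "\r"))
  if (any(dup)) {
    message(sum(dup), " duplicate pair(s) in ", path)
  }
  out
}

#' Write labeled pairs
#'
#' Writes records in the delimited format [read_pairs()] consumes
#' (tab-separated with a header by default); the round trip is lossless.
#'
#' @param records Data.frame with `smiles`, `sequence`, `label`.
#' @param path Output path.
#' @param sep Field separator.
#' @return `path`, invisibly.
#' @export
write_pairs <- function(records, path, sep = "\t") {
  stopifnot(all(c("smiles", "sequence", "label") %in% names(records)))
  utils::write.table(records[, c("smiles", "sequence", "label")], path,
                     sep = sep, quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Stratified train/validation/test split
#'
#' Deterministic under the seed, disjoint and exhaustive; records are
#' stratified by label so each partition's class ratio is within one record
#' of the global ratio.
#'
#' @param records Data.frame of interaction records.
#' @param fractions Length-3 numeric summing to 1 (train, valid, test).
#' @param seed Integer seed.
#' @return List of data.frames `train`, `valid`, `test` (each carrying the
#'   original row indices in `attr(, "rows")`).
#' @export
split_dataset <- function(records, fractions = c(0.8, 0.1, 0.1), seed = 1L) {
  if (abs(sum(fractions) - 1) > 1e-8) stop("fractions must sum to 1")
  n <- nrow(records)
  # global partition sizes (round half up), then per-class base counts by
  # floor with leftovers assigned by largest fractional remainder subject to
  # the remaining global capacity, so each class ratio stays within one
  # record of the global ratio while the partition sizes hit their targets.
  target <- floor(fractions * n + 0.5)
  target[1] <- n - sum(target[-1])
  classes <- split(seq_len(n), records$label)
  counts <- matrix(0L, length(classes), 3L)
  for (ci in seq_along(classes)) {
    counts[ci, ] <- floor(fractions * length(classes[[ci]]))
  }
  cap <- target - colSums(counts)
  for (ci in seq_along(classes)) {
    rem <- fractions * length(classes[[ci]]) - counts[ci, ]
    for (p in order(rem, decreasing = TRUE)) {
      extra <- length(classes[[ci]]) - sum(counts[ci, ])
      if (extra <= 0) break
      give <- min(extra, cap[p])
      if (give > 0) {
        counts[ci, p] <- counts[ci, p] + give
        cap[p] <- cap[p] - give
      }
    }
  }
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  set.seed(seed)
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  parts <- list(train = integer(0), valid = integer(0), test = integer(0))
  for (ci in seq_along(classes)) {
    idx <- classes[[ci]]
    perm <- idx[sample.int(length(idx))]
    ends <- cumsum(counts[ci, ])
    parts$train <- c(parts$train, perm[seq_len(ends[1])])
    parts$valid <- c(parts$valid, perm[seq2(ends[1] + 1L, ends[2])])
    parts$test <- c(parts$test, perm[seq2(ends[2] + 1L, ends[3])])
  }
  take <- function(part) {
    rows <- sort(parts[[part]])
    out <- records[rows, , drop = FALSE]
    attr(out, "rows") <- rows
    out
  }
  out <- list(train = take("train"), valid = take("valid"), test = take("test"))
  if (any(vapply(out, nrow, 1L) == 0)) {
    stop("split produced an empty partition (n = ", n, ", fractions ",
         paste(fractions, collapse = "/"), ")")
  }
  out
}

seq2 <- function(from, to) if (from > to) integer(0) else from:to
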
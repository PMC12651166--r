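# Molecular-graph featurization: SMILES -> padded 74-dimensional atom feature
# matrix plus self-loop-augmented adjacency. Parsing is delegated to
# OpenBabel (through ChemmineR/ChemmineOB); the kekulized SDF supplies the
# bond list and the MOL2 SYBYL atom types supply aromaticity and
# hybridization as perceived by the toolkit.

ATOM_SYMBOLS <- c(
  "C", "N", "O", "S", "F", "Si", "P", "Cl", "Br", "Mg", "Na", "Ca", "Fe",
  "As", "Al", "I", "B", "V", "K", "Tl", "Yb", "Sb", "Sn", "Ag", "Pd", "Co",
  "Se", "Ti", "Zn", "H", "Li", "Ge", "Cu", "Au", "Ni", "Cd", "In", "Mn",
  "Zr", "Cr", "Pt", "Hg", "other"
)
HYBRIDIZATIONS <- c("SP", "SP2", "SP3", "SP3D", "SP3D2")

#' Layout of the 74-dimensional atom feature vector
#'
#' Feature blocks, in order: atom-type one-hot (43: 42 element symbols plus
#' `"other"`), heavy-atom degree one-hot (0-10), implicit-valence one-hot
#' (0-6), formal charge (scalar), radical electrons (scalar), hybridization
#' one-hot (SP, SP2, SP3, SP3D, SP3D2), aromaticity flag, and total
#' hydrogen-count one-hot (0-4). Totals 74 columns.
#'
#' @return A data.frame with one row per block: `block`, `width`, `start`,
#'   `end` (1-based inclusive column ranges).
#' @export
atom_feature_blocks <- function() {
  w <- c(atom_type = 43L, degree = 11L, implicit_valence = 7L,
         formal_charge = 1L, radical_electrons = 1L, hybridization = 5L,
         aromatic = 1L, total_h = 5L)
  e <- cumsum(w)
  data.frame(block = names(w), width = as.integer(w),
             start = as.integer(e - w + 1L), end = as.integer(e),
             row.names = NULL, stringsAsFactors = FALSE)
}

ATOM_FEATURE_DIM <- 74L

# Parse one or more SMILES with OpenBabel. Returns a list per molecule:
# elements, charges, sybyl (atom types), aromatic (flags), bonds (matrix with
# columns from, to, order; kekulized orders).
parse_smiles <- function(smiles) {
  stopifnot(is.character(smiles), length(smiles) >= 1)
  bad <- !nzchar(trimws(smiles))
  if (any(bad)) stop("empty SMILES at position(s) ",
                     paste(which(bad), collapse = ", "))
  mol2 <- tryCatch(
    ChemmineOB::convertFormat("SMI", "MOL2",
                              paste0(paste(smiles, collapse = "\n"), "\n")),
    error = function(e) stop("SMILES conversion failed: ", conditionMessage(e)))
  blocks <- strsplit(mol2, "@<TRIPOS>MOLECULE", fixed = TRUE)[[1]]
  blocks <- blocks[nzchar(trimws(blocks))]
  if (length(blocks) != length(smiles)) {
    stop("unparsable SMILES in input (", length(smiles) - length(blocks),
         " of ", length(smiles), " inputs rejected by the parser); first ",
         "input: '", smiles[1], "'")
  }
  lapply(seq_along(blocks), function(i) {
    mol <- parse_mol2_block(blocks[[i]])
    if (mol$n == 0) stop("unparsable SMILES: '", smiles[i], "'")
    mol
  })
}

parse_mol2_block <- function(txt) {
  lines <- strsplit(txt, "\n", fixed = TRUE)[[1]]
  sect <- function(name) {
    at <- which(lines == paste0("@<TRIPOS>", name))
    if (!length(at) || at[1] >= length(lines)) return(character(0))
    rest <- lines[(at[1] + 1L):length(lines)]
    stop_at <- grep("^@<TRIPOS>", rest)
    if (length(stop_at)) rest <- rest[seq_len(stop_at[1] - 1L)]
    rest[nzchar(trimws(rest))]
  }
  atom_lines <- sect("ATOM")
  n <- length(atom_lines)
  if (n == 0) return(list(n = 0L))
  fields <- strsplit(trimws(atom_lines), "[[:space:]]+")
  sybyl <- vapply(fields, function(f) f[6], "")
  elements <- sub("\\..*$", "", sybyl)
  bond_lines <- sect("BOND")
  bonds <- if (length(bond_lines)) {
    bf <- strsplit(trimws(bond_lines), "[[:space:]]+")
    from <- vapply(bf, function(f) as.integer(f[2]), 1L)
    to <- vapply(bf, function(f) as.integer(f[3]), 1L)
    type <- vapply(bf, function(f) f[4], "")
    order <- ifelse(type == "ar", 1.5,
                    ifelse(type == "am", 1, suppressWarnings(as.numeric(type))))
    order[is.na(order)] <- 1
    cbind(from = from, to = to, order = order)
  } else {
    matrix(numeric(0), 0, 3, dimnames = list(NULL, c("from", "to", "order")))
  }
  charges <- numeric(n)
  attr_lines <- sect("UNITY_ATOM_ATTR")
  if (length(attr_lines) >= 2) {
    i <- 1L
    while (i <= length(attr_lines)) {
      hd <- strsplit(trimws(attr_lines[i]), "[[:space:]]+")[[1]]
      atom_id <- as.integer(hd[1]); n_attr <- as.integer(hd[2])
      for (j in seq_len(n_attr)) {
        kv <- strsplit(trimws(attr_lines[i + j]), "[[:space:]]+")[[1]]
        if (kv[1] == "charge") charges[atom_id] <- as.numeric(kv[2])
      }
      i <- i + n_attr + 1L
    }
  }
  aromatic <- grepl("\\.ar$", sybyl)
  if (nrow(bonds)) {
    ar_atoms <- unique(c(bonds[bonds[, "order"] == 1.5, "from"],
                         bonds[bonds[, "order"] == 1.5, "to"]))
    aromatic[ar_atoms] <- TRUE
  }
  list(n = n, elements = elements, sybyl = sybyl, charges = charges,
       aromatic = aromatic, bonds = bonds)
}

sybyl_hybridization <- function(sybyl) {
  suffix <- ifelse(grepl("\\.", sybyl), sub("^[^.]*\\.", "", sybyl), "")
  vapply(suffix, function(s) {
    switch(s,
           "1" = "SP",
           "2" = , "ar" = , "am" = , "pl3" = , "co2" = , "o" = , "o2" = "SP2",
           "SP3")
  }, "", USE.NAMES = FALSE)
}

default_valence <- function(element, charge) {
  base <- switch(element,
                 C = 4, N = 3, O = 2, S = 2, P = 3, B = 3,
                 F = 1, Cl = 1, Br = 1, I = 1, H = 1, 0)
  if (base == 0) return(0)
  adj <- switch(element,
                N = , P = base + charge,
                O = , S = base + charge,
                C = base - abs(charge),
                base)
  max(0, adj)
}

one_hot <- function(index, width) {
  v <- numeric(width)
  v[index] <- 1
  v
}

# 74-dimensional feature vector for atom i of a parsed molecule.
atom_features <- function(mol, i) {
  elem <- mol$elements[i]
  type_idx <- match(elem, ATOM_SYMBOLS)
  if (is.na(type_idx)) type_idx <- length(ATOM_SYMBOLS)
  nb <- mol$bonds[mol$bonds[, "from"] == i | mol$bonds[, "to"] == i, ,
                  drop = FALSE]
  degree <- nrow(nb)
  # bond-order sum on the kekulized graph: aromatic bonds alternate 1/2 in
  # the SDF form; MOL2 reports them as 1.5, so an aromatic atom with two ring
  # bonds contributes 3 either way.
  order_sum <- if (degree) sum(nb[, "order"]) else 0
  charge <- mol$charges[i]
  explicit_h <- if (degree) {
    others <- ifelse(nb[, "from"] == i, nb[, "to"], nb[, "from"])
    sum(mol$elements[others] == "H")
  } else 0
  implicit_h <- max(0, round(default_valence(elem, charge) - order_sum))
  total_h <- implicit_h + explicit_h
  hyb <- sybyl_hybridization(mol$sybyl[i])
  c(one_hot(type_idx, 43L),
    one_hot(min(degree, 10L) + 1L, 11L),
    one_hot(min(implicit_h, 6L) + 1L, 7L),
    charge,
    0,                                   # radical electrons
    one_hot(match(hyb, HYBRIDIZATIONS), 5L),
    as.numeric(mol$aromatic[i]),
    one_hot(min(total_h, 4L) + 1L, 5L))
}

#' Featurize a molecule as a padded graph
#'
#' Converts a SMILES string into the padded molecular-graph representation
#' consumed by the drug encoder: a `n_d x 74` node feature matrix (zero rows
#' beyond the real atoms), a binary adjacency matrix with self-loops on real
#' atoms, and a node mask.
#'
#' @param smiles A single SMILES string.
#' @param n_d Pad/capacity size; molecules with more than `n_d` atoms are
#'   rejected with an error (never truncated).
#' @return A list of class `"molecular_graph"` with elements `n_atoms`,
#'   `node_features` (`n_d x 74`), `adjacency` (`n_d x n_d`), `node_mask`
#'   (length `n_d`, 1 for real atoms) and `elements`.
#' @export
#' @examples
#' \donttest{
#' g <- featurize_atoms("CCO", n_d = 10)
#' g$n_atoms          # 3
#' colSums(g$adjacency)[1:3]  # degree + self-loop
#' }
featurize_atoms <- function(smiles, n_d = 290L) {
  stopifnot(length(smiles) == 1)
  mol <- parse_smiles(smiles)[[1]]
  graph_from_mol(mol, n_d, smiles)
}

graph_from_mol <- function(mol, n_d, label) {
  n <- mol$n
  if (n > n_d) {
    stop("molecule '", label, "' has ", n, " atoms, exceeding the capacity n_d = ",
         n_d, "; increase n_d rather than truncating")
  }
  feats <- matrix(0, n_d, ATOM_FEATURE_DIM)
  for (i in seq_len(n)) feats[i, ] <- atom_features(mol, i)
  adj <- matrix(0, n_d, n_d)
  if (nrow(mol$bonds)) {
    adj[mol$bonds[, c("from", "to"), drop = FALSE]] <- 1
    adj[mol$bonds[, c("to", "from"), drop = FALSE]] <- 1
  }
  diag(adj)[seq_len(n)] <- 1
  mask <- c(rep(1, n), rep(0, n_d - n))
  structure(list(n_atoms = n, node_features = feats, adjacency = adj,
                 node_mask = mask, elements = mol$elements),
            class = "molecular_graph")
}

#' Featurize many SMILES at once
#'
#' Batch variant of [featurize_atoms()]; parses all inputs in a single
#' OpenBabel call and optionally caches graphs keyed by the SMILES string.
#'
#' @param smiles Character vector of SMILES.
#' @param n_d Capacity as in [featurize_atoms()].
#' @param cache Optional environment used as a graph cache.
#' @return A list of `"molecular_graph"` objects.
#' @export
featurize_drugs <- function(smiles, n_d = 290L, cache = NULL) {
  out <- vector("list", length(smiles))
  todo <- seq_along(smiles)
  if (!is.null(cache)) {
    hit <- vapply(smiles, function(s) !is.null(cache[[s]]), TRUE)
    out[hit] <- lapply(smiles[hit], function(s) cache[[s]])
    todo <- which(!hit)
  }
  if (length(todo)) {
    uniq <- unique(smiles[todo])
    mols <- parse_smiles(uniq)
    graphs <- lapply(seq_along(uniq),
                     function(i) graph_from_mol(mols[[i]], n_d, uniq[i]))
    names(graphs) <- uniq
    out[todo] <- graphs[smiles[todo]]
    if (!is.null(cache)) for (s in uniq) cache[[s]] <- graphs[[s]]
  }
  out
}

#' Project padded atom features to dense model inputs
#'
#' Applies the linear map `X_d = M_d W^T` to the padded node feature matrix.
#' Padding rows stay identically zero because the map has no bias.
#'
#' @param graph A `"molecular_graph"`.
#' @param weights A `D x 74` projection matrix.
#' @return A list with `features` (`n_d x D`) and `projection_weights`.
#' @export
project_features <- function(graph, weights) {
  stopifnot(inherits(graph, "molecular_graph"))
  if (ncol(weights) != ncol(graph$node_features)) {
    stop("projection expects ", ncol(graph$node_features),
         " input columns, got ", ncol(weights))
  }
  list(features = tcrossprod(graph$node_features, weights),
       projection_weights = weights)
}

# Symmetric degree normalization D^{-1/2} (A) D^{-1/2} of a self-loop
# adjacency, restricted to real atoms (padding rows/columns stay zero).
normalize_adjacency <- function(adjacency, mask = NULL) {
  deg <- rowSums(adjacency)
  inv <- ifelse(deg > 0, 1 / sqrt(deg), 0)
  adjacency * outer(inv, inv)
}

#' Test molecules for a SMARTS substructure
#'
#' Thin wrapper over the toolkit's SMARTS matcher, used by the synthetic-data
#' generator tests as an independent check that planted substructures are
#' present.
#'
#' @param smiles Character vector of SMILES.
#' @param smarts A single SMARTS pattern.
#' @return Logical vector: does each molecule contain the pattern?
#' @export
has_substructure <- function(smiles, smarts) {
  counts <- ChemmineOB::forEachMol(
    "SMILES", paste(smiles, collapse = "\n"),
    function(mol) ChemmineOB::smartsSearch_OB(list(mol), smarts,
                                              uniqueMatches = TRUE))
  if (length(counts) != length(smiles)) {
    stop("substructure search parsed ", length(counts), " of ",
         length(smiles), " molecules")
  }
  unlist(counts) > 0
}
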
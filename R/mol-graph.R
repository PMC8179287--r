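# Molecular-graph data model and discrete featurization.
#
# Heavy-atom graphs only: explicit hydrogens are folded into the per-atom
# `num_h` count.  Atom indices are 1-based in memory (R idiom); the CSV
# interfaces of the descriptor tables use 0-based indices (see
# load_descriptor_table).

#' Element vocabulary of the featurizer
#'
#' The fixed heavy-element list C, O, N, P, S, F, Cl, Br, I, Si, B (hydrogen
#' enters as a count, not a node) plus a terminal "other" bucket, so
#' out-of-vocabulary elements never error.
#' @return character vector of element symbols, last element `"other"`
#' @export
element_vocab <- function() {
  c("C", "O", "N", "P", "S", "F", "Cl", "Br", "I", "Si", "B", "other")
}

# one-hot slot budgets for the discrete atom features (documented constants;
# degree/valence/num_h values above the cap share the last slot)
ATOM_DEGREE_MAX <- 4L
ATOM_VALENCE_MAX <- 6L
ATOM_NUMH_MAX <- 4L

#' Parse an (atom-mapped) SMILES string into a molecular graph
#'
#' Hydrogens are folded into `num_h`; atom-map numbers, when present, are
#' preserved and must be unique within the string (one reactant set).
#'
#' @param smiles a single SMILES string, possibly atom-mapped and
#'   multi-molecule (`.`-separated)
#' @return a `mol_graph` object: list with `atoms` (data.frame: index,
#'   map_number, symbol, atomic_num, degree, valence, aromatic, num_h,
#'   formal_charge, in_ring), `bonds` (data.frame: i, j, bond_type, in_ring;
#'   `i < j`, each bond stored once), `smiles_canonical`, `canonical_order`
#'   (canonical storage position -> in-memory atom index),
#'   `net_formal_charge`, and `smiles_input`.
#' @examples
#' \dontrun{
#' g <- parse_mapped_smiles("[CH3:1][OH:2]")
#' g$atoms$map_number  # 1 2
#' }
#' @export
parse_mapped_smiles <- function(smiles) {
  stopifnot(is.character(smiles), length(smiles) == 1L)
  raw <- chem_parse_raw(smiles)[[1]]
  if (!isTRUE(raw$ok)) {
    type <- switch(raw$error, mapping = "mapping", "parse")
    rs_abort(type, raw$message %||% paste("cannot parse", smiles))
  }
  atoms <- data.frame(
    index = seq_along(raw$atoms),
    map_number = vapply(raw$atoms, function(a) as.integer(a$map_number), integer(1)),
    symbol = vapply(raw$atoms, function(a) a$symbol, character(1)),
    atomic_num = vapply(raw$atoms, function(a) as.integer(a$atomic_num), integer(1)),
    degree = vapply(raw$atoms, function(a) as.integer(a$degree), integer(1)),
    valence = vapply(raw$atoms, function(a) as.integer(a$valence), integer(1)),
    aromatic = vapply(raw$atoms, function(a) isTRUE(a$aromatic), logical(1)),
    num_h = vapply(raw$atoms, function(a) as.integer(a$num_h), integer(1)),
    formal_charge = vapply(raw$atoms, function(a) as.integer(a$formal_charge), integer(1)),
    in_ring = vapply(raw$atoms, function(a) isTRUE(a$in_ring), logical(1)),
    stringsAsFactors = FALSE
  )
  atoms$map_number[atoms$map_number == 0L] <- NA_integer_
  nb <- length(raw$bonds)
  bonds <- data.frame(
    i = integer(nb), j = integer(nb),
    bond_type = character(nb), in_ring = logical(nb),
    stringsAsFactors = FALSE
  )
  for (k in seq_len(nb)) {
    b <- raw$bonds[[k]]
    ij <- sort(c(as.integer(b$i), as.integer(b$j))) + 1L
    bonds$i[k] <- ij[1]; bonds$j[k] <- ij[2]
    bonds$bond_type[k] <- b$bond_type
    bonds$in_ring[k] <- isTRUE(b$in_ring)
  }
  g <- structure(list(
    atoms = atoms,
    bonds = bonds,
    smiles_canonical = raw$canonical,
    canonical_order = vapply(raw$canonical_order, as.integer, integer(1)) + 1L,
    net_formal_charge = as.integer(raw$net_formal_charge),
    smiles_input = smiles
  ), class = "mol_graph")
  stopifnot(all(g$bonds$i >= 1), all(g$bonds$j <= nrow(atoms)),
            all(g$bonds$i != g$bonds$j))
  g
}

#' @export
print.mol_graph <- function(x, ...) {
  cat("<mol_graph> ", x$smiles_canonical, "\n",
      "  atoms: ", nrow(x$atoms), ", bonds: ", nrow(x$bonds),
      ", net charge: ", x$net_formal_charge, "\n", sep = "")
  invisible(x)
}

#' Number of atoms in a molecular graph
#' @param g a `mol_graph`
#' @export
n_atoms <- function(g) nrow(g$atoms)

one_hot <- function(value, levels) {
  v <- numeric(length(levels))
  k <- match(value, levels)
  if (is.na(k)) k <- length(levels)  # terminal bucket
  v[k] <- 1
  v
}

one_hot_capped <- function(value, max) {
  v <- numeric(max + 1L)
  v[min(value, max) + 1L] <- 1
  v
}

#' Discrete atom feature matrix
#'
#' One fixed-length row per atom: one-hot element over [element_vocab()],
#' one-hot degree (0..4, capped), one-hot valence (0..6, capped), one-hot
#' hydrogen count (0..4, capped), and an aromaticity flag.
#'
#' @param g a `mol_graph`
#' @return numeric matrix, `n_atoms x atom_feature_dim()`
#' @export
atom_features <- function(g) {
  vocab <- element_vocab()
  n <- n_atoms(g)
  X <- matrix(0, n, atom_feature_dim())
  for (i in seq_len(n)) {
    a <- g$atoms[i, ]
    X[i, ] <- c(
      one_hot(a$symbol, vocab),
      one_hot_capped(a$degree, ATOM_DEGREE_MAX),
      one_hot_capped(a$valence, ATOM_VALENCE_MAX),
      one_hot_capped(a$num_h, ATOM_NUMH_MAX),
      as.numeric(a$aromatic)
    )
  }
  colnames(X) <- c(paste0("el_", vocab),
                   paste0("deg_", 0:ATOM_DEGREE_MAX),
                   paste0("val_", 0:ATOM_VALENCE_MAX),
                   paste0("nH_", 0:ATOM_NUMH_MAX),
                   "aromatic")
  X
}

#' Length of the discrete atom feature vector
#' @export
atom_feature_dim <- function() {
  length(element_vocab()) + (ATOM_DEGREE_MAX + 1L) +
    (ATOM_VALENCE_MAX + 1L) + (ATOM_NUMH_MAX + 1L) + 1L
}

BOND_TYPES <- c("single", "double", "triple", "aromatic")

#' Discrete bond feature matrix
#'
#' One row per (undirected) bond: one-hot bond type (single, double, triple,
#' aromatic) plus a ring-membership flag.
#'
#' @param g a `mol_graph`
#' @return numeric matrix, `n_bonds x bond_feature_dim()`
#' @export
bond_features_discrete <- function(g) {
  nb <- nrow(g$bonds)
  E <- matrix(0, nb, bond_feature_dim())
  for (k in seq_len(nb)) {
    E[k, ] <- c(one_hot(g$bonds$bond_type[k], BOND_TYPES),
                as.numeric(g$bonds$in_ring[k]))
  }
  colnames(E) <- c(paste0("bt_", BOND_TYPES), "in_ring")
  E
}

#' Length of the discrete bond feature vector
#' @export
bond_feature_dim <- function() length(BOND_TYPES) + 1L
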
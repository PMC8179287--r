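# Data model, CSV I/O, and radial-basis expansion for the six QM reactivity
# descriptors: per-atom partial charge (e), electrophilic and nucleophilic
# condensed Fukui indices (e), isotropic NMR shielding (ppm); per-bond bond
# order (dimensionless) and bond length (Angstrom).

ATOM_CHANNELS <- c("charge", "fukui_elec", "fukui_nuc", "nmr")
BOND_CHANNELS <- c("bond_order", "bond_length")

#' Names of the atomic and bond descriptor channels
#' @return list with `atom` and `bond` character vectors, in the fixed
#'   channel order used throughout the package
#' @export
descriptor_channels <- function() {
  list(atom = ATOM_CHANNELS, bond = BOND_CHANNELS)
}

#' Radial-basis expansion specification
#'
#' @param centers strictly increasing numeric vector of grid centers, in the
#'   units of the descriptor being expanded
#' @param gamma positive width parameter (inverse squared descriptor units);
#'   default `1 / spacing^2` so neighbouring Gaussians overlap at ~e^-1
#' @return an `rbf_spec` object
#' @export
rbf_spec <- function(centers, gamma = NULL) {
  stopifnot(is.numeric(centers), length(centers) >= 1)
  if (length(centers) > 1) stopifnot(all(diff(centers) > 0))
  if (is.null(gamma)) {
    d <- if (length(centers) > 1) min(diff(centers)) else 1
    gamma <- 1 / d^2
  }
  stopifnot(gamma > 0)
  structure(list(centers = as.numeric(centers), gamma = as.numeric(gamma)),
            class = "rbf_spec")
}

#' Expand scalars on a Gaussian grid
#'
#' Component `k` of the expansion of `x` is `exp(-gamma * (x - centers[k])^2)`:
#' bounded in (0, 1], equal to 1 exactly at a center, decaying smoothly away
#' from the grid (values outside the center range are legal).
#'
#' @param x numeric vector of scalars to expand
#' @param spec an [rbf_spec()]
#' @return numeric matrix, `length(x) x length(spec$centers)`
#' @export
rbf_expand <- function(x, spec) {
  stopifnot(inherits(spec, "rbf_spec"))
  d <- outer(as.numeric(x), spec$centers, "-")
  exp(-spec$gamma * d^2)
}

#' Default RBF grids for the six descriptor channels
#'
#' Every channel uses the same expansion dimension so the concatenated QM
#' block of the fusion model is balanced against the learned embedding.
#' Ranges cover the values produced by the synthetic descriptor oracle and
#' typical externally computed tables: charge in [-1, 1] e, Fukui indices in
#' [0, 1], shielding in [0, 400] ppm, bond order in [0.5, 3.2], bond length
#' in [0.9, 2.2] Angstrom.
#'
#' @param dim number of centers per channel (default 8)
#' @return named list of [rbf_spec()], one per channel
#' @export
default_rbf_specs <- function(dim = 8L) {
  grid <- function(lo, hi) rbf_spec(seq(lo, hi, length.out = dim))
  list(
    charge = grid(-1, 1),
    fukui_elec = grid(0, 1),
    fukui_nuc = grid(0, 1),
    nmr = grid(0, 400),
    bond_order = grid(0.5, 3.2),
    bond_length = grid(0.9, 2.2)
  )
}

#' RBF grids fitted to the observed range of a descriptor table
#'
#' Scans each channel of the table and places the center grid over the
#' observed range (padded by `pad` of the span on both sides), so the
#' expansion's resolution is spent where the data live.  This is the
#' recommended way to build specs for a given descriptor source; the static
#' [default_rbf_specs()] grids are the fallback when no table is available.
#' Degenerate (constant) channels fall back to the default grid.
#'
#' @param table a `descriptor_table`
#' @param dim number of centers per channel
#' @param pad fractional padding of the observed span
#' @return named list of [rbf_spec()], one per channel
#' @export
rbf_specs_from_table <- function(table, dim = 8L, pad = 0.05) {
  fallback <- default_rbf_specs(dim)
  fit <- function(x, fb) {
    r <- range(x, na.rm = TRUE)
    if (!all(is.finite(r)) || diff(r) < 1e-9) return(fb)
    span <- diff(r)
    rbf_spec(seq(r[1] - pad * span, r[2] + pad * span, length.out = dim))
  }
  out <- list()
  for (ch in ATOM_CHANNELS) out[[ch]] <- fit(table$atoms[[ch]], fallback[[ch]])
  for (ch in BOND_CHANNELS) out[[ch]] <- fit(table$bonds[[ch]], fallback[[ch]])
  out
}

#' Construct a descriptor table
#'
#' A descriptor table maps canonical SMILES to per-atom and per-bond QM
#' reactivity descriptors.  Atom rows are stored in canonical atom order
#' (the atom order obtained when parsing the canonical SMILES); map numbers
#' are never stored.
#'
#' @param atoms data.frame with columns `smiles`, `atom_index` (1-based in
#'   memory), `charge`, `fukui_elec`, `fukui_nuc`, `nmr`
#' @param bonds data.frame with columns `smiles`, `atom_index_1`,
#'   `atom_index_2` (1-based), `bond_order`, `bond_length`
#' @param provenance `"qm"` for externally computed tables, `"ml"` for model
#'   predictions, `"oracle"` for synthetic fixtures
#' @param validate check conservation sums and alignment against the parsed
#'   molecules
#' @param tol tolerance for the conservation sums when validating externally
#'   computed tables
#' @return a `descriptor_table` object
#' @export
descriptor_table <- function(atoms, bonds, provenance = "qm",
                             validate = TRUE, tol = 1e-2) {
  need_a <- c("smiles", "atom_index", ATOM_CHANNELS)
  need_b <- c("smiles", "atom_index_1", "atom_index_2", BOND_CHANNELS)
  rs_assert(all(need_a %in% names(atoms)), "schema",
            paste("atom table missing columns:",
                  paste(setdiff(need_a, names(atoms)), collapse = ", ")))
  rs_assert(all(need_b %in% names(bonds)), "schema",
            paste("bond table missing columns:",
                  paste(setdiff(need_b, names(bonds)), collapse = ", ")))
  tab <- structure(list(atoms = atoms[need_a], bonds = bonds[need_b],
                        provenance = provenance),
                   class = "descriptor_table")
  if (validate) validate_descriptor_table(tab, tol = tol)
  tab
}

#' @export
print.descriptor_table <- function(x, ...) {
  cat("<descriptor_table> ", length(unique(x$atoms$smiles)), " molecules, ",
      nrow(x$atoms), " atom rows, ", nrow(x$bonds), " bond rows (",
      x$provenance, ")\n", sep = "")
  invisible(x)
}

#' Molecules present in a descriptor table
#' @param table a `descriptor_table`
#' @export
table_molecules <- function(table) unique(table$atoms$smiles)

#' Look up one molecule's descriptors
#'
#' @param table a `descriptor_table`
#' @param smiles canonical SMILES key
#' @return list with `atoms` (rows in canonical atom order) and `bonds`
#'   data.frames, or signals a `missing_descriptor` error
#' @export
desc_for <- function(table, smiles) {
  a <- table$atoms[table$atoms$smiles == smiles, , drop = FALSE]
  rs_assert(nrow(a) > 0, "missing_descriptor",
            paste("no descriptors for", smiles))
  b <- table$bonds[table$bonds$smiles == smiles, , drop = FALSE]
  list(atoms = a[order(a$atom_index), , drop = FALSE], bonds = b)
}

#' Validate conservation sums and graph alignment of a table
#'
#' Per molecule: atom-row count must equal the heavy-atom count, bond rows
#' must reference existing bonds, sum(charge) must equal the net formal
#' charge and both Fukui channels must each sum to 1 (within `tol` for
#' externally computed tables; model/oracle tables are expected to be exact
#' and checked at 1e-6).
#'
#' @param table a `descriptor_table`
#' @param tol tolerance for conservation sums
#' @return invisibly TRUE; signals `alignment`/`schema` errors otherwise
#' @export
validate_descriptor_table <- function(table, tol = 1e-2) {
  if (table$provenance %in% c("ml", "oracle")) tol <- 1e-6
  chem_prefetch(table_molecules(table))
  for (smi in table_molecules(table)) {
    g <- parse_mapped_smiles(smi)
    d <- desc_for(table, smi)
    rs_assert(nrow(d$atoms) == n_atoms(g), "alignment",
              paste0(smi, ": ", nrow(d$atoms), " atom rows for ",
                     n_atoms(g), " heavy atoms"))
    rs_assert(all(sort(d$atoms$atom_index) == seq_len(n_atoms(g))), "alignment",
              paste0(smi, ": atom_index must cover 1..n exactly once"))
    rs_assert(abs(sum(d$atoms$charge) - g$net_formal_charge) <= tol, "alignment",
              paste0(smi, ": charges sum to ", sum(d$atoms$charge),
                     ", expected net charge ", g$net_formal_charge))
    for (ch in c("fukui_elec", "fukui_nuc")) {
      rs_assert(abs(sum(d$atoms[[ch]]) - 1) <= tol, "alignment",
                paste0(smi, ": ", ch, " sums to ", sum(d$atoms[[ch]]),
                       ", expected 1"))
    }
    if (nrow(d$bonds) > 0) {
      have <- paste(pmin(d$bonds$atom_index_1, d$bonds$atom_index_2),
                    pmax(d$bonds$atom_index_1, d$bonds$atom_index_2))
      canon <- canonical_bond_key(g, smi)
      rs_assert(setequal(have, canon) && nrow(d$bonds) == length(canon),
                "alignment", paste0(smi, ": bond rows do not match bonds"))
      rs_assert(all(d$bonds$bond_order > 0) && all(d$bonds$bond_length > 0),
                "alignment", paste0(smi, ": bond order/length must be > 0"))
    }
  }
  invisible(TRUE)
}

# bond keys of smiles, expressed in canonical storage order
canonical_bond_key <- function(g, smiles) {
  gc <- parse_mapped_smiles(smiles)
  paste(pmin(gc$bonds$i, gc$bonds$j), pmax(gc$bonds$i, gc$bonds$j))
}

#' Renormalize the constrained channels of a table
#'
#' Shifts charges uniformly so they sum to the net formal charge and rescales
#' each Fukui channel so it sums to 1 exactly.  Intended for externally
#' computed tables whose sums hold only within a tolerance.
#'
#' @param table a `descriptor_table`
#' @return a new `descriptor_table` with exact sums, provenance unchanged
#' @export
renormalize_table <- function(table) {
  atoms <- table$atoms
  for (smi in table_molecules(table)) {
    sel <- atoms$smiles == smi
    g <- parse_mapped_smiles(smi)
    n <- sum(sel)
    atoms$charge[sel] <- atoms$charge[sel] +
      (g$net_formal_charge - sum(atoms$charge[sel])) / n
    for (ch in c("fukui_elec", "fukui_nuc")) {
      s <- sum(atoms[[ch]][sel])
      rs_assert(s > 0, "alignment", paste0(smi, ": cannot renormalize ", ch))
      atoms[[ch]][sel] <- atoms[[ch]][sel] / s
    }
  }
  descriptor_table(atoms, table$bonds, provenance = table$provenance,
                   validate = FALSE)
}

#' Write a descriptor table to a pair of CSV files
#'
#' Schema (UTF-8, header row): atom file `smiles, atom_index, charge,
#' fukui_elec, fukui_nuc, nmr`; bond file `smiles, atom_index_1,
#' atom_index_2, bond_order, bond_length`.  Indices are written 0-based.
#'
#' @param table a `descriptor_table`
#' @param atom_path,bond_path output CSV paths
#' @export
save_descriptor_table <- function(table, atom_path, bond_path) {
  a <- table$atoms
  a$atom_index <- a$atom_index - 1L
  b <- table$bonds
  b$atom_index_1 <- b$atom_index_1 - 1L
  b$atom_index_2 <- b$atom_index_2 - 1L
  utils::write.csv(a, atom_path, row.names = FALSE)
  utils::write.csv(b, bond_path, row.names = FALSE)
  invisible(c(atom_path, bond_path))
}

#' Read a descriptor table from CSV
#'
#' Inverse of [save_descriptor_table()]: indices are converted back to
#' 1-based, rows are aligned to canonical atom order, and alignment plus
#' conservation invariants are checked (`tol` for provenance `"qm"`, exact
#' for `"ml"`/`"oracle"`).
#'
#' @param atom_path,bond_path input CSV paths
#' @param provenance descriptor provenance flag
#' @param tol conservation tolerance for externally computed tables
#' @return a `descriptor_table`
#' @export
load_descriptor_table <- function(atom_path, bond_path, provenance = "qm",
                                  tol = 1e-2) {
  rs_assert(file.exists(atom_path), "io", paste("no such file:", atom_path))
  rs_assert(file.exists(bond_path), "io", paste("no such file:", bond_path))
  a <- utils::read.csv(atom_path, stringsAsFactors = FALSE)
  b <- utils::read.csv(bond_path, stringsAsFactors = FALSE)
  rs_assert("atom_index" %in% names(a), "schema",
            "atom table missing column atom_index")
  a$atom_index <- as.integer(a$atom_index) + 1L
  if (nrow(b) > 0) {
    b$atom_index_1 <- as.integer(b$atom_index_1) + 1L
    b$atom_index_2 <- as.integer(b$atom_index_2) + 1L
  }
  descriptor_table(a, b, provenance = provenance, validate = TRUE, tol = tol)
}
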
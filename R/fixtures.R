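# Synthetic fixtures: molecules, a deterministic topology-based descriptor
# oracle obeying all conservation constraints, and toy selective reactions
# whose major site is a known function of the oracle descriptors.  These
# stand in for a DFT-derived descriptor database and a mined reaction corpus
# in every learning experiment; they make no claim of chemical realism.

EN_TABLE <- c(H = 2.20, C = 2.55, N = 3.04, O = 3.44, F = 3.98, P = 2.19,
              S = 2.58, Cl = 3.16, Br = 2.96, I = 2.66, Si = 1.90, B = 2.04)
COV_RADIUS <- c(H = 0.31, C = 0.76, N = 0.71, O = 0.66, F = 0.57, P = 1.07,
                S = 1.05, Cl = 1.02, Br = 1.20, I = 1.39, Si = 1.11, B = 0.84)
NMR_BASE <- c(C = 150, N = 220, O = 300, F = 350, P = 280, S = 250,
              Cl = 380, Br = 390, I = 360, Si = 240, B = 260)
BOND_ORDER_BASE <- c(single = 1, double = 2, triple = 3, aromatic = 1.5)

en_of <- function(sym) ifelse(is.na(EN_TABLE[sym]), 2.5, EN_TABLE[sym])

#' Synthetic descriptor oracle specification
#'
#' Fixes the deterministic topology rules (coefficients are constants in the
#' package source) together with per-channel Gaussian noise scales and a
#' seed.  Noise is added before the conservation renormalization, so
#' constrained channels always satisfy their sums exactly.
#'
#' @param noise_sigma named numeric vector of per-channel noise standard
#'   deviations; any subset of `charge`, `fukui_elec`, `fukui_nuc`, `nmr`,
#'   `bond_order`, `bond_length` (units of each channel)
#' @param seed integer seed; molecule-level noise is derived from
#'   `seed` and the canonical SMILES, so tables are reproducible regardless
#'   of call order
#' @return an `oracle_spec` object
#' @export
oracle_spec <- function(noise_sigma = c(charge = 0.02, fukui_elec = 0.01,
                                        fukui_nuc = 0.01, nmr = 5,
                                        bond_order = 0.02, bond_length = 0.01),
                        seed = 20260101L) {
  full <- c(charge = 0, fukui_elec = 0, fukui_nuc = 0, nmr = 0,
            bond_order = 0, bond_length = 0)
  full[names(noise_sigma)] <- noise_sigma
  structure(list(noise_sigma = full, seed = as.integer(seed)),
            class = "oracle_spec")
}

# all-pairs shortest path (bond count) by BFS; n is small
graph_distances <- function(g) {
  n <- n_atoms(g)
  adj <- vector("list", n)
  for (k in seq_len(nrow(g$bonds))) {
    i <- g$bonds$i[k]; j <- g$bonds$j[k]
    adj[[i]] <- c(adj[[i]], j); adj[[j]] <- c(adj[[j]], i)
  }
  D <- matrix(Inf, n, n)
  for (s in seq_len(n)) {
    D[s, s] <- 0
    q <- s
    while (length(q)) {
      u <- q[1]; q <- q[-1]
      for (v in adj[[u]]) if (is.infinite(D[s, v])) {
        D[s, v] <- D[s, u] + 1
        q <- c(q, v)
      }
    }
  }
  D
}

# electron-donating substituent heteroatoms: non-aromatic N/O
oracle_donors <- function(g) {
  which(g$atoms$symbol %in% c("N", "O") & !g$atoms$aromatic)
}
# electron-withdrawing centers: halogens and aromatic nitrogen
oracle_withdrawers <- function(g) {
  which(g$atoms$symbol %in% c("F", "Cl", "Br") |
          (g$atoms$symbol == "N" & g$atoms$aromatic))
}

# directing-effect kernel: weight of a donor/withdrawer at bond distance d
direct_kernel <- function(d, w2, w3, w4) {
  ifelse(d == 2, w2, ifelse(d == 3, w3, ifelse(d == 4, w4, 0)))
}

#' Oracle QM descriptors for one molecule
#'
#' Deterministic, interpretable topology rules (plus optional Gaussian
#' noise) for all six channels:
#' * `charge`: electronegativity differences summed over heavy neighbours
#'   and implicit hydrogens, re-centred so the molecular sum equals the net
#'   formal charge exactly;
#' * `fukui_nuc` / `fukui_elec`: softmax-normalized site activities peaked
#'   ortho/para-like (bond distance 2/4) to donor substituents
#'   (withdrawing groups for `fukui_elec`), summing to 1 exactly;
#' * `nmr`: element baseline shifted by aromaticity, hydrogen count and
#'   neighbour electronegativity;
#' * `bond_order`: bond-type baseline minus a crowding correction;
#' * `bond_length`: covalent-radius sum contracted with bond order.
#'
#' @param smiles a single neutral molecule SMILES
#' @param spec an [oracle_spec()]
#' @return list of `atoms` / `bonds` data.frames in the descriptor-table
#'   schema (canonical atom order)
#' @export
oracle_descriptors <- function(smiles, spec = oracle_spec()) {
  stopifnot(inherits(spec, "oracle_spec"))
  can <- chem_canonical(smiles)
  rs_assert(!is.na(can), "parse", paste("cannot parse", smiles))
  g <- parse_mapped_smiles(can)
  rs_assert(g$net_formal_charge == 0L, "parse",
            paste("oracle covers neutral molecules only:", smiles))
  n <- n_atoms(g)
  sym <- g$atoms$symbol
  en <- en_of(sym)
  D <- graph_distances(g)
  donors <- oracle_donors(g)
  withdr <- oracle_withdrawers(g)
  nb <- nrow(g$bonds)

  nbr_en_excess <- numeric(n)
  for (k in seq_len(nb)) {
    i <- g$bonds$i[k]; j <- g$bonds$j[k]
    nbr_en_excess[i] <- nbr_en_excess[i] + (en[j] - en[i])
    nbr_en_excess[j] <- nbr_en_excess[j] + (en[i] - en[j])
  }

  with_seed(child_seed(spec$seed, can), {
    ns <- spec$noise_sigma
    # --- charge ---
    q <- 0.10 * nbr_en_excess + 0.05 * g$atoms$num_h * (EN_TABLE[["H"]] - en)
    q <- q + stats::rnorm(n, 0, ns[["charge"]])
    q <- q + (g$net_formal_charge - sum(q)) / n

    # --- Fukui indices ---
    site_act <- function(centers, w2, w3, w4, ipso, base_arom, base_hetero) {
      act <- base_arom * g$atoms$aromatic +
        base_hetero * (sym %in% c("N", "O", "S") & !g$atoms$aromatic)
      for (c0 in centers) {
        act <- act + direct_kernel(D[c0, ], w2, w3, w4)
        act[D[c0, ] == 1] <- act[D[c0, ] == 1] + ipso
      }
      act
    }
    fk <- function(act, sigma) {
      s <- exp(act)
      f <- s / sum(s)
      f <- pmax(f + stats::rnorm(n, 0, sigma), 1e-4)
      f / sum(f)
    }
    f_nuc <- fk(site_act(donors, 0.9, -0.35, 0.8, -0.5, 0.3, 0.4) +
                  site_act(withdr, -0.45, 0.1, -0.35, -0.2, 0, 0),
                ns[["fukui_nuc"]])
    f_elec <- fk(site_act(withdr, 0.7, -0.25, 0.6, -0.3, 0.2, 0) +
                   site_act(donors, -0.5, 0.15, -0.4, -0.2, 0, 0.5),
                 ns[["fukui_elec"]])

    # --- NMR shielding ---
    base <- NMR_BASE[sym]
    base[is.na(base)] <- 200
    nmr <- base - 40 * g$atoms$aromatic + 6 * g$atoms$num_h -
      15 * nbr_en_excess + stats::rnorm(n, 0, ns[["nmr"]])

    # --- bonds ---
    bo <- bl <- numeric(nb)
    if (nb > 0) {
      tb <- BOND_ORDER_BASE[g$bonds$bond_type]
      deg_i <- g$atoms$degree[g$bonds$i]
      deg_j <- g$atoms$degree[g$bonds$j]
      bo <- tb - 0.03 * (deg_i + deg_j - 2) +
        stats::rnorm(nb, 0, ns[["bond_order"]])
      bo <- pmax(bo, 0.55)
      ri <- COV_RADIUS[sym[g$bonds$i]]; ri[is.na(ri)] <- 1
      rj <- COV_RADIUS[sym[g$bonds$j]]; rj[is.na(rj)] <- 1
      bl <- (ri + rj) * (1 - 0.07 * (tb - 1)) +
        stats::rnorm(nb, 0, ns[["bond_length"]])
      bl <- pmax(bl, 0.6)
    }

    list(
      atoms = data.frame(smiles = can, atom_index = seq_len(n),
                         charge = unname(q), fukui_elec = unname(f_elec),
                         fukui_nuc = unname(f_nuc), nmr = unname(nmr),
                         stringsAsFactors = FALSE),
      bonds = if (nb > 0) data.frame(smiles = can,
                                     atom_index_1 = g$bonds$i,
                                     atom_index_2 = g$bonds$j,
                                     bond_order = unname(bo),
                                     bond_length = unname(bl),
                                     stringsAsFactors = FALSE)
      else data.frame(smiles = character(), atom_index_1 = integer(),
                      atom_index_2 = integer(), bond_order = numeric(),
                      bond_length = numeric(), stringsAsFactors = FALSE)
    )
  })
}

#' Oracle descriptor table for a set of molecules
#' @param smiles character vector of molecule SMILES
#' @param spec an [oracle_spec()]
#' @param validate check all table invariants after generation
#' @return a `descriptor_table` with provenance `"oracle"`
#' @export
oracle_table <- function(smiles, spec = oracle_spec(), validate = FALSE) {
  chem_prefetch(chem_canonical(smiles))
  per <- lapply(smiles, oracle_descriptors, spec = spec)
  descriptor_table(
    do.call(rbind, lapply(per, `[[`, "atoms")),
    do.call(rbind, lapply(per, `[[`, "bonds")),
    provenance = "oracle", validate = validate
  )
}

# Aromatic core templates: "{}" marks a C-H ring position that may carry a
# substituent (written as "(R)" in place).  Several ring systems (single
# rings, a fused bicycle, a ring-ring linker) give the fixture world a
# non-trivial scaffold structure.
RING_CORES <- list(
  benzene = "c1{}c{}c{}c{}c{}c1{}",
  pyridine = "n1c{}c{}c{}c{}c1{}",
  pyrimidine = "n1cnc{}c{}c1{}",
  thiophene = "s1c{}c{}c{}c1{}",
  naphthalene = "c1{}c{}c{}c2c{}c{}c{}c{}c2c1{}",
  quinoline = "n1c{}c{}c2c{}c{}c{}c{}c2c1",
  biphenyl = "c1{}c{}c{}c{}c{}c1-c1{}c{}c{}c{}c{}c1"
)
RING_CORE_WEIGHTS <- c(benzene = 0.35, pyridine = 0.2, pyrimidine = 0.08,
                       thiophene = 0.08, naphthalene = 0.12,
                       quinoline = 0.07, biphenyl = 0.1)
SUBSTITUENTS <- c("C", "CC", "C(C)C", "O", "OC", "N", "N(C)C", "F", "Cl",
                  "C#N", "CO", "C=O")
CHAIN_ATOMS <- c("C", "C", "C", "N", "O")  # carbon-biased

random_ring_smiles <- function() {
  core <- RING_CORES[[sample.int(length(RING_CORES), 1,
                                 prob = RING_CORE_WEIGHTS)]]
  nslot <- lengths(regmatches(core, gregexpr("\\{\\}", core, fixed = FALSE)))
  k <- sample.int(3, 1)                      # 1..3 substituents
  pos <- sample.int(nslot, min(k, nslot))
  fill <- rep("", nslot)
  fill[pos] <- paste0("(", sample(SUBSTITUENTS, length(pos), replace = TRUE),
                      ")")
  out <- core
  for (f in fill) out <- sub("{}", f, out, fixed = TRUE)
  out
}

random_chain_smiles <- function() {
  len <- sample(2:6, 1)
  atoms <- sample(CHAIN_ATOMS, len, replace = TRUE)
  atoms[1] <- "C"                            # avoid O-O / N-O strings at the head
  out <- atoms[1]
  for (k in 2:len) {
    branch <- atoms[k] == "C" && stats::runif(1) < 0.25
    out <- paste0(out, if (branch) "(C)" else "", atoms[k])
  }
  out
}

#' Generate distinct, valid, neutral fixture molecules
#'
#' Draws substituted six-membered aromatics (benzene/pyridine cores with 1-3
#' substituents from a fixed fragment set) and short heteroatom chains from
#' a fragment grammar, deduplicated by canonical SMILES.  Deterministic per
#' seed.
#'
#' @param n number of molecules
#' @param seed integer seed
#' @param aromatic_frac fraction of draws from the aromatic grammar
#' @return character vector of `n` unique canonical SMILES
#' @export
generate_molecules <- function(n, seed = 1L, aromatic_frac = 0.7) {
  stopifnot(n >= 1)
  out <- character(0)
  with_seed(child_seed(seed, "molecules"), {
    tries <- 0L
    while (length(out) < n && tries < 200L * n) {
      batch <- replicate(max(16L, n), {
        if (stats::runif(1) < aromatic_frac) random_ring_smiles()
        else random_chain_smiles()
      })
      can <- chem_canonical(batch)
      can <- can[!is.na(can)]
      out <- unique(c(out, can))
      tries <- tries + length(batch)
    }
  })
  rs_assert(length(out) >= n, "insufficient_data",
            "fragment grammar exhausted before reaching n unique molecules")
  out[seq_len(n)]
}

#' Toy reaction generator specification
#'
#' The toy transformation is an electrophilic aromatic chlorination:
#' substrate + Cl2 gives an aryl chloride at one of the symmetry-distinct
#' aromatic C-H sites.  The major site is the argmax over candidate sites of
#' `fukui_nuc(site) - steric_weight * steric(site)`, where `steric(site)` is
#' the number of heavy atoms within 2 bonds of the site (purely
#' topological).  `label_noise` flips the major label to a random minor
#' candidate with the given probability.
#'
#' @param oracle an [oracle_spec()] supplying the mock descriptors (the rule
#'   is evaluated on noise-free descriptors so labels are a deterministic
#'   function of topology)
#' @param steric_weight weight of the steric penalty (Fukui-index units per
#'   neighbouring heavy atom)
#' @param label_noise probability of flipping the major label
#' @param min_margin minimum rule-score margin by which the major site must
#'   beat the runner-up for a record to count as selective.  The default is
#'   the oracle's Fukui noise scale (0.01): below it the argmax label is
#'   numerically fragile rather than a stable function of the descriptors,
#'   the toy analogue of an ambiguous product mixture a yield-based
#'   curation would exclude.
#' @return a `toy_reaction_spec`
#' @export
toy_reaction_spec <- function(oracle = oracle_spec(), steric_weight = 0.015,
                              label_noise = 0, min_margin = 0.01) {
  stopifnot(label_noise >= 0, label_noise <= 1, min_margin >= 0)
  structure(list(oracle = oracle, steric_weight = steric_weight,
                 label_noise = label_noise, min_margin = min_margin,
                 template = "[cH:1].[Cl:2][Cl:3]>>[c:1][Cl:2]",
                 pair_tmaps = c(1L, 2L)),
            class = "toy_reaction_spec")
}

steric_count <- function(g, site) {
  D <- graph_distances(g)
  sum(D[site, ] > 0 & D[site, ] <= 2)
}

#' Selectivity rule score of each candidate site
#' @param g substrate `mol_graph` in canonical order
#' @param sites integer vector of candidate site indices (canonical order)
#' @param spec a [toy_reaction_spec()]
#' @return numeric scores; the major site is the argmax
#' @export
selectivity_rule <- function(g, sites, spec) {
  noiseless <- oracle_spec(noise_sigma = c(charge = 0), seed = spec$oracle$seed)
  noiseless$noise_sigma[] <- 0
  d <- oracle_descriptors(g$smiles_canonical, noiseless)
  vapply(sites, function(s) {
    d$atoms$fukui_nuc[s] - spec$steric_weight * steric_count(g, s)
  }, numeric(1))
}

#' Generate selective toy reactions
#'
#' Each record is an atom-mapped chlorination with all symmetry-distinct
#' candidate outcomes enumerated through the reaction template, a major
#' outcome selected by [selectivity_rule()] (optionally label-flipped), and
#' a yield drawn uniformly from [50, 100] so every record survives the
#' default yield filter.  Substrate map numbers follow canonical atom order,
#' so map k is storage row k of the descriptor tables.
#'
#' @param n number of selective records
#' @param spec a [toy_reaction_spec()]
#' @param seed integer seed
#' @return list of `reaction_record` objects (see [reaction_record()])
#' @export
generate_selective_reactions <- function(n, spec = toy_reaction_spec(),
                                         seed = 1L) {
  stopifnot(n >= 1)
  records <- list()
  with_seed(child_seed(seed, "reactions"), {
    batch_seed <- 0L
    while (length(records) < n && batch_seed < 50L) {
      batch_seed <- batch_seed + 1L
      mols <- generate_molecules(max(2L * (n - length(records)), 32L),
                                 seed = child_seed(seed, paste0("sub", batch_seed)),
                                 aromatic_frac = 1)
      chem_prefetch(mols)
      mapped <- chem_map_smiles(mols)
      rsmis <- vapply(seq_along(mols), function(mi) {
        noff <- n_atoms(parse_mapped_smiles(mols[mi]))
        paste0(mapped[mi], ".",
               sprintf("[Cl:%d][Cl:%d]", noff + 1L, noff + 2L))
      }, character(1))
      apps <- chem_call("apply_template",
                        list(smarts = spec$template,
                             pair_tmaps = spec$pair_tmaps,
                             reactants = as.list(rsmis)))
      chem_prefetch(rsmis)
      for (mi in seq_along(mols)) {
        if (length(records) >= n) break
        g <- parse_mapped_smiles(mols[mi])
        rsmi <- rsmis[mi]
        app <- apps[[mi]]
        if (!isTRUE(app$ok) || length(app$outcomes) < 2) next
        cands <- lapply(app$outcomes, function(o) {
          list(pair = c(as.integer(o$pair[[1]]), as.integer(o$pair[[2]])),
               product_smiles = o$product)
        })
        sites <- vapply(cands, function(cc) cc$pair[1], integer(1))
        sc <- selectivity_rule(g, sites, spec)
        top2 <- sort(sc, decreasing = TRUE)[1:2]
        if (top2[1] - top2[2] < spec$min_margin) next  # not genuinely selective
        major <- which.max(sc)             # ties: lowest candidate index
        if (spec$label_noise > 0 && stats::runif(1) < spec$label_noise) {
          minor <- setdiff(seq_along(cands), major)
          major <- minor[sample.int(length(minor), 1)]
        }
        records[[length(records) + 1L]] <- reaction_record(
          reactant_smiles = rsmi,
          candidates = cands,
          major_index = major,
          yield_pct = stats::runif(1, 50, 100),
          reaction_class = "aromatic_CH_functionalization"
        )
      }
    }
  })
  rs_assert(length(records) >= n, "insufficient_data",
            "could not generate enough selective substrates")
  records[seq_len(n)]
}

#' Write a self-consistent fixture bundle to disk
#'
#' Produces molecules, oracle atom/bond descriptor tables, a selective toy
#' reaction dataset and a JSON manifest recording every generation
#' parameter.
#'
#' @param dir output directory (created if missing)
#' @param n_molecules,n_reactions bundle sizes
#' @param seed integer seed
#' @param spec a [toy_reaction_spec()]
#' @return invisibly, a list of written paths
#' @export
make_fixture_bundle <- function(dir, n_molecules = 100L, n_reactions = 50L,
                                seed = 1L, spec = toy_reaction_spec()) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  mols <- generate_molecules(n_molecules, seed = seed)
  records <- generate_selective_reactions(n_reactions, spec = spec, seed = seed)
  subs <- vapply(records, function(r) {
    chem_canonical(strsplit(r$reactant_smiles, ".", fixed = TRUE)[[1]][1])
  }, character(1))
  tab <- oracle_table(unique(c(mols, subs, "ClCl")), spec = spec$oracle)
  paths <- list(
    molecules = file.path(dir, "molecules.smi"),
    atoms = file.path(dir, "descriptors_atoms.csv"),
    bonds = file.path(dir, "descriptors_bonds.csv"),
    reactions = file.path(dir, "reactions.csv"),
    manifest = file.path(dir, "manifest.json")
  )
  writeLines(mols, paths$molecules)
  save_descriptor_table(tab, paths$atoms, paths$bonds)
  save_reaction_records(records, paths$reactions)
  validate_descriptor_table(tab)
  jsonlite::write_json(list(
    seed = seed, n_molecules = n_molecules, n_reactions = n_reactions,
    oracle_noise_sigma = as.list(spec$oracle$noise_sigma),
    oracle_seed = spec$oracle$seed,
    steric_weight = spec$steric_weight, label_noise = spec$label_noise,
    template = spec$template,
    package_version = as.character(utils::packageVersion("regiosel"))
  ), paths$manifest, auto_unbox = TRUE, digits = NA)
  invisible(paths)
}
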